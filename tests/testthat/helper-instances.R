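# Fixture builders shared across tests. Everything is generated in code
# under fixed seeds; no data files.

# random positive data matrix + random positive factors (not a fit)
randomInstance <- function(n, m, k1, k2, seed) {
    set.seed(seed)
    X <- matrix(runif(n * m), n, m)
    F <- factorTriple(matrix(runif(n * k1), n, k1),
                      matrix(runif(k1 * k2), k1, k2),
                      matrix(runif(m * k2), m, k2))
    list(X = X, F = F)
}

# exactly factorizable instance: X = U S V^T from random positive factors
exactInstance <- function(n, m, k1, k2, seed) {
    set.seed(seed)
    F <- factorTriple(matrix(runif(n * k1), n, k1),
                      matrix(runif(k1 * k2), k1, k2),
                      matrix(runif(m * k2), m, k2))
    list(X = reconstruct(F), F = F)
}

# exactly factorizable instance whose factors have entries bounded away
# from zero AND near-orthogonal columns (block-dominant structure), so the
# normal matrices are well conditioned and small perturbations keep the
# unconstrained least-squares solves inside the non-negative orthant
exactInstancePos <- function(n, m, k1, k2, seed) {
    set.seed(seed)
    blockFactor <- function(nr, k) {
        A <- matrix(runif(nr * k, 0.2, 0.4), nr, k)
        A[cbind(seq_len(nr), rep_len(seq_len(k), nr))] <- runif(nr, 2, 3)
        A
    }
    S <- matrix(runif(k1 * k2, 0.2, 0.4), k1, k2)
    S[cbind(seq_len(min(k1, k2)), seq_len(min(k1, k2)))] <- runif(min(k1, k2), 2, 3)
    F <- factorTriple(blockFactor(n, k1), S, blockFactor(m, k2))
    list(X = reconstruct(F), F = F)
}

# multiply factors by (1 + scale * uniform): small positive perturbation
perturbFactors <- function(F, scale, seed) {
    set.seed(seed)
    jit <- function(A) A * (1 + scale * matrix(runif(length(A)), nrow(A)))
    factorTriple(jit(factorU(F)), jit(factorS(F)), jit(factorV(F)))
}

# dense matrix with a given fraction of non-zero entries
sparseRandomMatrix <- function(n, m, density, seed) {
    set.seed(seed)
    X <- matrix(0, n, m)
    keep <- sample.int(n * m, ceiling(density * n * m))
    X[keep] <- runif(length(keep))
    X
}

maxAbsDiff <- function(A, B) max(abs(as.matrix(A) - as.matrix(B)))

tripleDiff <- function(F1, F2) {
    max(maxAbsDiff(factorU(F1), factorU(F2)),
        maxAbsDiff(factorS(F1), factorS(F2)),
        maxAbsDiff(factorV(F1), factorV(F2)))
}

# Independent oracle for one full cyclic coordinate-descent iteration,
# derived from the residual form of the objective rather than the
# precomputed Gram-matrix form the implementation uses. For each
# coordinate block the non-negative 1-D quadratic minimizer is computed
# in closed form from the residual against that block's rank-1 term,
# sweeping in the same cyclic order with immediate propagation.
codOracle <- function(X, F) {
    X <- as.matrix(X)
    U <- factorU(F); S <- factorS(F); V <- factorV(F)
    k1 <- ncol(U); k2 <- ncol(V)
    for (i in seq_len(k1)) {                   # columns of U
        W <- S %*% t(V)                        # k1 x m
        w <- W[i, ]
        den <- sum(w^2)
        if (den <= 1e-12) next
        R <- X - U %*% W + outer(U[, i], w)    # residual without block i
        U[, i] <- pmax(0, as.vector(R %*% w) / den)
    }
    for (j in seq_len(k2)) {                   # columns of V
        W <- U %*% S                           # n x k2
        w <- W[, j]
        den <- sum(w^2)
        if (den <= 1e-12) next
        R <- X - W %*% t(V) + outer(w, V[, j])
        V[, j] <- pmax(0, as.vector(crossprod(R, w)) / den)
    }
    for (i in seq_len(k1)) {                   # entries of S, row-major
        for (j in seq_len(k2)) {
            den <- sum(U[, i]^2) * sum(V[, j]^2)
            if (den <= 1e-12) next
            R <- X - U %*% S %*% t(V) + S[i, j] * outer(U[, i], V[, j])
            S[i, j] <- pmax(0, sum(R * outer(U[, i], V[, j])) / den)
        }
    }
    factorTriple(U, S, V)
}
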