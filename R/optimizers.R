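# One-full-iteration updates for the four optimization methods. Each step
# takes (X, FactorTriple) and returns the updated FactorTriple. Factors
# are updated sequentially in the order U, V, S, each later sub-update
# seeing the already-updated earlier factors. All methods share the same
# gradient building blocks:
#   U-subproblem: numerator X V S^T,      denominator U (S V^T V S^T)
#   V-subproblem: numerator X^T U S,      denominator V (S^T U^T U S)
#   S-subproblem: numerator U^T X V,      denominator (U^T U) S (V^T V)
# For sparse X only the products X V and X^T U touch the data matrix, so
# nothing n x m is ever materialized.

# floor for Hadamard-division denominators; keeps the multiplicative lock
# (zero factor entries stay zero) while never producing NaN/Inf
.DIV_FLOOR <- 1e-12

.xv <- function(X, V) as.matrix(X %*% V)      # n x k2
.xtu <- function(X, U) as.matrix(crossprod(X, U))  # m x k1

#' Multiplicative update rules (MUR): one iteration
#'
#' Applies the classical gradient-ratio updates
#' \deqn{U \leftarrow U \odot (X V S^T \oslash U S V^T V S^T)}
#' \deqn{V \leftarrow V \odot (X^T U S \oslash V S^T U^T U S)}
#' \deqn{S \leftarrow S \odot (U^T X V \oslash U^T U S V^T V)}
#' in that order, where \eqn{\odot}/\eqn{\oslash} are elementwise
#' product/division. Non-negativity is preserved by construction and zero
#' entries stay zero (multiplicative lock). Denominators are floored at
#' 1e-12 so a vanishing denominator yields a finite update instead of
#' NaN.
#'
#' @param X non-negative data matrix, dense or sparse.
#' @param F current [FactorTriple-class].
#' @return The updated \code{FactorTriple}.
#' @family solver steps
#' @export
murStep <- function(X, F) {
    U <- F@U; S <- F@S; V <- F@V
    VtV <- crossprod(V)
    U <- U * (.xv(X, V) %*% t(S)) / pmax(U %*% (S %*% VtV %*% t(S)), .DIV_FLOOR)
    UtU <- crossprod(U)
    V <- V * (.xtu(X, U) %*% S) / pmax(V %*% (t(S) %*% UtU %*% S), .DIV_FLOOR)
    VtV <- crossprod(V)
    S <- S * (crossprod(U, .xv(X, V))) / pmax(UtU %*% S %*% VtV, .DIV_FLOOR)
    new("FactorTriple", U = U, S = S, V = V)
}

# Right-divide M %*% solve(A) for symmetric A, falling back to the
# Moore-Penrose pseudo-inverse when A is singular.
.rightSolve <- function(M, A) {
    tryCatch(t(solve(A, t(M))),
        error = function(e) {
            warning("singular normal matrix in ALS solve; using pseudo-inverse")
            M %*% MASS::ginv(A)
        })
}

.leftSolve <- function(A, M) {
    tryCatch(solve(A, M),
        error = function(e) {
            warning("singular normal matrix in ALS solve; using pseudo-inverse")
            MASS::ginv(A) %*% M
        })
}

#' Alternating least squares (ALS): one iteration
#'
#' Solves the unconstrained least-squares subproblem for each factor via
#' its k x k normal equations and then projects negative entries to zero:
#' \deqn{U \leftarrow [(X V S^T)(S V^T V S^T)^{-1}]_+}
#' \deqn{V \leftarrow [(X^T U S)(S^T U^T U S)^{-1}]_+}
#' \deqn{S \leftarrow [(U^T U)^{-1}(U^T X V)(V^T V)^{-1}]_+}
#' The projection is a heuristic: the objective is not guaranteed to
#' decrease across an ALS iteration, and on dense data the method can
#' diverge. Singular normal matrices fall back to a pseudo-inverse with a
#' warning.
#'
#' @inheritParams murStep
#' @return The updated \code{FactorTriple}.
#' @family solver steps
#' @export
alsStep <- function(X, F) {
    U <- F@U; S <- F@S; V <- F@V
    VtV <- crossprod(V)
    U <- projectNonnegative(.rightSolve(.xv(X, V) %*% t(S),
                                        S %*% VtV %*% t(S)))
    UtU <- crossprod(U)
    V <- projectNonnegative(.rightSolve(.xtu(X, U) %*% S,
                                        t(S) %*% UtU %*% S))
    VtV <- crossprod(V)
    S <- projectNonnegative(.rightSolve(
        .leftSolve(UtU, crossprod(U, .xv(X, V))), VtV))
    new("FactorTriple", U = U, S = S, V = V)
}

#' Projected gradients (PG): one iteration
#'
#' For each factor in the order U, V, S, forms the projection matrix
#' (a rescaled gradient), e.g. for U
#' \deqn{P_u = U - U \oslash (U S V^T V S^T) \odot (X V S^T),}
#' computes the adaptive step size as the ratio of
#' \eqn{\sum(P_u \odot (U S V^T V S^T - X V S^T))} to
#' \eqn{\mathrm{tr}((S V^T V)(S^T P_u^T P_u))} (and the analogous
#' expressions for V and S), and applies
#' \eqn{U \leftarrow [U - \eta_u P_u]_+}. The step size takes the largest
#' move along the scaled gradient that the quadratic model supports; with
#' the step size pinned to 1 the update reduces exactly to the
#' multiplicative update rule. When a step-size denominator vanishes
#' (e.g. at an exact factorization, where P = 0) that factor's update is
#' skipped, preserving the fixed point.
#'
#' @inheritParams murStep
#' @param fixedStep optional numeric; when given (e.g. \code{1}), it is
#'   used as the step size for all three factors instead of the adaptive
#'   value.
#' @return The updated \code{FactorTriple}.
#' @family solver steps
#' @export
pgStep <- function(X, F, fixedStep = NULL) {
    U <- F@U; S <- F@S; V <- F@V

    .move <- function(A, num, den, trDen) {
        P <- A - (A / pmax(den, .DIV_FLOOR)) * num
        if (is.null(fixedStep)) {
            tr <- trDen(P)
            if (!is.finite(tr) || tr <= 0) return(A)  # degenerate: skip
            eta <- sum(P * (den - num)) / tr
        } else eta <- fixedStep
        projectNonnegative(A - eta * P)
    }

    VtV <- crossprod(V)
    SVtV <- S %*% VtV
    U <- .move(U, .xv(X, V) %*% t(S), U %*% (SVtV %*% t(S)),
               function(P) sum(SVtV * t(t(S) %*% crossprod(P))))
    UtU <- crossprod(U)
    V <- .move(V, .xtu(X, U) %*% S, V %*% (t(S) %*% UtU %*% S),
               function(P) sum((S %*% crossprod(P)) * (UtU %*% S)))
    VtV <- crossprod(V)
    S <- .move(S, crossprod(U, .xv(X, V)), UtU %*% S %*% VtV,
               function(P) sum((UtU %*% P) * (P %*% VtV)))
    new("FactorTriple", U = U, S = S, V = V)
}

#' Cyclic coordinate descent (COD / HALS): one iteration
#'
#' Sweeps the columns of U (i = 1..k1), then the columns of V
#' (j = 1..k2), then the entries of S (row-major), replacing each
#' coordinate block by its exact non-negative least-squares minimizer
#' given everything else:
#' \deqn{u_{\cdot i} \leftarrow \left[u_{\cdot i} +
#'   \frac{(X V S^T)_{\cdot i} - (U S V^T V S^T)_{\cdot i}}
#'        {s_{i\cdot} V^T V s_{i\cdot}^T}\right]_+}
#' and analogously for \eqn{v_{\cdot j}} and \eqn{s_{ij}}. Updated
#' coordinates are used immediately inside the sweep, which is what makes
#' coordinate descent converge in far fewer iterations than joint-gradient
#' methods. The whole updated value is projected, so each update is the
#' coordinate-wise minimizer clipped at the non-negativity boundary. A
#' coordinate whose curvature (denominator) is zero is skipped unchanged.
#'
#' @inheritParams murStep
#' @return The updated \code{FactorTriple}.
#' @family solver steps
#' @export
codStep <- function(X, F) {
    U <- F@U; S <- F@S; V <- F@V
    k1 <- ncol(U); k2 <- ncol(V)

    # --- columns of U; curvature of column i is B[i,i] = s_i. V^T V s_i.^T
    VtV <- crossprod(V)
    A <- .xv(X, V) %*% t(S)          # n x k1
    B <- S %*% VtV %*% t(S)          # k1 x k1
    for (i in seq_len(k1)) {
        if (B[i, i] <= .DIV_FLOOR) next
        U[, i] <- pmax(0, U[, i] + (A[, i] - U %*% B[, i]) / B[i, i])
    }

    # --- columns of V
    UtU <- crossprod(U)
    A2 <- .xtu(X, U) %*% S           # m x k2
    B2 <- t(S) %*% UtU %*% S         # k2 x k2
    for (j in seq_len(k2)) {
        if (B2[j, j] <= .DIV_FLOOR) next
        V[, j] <- pmax(0, V[, j] + (A2[, j] - V %*% B2[, j]) / B2[j, j])
    }

    # --- entries of S, row-major; M = U^T U S V^T V maintained incrementally
    VtV <- crossprod(V)
    C <- crossprod(U, .xv(X, V))     # k1 x k2
    M <- UtU %*% S %*% VtV
    for (i in seq_len(k1)) {
        for (j in seq_len(k2)) {
            den <- UtU[i, i] * VtV[j, j]
            if (den <= .DIV_FLOOR) next
            snew <- max(0, S[i, j] + (C[i, j] - M[i, j]) / den)
            d <- snew - S[i, j]
            if (d != 0) {
                M <- M + d * tcrossprod(UtU[, i], VtV[j, ])
                S[i, j] <- snew
            }
        }
    }
    new("FactorTriple", U = U, S = S, V = V)
}

.stepFunction <- function(method) {
    switch(method,
        mur = murStep, als = alsStep, pg = pgStep, cod = codStep,
        stop("unknown method: ", method))
}
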