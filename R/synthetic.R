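# Synthetic tri-factorizable matrices with known latent structure, in the
# two regimes the solvers are benchmarked on: fully dense non-negative
# matrices (image-like data) and highly sparse matrices with densities of
# a few percent down to a tenth of a percent (ratings / document-term
# like data).
#
# The dense regime is a noisy product of dense uniform factors. The
# sparse regime is built from factors with sparse supports: each of the
# r = min(k1, k2) active components is an overlapping co-cluster, a
# rectangle supp(u_k) x supp(v_k) of positive values, paired through a
# positive diagonal core. The result is exactly rank <= r, non-negative,
# and sparse -- the structure a tri-factor model can actually recover,
# as the sparse benchmark datasets in this field (ratings, document-term
# matrices) are approximately low-rank. Zeroing a uniformly random mask
# of cells would instead produce a matrix with no usable low-rank
# structure, on which no optimizer can reach a small objective.

#' Generate a synthetic non-negative matrix with known factors
#'
#' For \code{density = 1}: draws ground-truth factors U (n x k1),
#' S (k1 x k2), V (m x k2) with uniform(0, 1) entries and forms
#' \deqn{X = U S V^T + \sigma E,} with \eqn{E} elementwise uniform(0, 1)
#' noise, so X is non-negative by construction (additive uniform noise
#' avoids the clipping a Gaussian model would need).
#'
#' For \code{density < 1}: the truth factors have sparse supports. Each
#' of the \code{min(k1, k2)} active components k gets a random row
#' support in U and column support in V, sized so that the union of the
#' component rectangles covers approximately \code{density} of the cells;
#' entries on the support are uniform(0, 1), the core S is diagonal with
#' entries uniform(0.5, 1.5), and the product is returned in sparse
#' storage. The achieved density matches the request up to support
#' overlap and rounding. With \code{noiseLevel > 0}, noise is added on
#' the support only, preserving sparsity.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list with elements \code{X} (dense \code{matrix}, or
#'   \code{Matrix::dgCMatrix} when \code{density < 1}) and \code{truth}
#'   (the generating [FactorTriple-class]).
#' @examples
#' out <- makeSynthetic(syntheticSpec(40, 30, seed = 1))
#' relativeObjective(out$X, out$truth)  # 0: noise-free exact product
#' @export
makeSynthetic <- function(spec) {
    .withSeed(spec@seed, {
        truthSeed <- as.integer((2 * as.numeric(spec@seed) + 1) %% 2^31)
        if (spec@density < 1) .makeSparseSynthetic(spec, truthSeed)
        else .makeDenseSynthetic(spec, truthSeed)
    })
}

.makeDenseSynthetic <- function(spec, truthSeed) {
    n <- spec@n; m <- spec@m
    truth <- initFactors(n, m, spec@k1, spec@k2, seed = truthSeed)
    X <- reconstruct(truth)
    if (spec@noiseLevel > 0)
        X <- X + spec@noiseLevel * matrix(runif(n * m), n, m)
    list(X = X, truth = truth)
}

.makeSparseSynthetic <- function(spec, truthSeed) {
    n <- spec@n; m <- spec@m
    r <- min(spec@k1, spec@k2)
    # per-component rectangle fraction q so that the union of r
    # independent rectangles covers ~density of the cells
    q <- 1 - (1 - spec@density)^(1 / r)
    a <- max(1L, round(sqrt(q) * n))
    b <- max(1L, round(sqrt(q) * m))
    .withSeed(truthSeed, {
        U <- matrix(0, n, spec@k1)
        V <- matrix(0, m, spec@k2)
        S <- matrix(0, spec@k1, spec@k2)
        for (k in seq_len(r)) {
            U[sample.int(n, a), k] <- runif(a)
            V[sample.int(m, b), k] <- runif(b)
            S[k, k] <- runif(1, 0.5, 1.5)
        }
        truth <- factorTriple(U, S, V)
        X <- reconstruct(truth)
        if (spec@noiseLevel > 0) {
            on <- X > 0
            X[on] <- X[on] + spec@noiseLevel * runif(sum(on))
        }
        list(X = methods::as(Matrix::Matrix(X, sparse = TRUE),
                             "CsparseMatrix"),
             truth = truth)
    })
}

#' Desk-scale synthetic presets mirroring the benchmark regimes
#'
#' Named presets covering the two data regimes the optimization methods
#' behave differently on: \describe{
#'   \item{\code{dense-small}}{fully dense (density 1), like flattened
#'     image data.}
#'   \item{\code{sparse-1pct}}{density 1.3\%, like user-item rating
#'     matrices.}
#'   \item{\code{sparse-sub1pct}}{density 0.1\%, like TF-IDF
#'     document-term matrices.}
#' }
#' All presets use true ranks k1 = k2 = 4, no noise, and dimensions with
#' \code{n * m <= 250000} so that a full four-method comparison runs on a
#' desktop in minutes.
#'
#' @return A named list of [SyntheticSpec-class] objects.
#' @examples
#' names(regimePresets())
#' @export
regimePresets <- function() {
    list(
        "dense-small" = syntheticSpec(150L, 100L, 4L, 4L,
                                      noiseLevel = 0, density = 1, seed = 11L),
        "sparse-1pct" = syntheticSpec(400L, 300L, 4L, 4L,
                                      noiseLevel = 0, density = 0.013,
                                      seed = 13L),
        "sparse-sub1pct" = syntheticSpec(500L, 500L, 4L, 4L,
                                         noiseLevel = 0, density = 0.001,
                                         seed = 17L)
    )
}
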