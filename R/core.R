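# Shared numerics: data validation, the relative Frobenius objective in
# dense and sparse form, the stopping rule, and non-negative projection.

.isSparse <- function(X) methods::is(X, "sparseMatrix")

#' Number of explicitly stored non-zeros
#'
#' For sparse matrices, the count of stored entries; for dense matrices,
#' the count of non-zero entries.
#' @param X a dense or sparse non-negative matrix.
#' @return integer count.
#' @export
nnzCount <- function(X) {
    if (.isSparse(X)) length(methods::as(X, "CsparseMatrix")@x)
    else sum(X != 0)
}

#' @describeIn nnzCount Fraction of stored/non-zero entries,
#'   \code{nnzCount(X) / (n * m)}.
#' @export
matrixDensity <- function(X) nnzCount(X) / (nrow(X) * ncol(X))

# Validate a data matrix: numeric, finite, non-negative, not all zero.
# Returns the squared Frobenius norm so callers can cache it.
.checkDataMatrix <- function(X) {
    if (!(is.matrix(X) || .isSparse(X)))
        stop("X must be a numeric matrix or a Matrix sparse matrix")
    vals <- if (.isSparse(X)) methods::as(X, "CsparseMatrix")@x else X
    if (anyNA(vals) || any(!is.finite(vals)))
        stop("X contains missing or non-finite values")
    if (any(vals < 0)) {
        idx <- which(as.matrix(X) < 0, arr.ind = TRUE)[1L, ]
        stop("negative entry in X at row ", idx[1L], ", column ", idx[2L])
    }
    normX2 <- sum(vals^2)
    if (normX2 == 0)
        stop("degenerate input: X is all zero, relative objective undefined")
    normX2
}

.checkShapes <- function(X, F) {
    if (nrow(F@U) != nrow(X) || nrow(F@V) != ncol(X))
        stop("shape mismatch: X is ", nrow(X), "x", ncol(X),
             " but factors reconstruct ", nrow(F@U), "x", nrow(F@V))
    invisible(TRUE)
}

#' Relative Frobenius objective of a tri-factorization
#'
#' Computes \deqn{D = \|X - U S V^T\|_F^2 / \|X\|_F^2,} the squared
#' Frobenius reconstruction error normalized by the squared norm of the
#' data. \code{D = 0} at an exact factorization and \code{D = 1} for the
#' all-zero model. All solvers trace and test convergence on this
#' normalized objective; the unnormalized Frobenius loss is
#' \code{D * sum(X^2)}.
#'
#' For sparse \code{X} the dense reconstruction is never materialized.
#' The norm is expanded as
#' \deqn{\|X\|_F^2 - 2\,\mathrm{tr}(S^T U^T X V) +
#'       \mathrm{tr}((U^T U) S (V^T V) S^T)}
#' which touches only the stored non-zeros and k-sized intermediates.
#' Tiny negative values arising from cancellation are clamped to zero.
#'
#' @param X non-negative data matrix (dense \code{matrix} or
#'   \code{Matrix} sparse), not all zero.
#' @param F a [FactorTriple-class] with conforming shapes.
#' @param normX2 optional cached value of \code{sum(X^2)}; when looping,
#'   pass it to avoid recomputation.
#' @return A single non-negative number.
#' @examples
#' f <- factorTriple(matrix(1), matrix(1), matrix(1))
#' relativeObjective(matrix(2), f)  # (2-1)^2 / 2^2 = 0.25
#' @export
relativeObjective <- function(X, F, normX2 = NULL) {
    if (is.null(normX2)) normX2 <- .checkDataMatrix(X)
    .checkShapes(X, F)
    U <- F@U; S <- F@S; V <- F@V
    if (.isSparse(X)) {
        UtXV <- as.matrix(crossprod(U, X %*% V))
        cross <- sum(UtXV * S)
        quad <- sum((crossprod(U) %*% S %*% crossprod(V)) * S)
        max(0, normX2 - 2 * cross + quad) / normX2
    } else {
        sum((X - U %*% S %*% t(V))^2) / normX2
    }
}

#' Stopping rule on the relative objective change
#'
#' Fires when the relative change between successive objective values,
#' \eqn{|D_{i+1} - D_i| / D_i}, drops below \code{epsilon} -- but never
#' before \code{nStart} iterations, because slow early progress (typical
#' of multiplicative updates during their start-up phase) can otherwise
#' trigger the criterion spuriously. The absolute value means an
#' objective *increase* smaller than epsilon also stops; divergence is
#' the job of [detectDivergence()], not of this rule.
#'
#' @param dPrev objective at the previous iteration (> 0; an exact zero
#'   is treated as already converged).
#' @param dCurr objective at the current iteration.
#' @param cfg a [SolverConfig-class] supplying \code{epsilon} and
#'   \code{nStart}.
#' @param iteration current iteration index (>= 1).
#' @return \code{TRUE} if optimization should stop.
#' @export
checkStop <- function(dPrev, dCurr, cfg, iteration) {
    if (dPrev == 0) return(TRUE)
    iteration >= cfg@nStart && abs(dCurr - dPrev) / dPrev < cfg@epsilon
}

#' Projection onto the non-negative orthant
#'
#' Elementwise \code{max(a, 0)}: negative entries are set to zero, the
#' shape is preserved. This is the \eqn{[A]_+} operation used by the ALS,
#' PG and COD updates.
#'
#' @param A a numeric matrix or vector.
#' @return \code{A} with negative entries replaced by 0.
#' @examples
#' projectNonnegative(matrix(c(-1, 2, 0, -3), 2, 2))
#' @export
projectNonnegative <- function(A) pmax(A, 0)
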