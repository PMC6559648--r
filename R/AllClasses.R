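#' @import methods
#' @importFrom stats runif
#' @importFrom utils read.table write.table
#' @importFrom Matrix readMM writeMM sparseMatrix crossprod tcrossprod t
#' @importFrom MASS ginv
NULL

#' @importClassesFrom Matrix sparseMatrix
setClassUnion("DataMatrix", members = c("matrix", "sparseMatrix"))

#' Triple of non-negative latent matrices
#'
#' Container for the three latent matrices of a tri-factorization
#' \eqn{X \approx U S V^T}: \code{U} (\eqn{n \times k_1}) spans the row
#' space, \code{V} (\eqn{m \times k_2}) the column space, and \code{S}
#' (\eqn{k_1 \times k_2}) encodes interactions between the two latent
#' spaces. All entries must be non-negative.
#'
#' @slot U numeric matrix, \eqn{n \times k_1}, entries >= 0.
#' @slot S numeric matrix, \eqn{k_1 \times k_2}, entries >= 0.
#' @slot V numeric matrix, \eqn{m \times k_2}, entries >= 0.
#'
#' @seealso [factorTriple()] for the user-facing constructor,
#'   [factorU()], [factorS()], [factorV()] for accessors.
#' @exportClass FactorTriple
setClass("FactorTriple",
    representation(U = "matrix", S = "matrix", V = "matrix"))

setValidity("FactorTriple", function(object) {
    msgs <- character()
    if (nrow(object@S) != ncol(object@U))
        msgs <- c(msgs, "nrow(S) must equal ncol(U) (rank k1)")
    if (ncol(object@S) != ncol(object@V))
        msgs <- c(msgs, "ncol(S) must equal ncol(V) (rank k2)")
    for (nm in c("U", "S", "V")) {
        A <- slot(object, nm)
        if (!is.numeric(A) || anyNA(A))
            msgs <- c(msgs, paste0(nm, " must be numeric with no NA"))
        else if (any(A < 0))
            msgs <- c(msgs, paste0(nm, " has negative entries"))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FactorTriple
#'
#' @param U,S,V non-negative numeric matrices with conforming shapes
#'   (\code{ncol(U) == nrow(S)}, \code{ncol(S) == ncol(V)}).
#' @return A [FactorTriple-class] object. A warning (not an error) is
#'   issued when a rank exceeds the corresponding data dimension
#'   (\code{k1 > nrow(U)} or \code{k2 > nrow(V)}); such factorizations
#'   are unusual but not invalid.
#' @examples
#' f <- factorTriple(matrix(1, 4, 2), matrix(1, 2, 3), matrix(1, 5, 3))
#' dim(reconstruct(f))
#' @export
factorTriple <- function(U, S, V) {
    U <- as.matrix(U); S <- as.matrix(S); V <- as.matrix(V)
    storage.mode(U) <- storage.mode(S) <- storage.mode(V) <- "double"
    if (ncol(U) > nrow(U))
        warning("rank k1 = ", ncol(U), " exceeds n = ", nrow(U))
    if (ncol(V) > nrow(V))
        warning("rank k2 = ", ncol(V), " exceeds m = ", nrow(V))
    new("FactorTriple", U = U, S = S, V = V)
}

#' @describeIn factorTriple Row-space latent matrix U.
#' @param object a \code{FactorTriple} (or, for [factors()], a
#'   \code{FitResult}).
#' @export
factorU <- function(object) object@U

#' @describeIn factorTriple Interaction matrix S.
#' @export
factorS <- function(object) object@S

#' @describeIn factorTriple Column-space latent matrix V.
#' @export
factorV <- function(object) object@V

#' @describeIn factorTriple Factorization ranks \code{c(k1, k2)}.
#' @export
ranks <- function(object) c(k1 = ncol(object@U), k2 = ncol(object@V))

#' @describeIn factorTriple Dense reconstruction \eqn{U S V^T}.
#' @export
reconstruct <- function(object) object@U %*% object@S %*% t(object@V)

setMethod("show", "FactorTriple", function(object) {
    cat("FactorTriple: U[", nrow(object@U), "x", ncol(object@U),
        "] S[", nrow(object@S), "x", ncol(object@S),
        "] V[", nrow(object@V), "x", ncol(object@V), "]\n", sep = "")
})

#' Solver configuration
#'
#' Holds the optimization method and convergence parameters shared by all
#' solvers: the relative-change threshold \code{epsilon} of the stopping
#' rule, the minimum number of iterations \code{nStart} before stopping
#' is allowed (guards against premature stops during the slow start-up
#' phase of multiplicative updates), the iteration cap \code{nStop}, and
#' the seed for reproducible uniform random initialization.
#'
#' @slot method one of \code{"mur"}, \code{"als"}, \code{"pg"}, \code{"cod"}.
#' @slot epsilon positive stopping threshold on the relative objective change.
#' @slot nStart minimum iterations before the stopping rule may fire.
#' @slot nStop maximum number of iterations.
#' @slot seed integer seed for initialization.
#' @exportClass SolverConfig
setClass("SolverConfig",
    representation(method = "character", epsilon = "numeric",
                   nStart = "integer", nStop = "integer", seed = "integer"))

setValidity("SolverConfig", function(object) {
    msgs <- character()
    if (!object@method %in% c("mur", "als", "pg", "cod"))
        msgs <- c(msgs, "method must be one of mur, als, pg, cod")
    if (!(length(object@epsilon) == 1L && object@epsilon > 0))
        msgs <- c(msgs, "epsilon must be a single positive number")
    if (!(object@nStart >= 0L && object@nStart < object@nStop))
        msgs <- c(msgs, "need 0 <= nStart < nStop")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SolverConfig
#'
#' @param method optimization method: multiplicative update rules
#'   (\code{"mur"}), alternating least squares (\code{"als"}), projected
#'   gradients (\code{"pg"}), or cyclic coordinate descent (\code{"cod"}).
#'   Case-insensitive.
#' @param epsilon stopping threshold on \eqn{|D_{i+1}-D_i|/D_i}
#'   (default \code{1e-6}).
#' @param nStart minimum iterations before stopping is allowed (default 100).
#' @param nStop maximum iterations (default 50000).
#' @param seed integer seed for the uniform random initialization.
#' @return A [SolverConfig-class] object.
#' @examples
#' solverConfig("cod", seed = 7)
#' @export
solverConfig <- function(method = c("mur", "als", "pg", "cod"),
                         epsilon = 1e-6, nStart = 100L, nStop = 50000L,
                         seed = 1L) {
    if (length(method) > 1L) method <- method[1L]
    method <- match.arg(tolower(method), c("mur", "als", "pg", "cod"))
    new("SolverConfig", method = method, epsilon = as.numeric(epsilon),
        nStart = as.integer(nStart), nStop = as.integer(nStop),
        seed = as.integer(seed))
}

setMethod("show", "SolverConfig", function(object) {
    cat("SolverConfig: method=", object@method,
        " epsilon=", format(object@epsilon),
        " nStart=", object@nStart, " nStop=", object@nStop,
        " seed=", object@seed, "\n", sep = "")
})

#' Result of one factorization run
#'
#' @slot factors final [FactorTriple-class].
#' @slot status \code{"converged"}, \code{"max_iter_reached"} or
#'   \code{"diverged"}. Runs that hit the iteration cap or diverged are
#'   the ones benchmark tables mark as non-converged and exclude from
#'   iteration and runtime averages.
#' @slot iterations number of iterations performed.
#' @slot finalObjective relative objective \eqn{D} at termination.
#' @slot trace data.frame with columns \code{iteration}, \code{objective}
#'   (the relative objective \eqn{D_i}) and \code{elapsed_seconds}
#'   (cumulative wall time), one row per iteration.
#' @seealso [factorize()], [optTrace()], [writeTrace()]
#' @exportClass FitResult
setClass("FitResult",
    representation(factors = "FactorTriple", status = "character",
                   iterations = "integer", finalObjective = "numeric",
                   trace = "data.frame"))

setValidity("FitResult", function(object) {
    if (!object@status %in% c("converged", "max_iter_reached", "diverged"))
        return("status must be converged, max_iter_reached or diverged")
    TRUE
})

#' @describeIn factorize Final factors of a fit.
#' @export
factors <- function(object) object@factors

#' @describeIn factorize Convergence status of a fit.
#' @export
status <- function(object) object@status

#' @describeIn factorize Number of iterations performed.
#' @export
iterations <- function(object) object@iterations

#' @describeIn factorize Relative objective at termination.
#' @export
finalObjective <- function(object) object@finalObjective

#' @describeIn factorize Per-iteration optimization trace as a data.frame
#'   with columns \code{iteration}, \code{objective},
#'   \code{elapsed_seconds}.
#' @export
optTrace <- function(object) object@trace

setMethod("show", "FitResult", function(object) {
    cat("FitResult (", object@status, "): ", object@iterations,
        " iterations, final relative objective ",
        format(object@finalObjective, digits = 6), "\n", sep = "")
})

#' Specification of a synthetic tri-factorizable matrix
#'
#' @slot n,m data dimensions.
#' @slot k1,k2 true latent ranks of the generating factors.
#' @slot noiseLevel scale of additive uniform(0,1) noise (>= 0).
#' @slot density fraction of entries retained; values in (0, 1). Matrices
#'   with density < 1 are returned in sparse storage.
#' @slot seed integer seed.
#' @seealso [syntheticSpec()], [makeSynthetic()], [regimePresets()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(n = "integer", m = "integer", k1 = "integer",
                   k2 = "integer", noiseLevel = "numeric",
                   density = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@n < 1L || object@m < 1L) msgs <- c(msgs, "need n, m >= 1")
    if (object@k1 > object@n || object@k2 > object@m)
        msgs <- c(msgs, "need k1 <= n and k2 <= m")
    if (!(object@density > 0 && object@density <= 1))
        msgs <- c(msgs, "density must be in (0, 1]")
    if (object@noiseLevel < 0) msgs <- c(msgs, "noiseLevel must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param n,m dimensions of the generated matrix.
#' @param k1,k2 true ranks of the generating factors.
#' @param noiseLevel scale of the additive uniform noise (default 0).
#' @param density fraction of entries retained (default 1 = dense).
#' @param seed integer seed.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' makeSynthetic(syntheticSpec(30, 20, seed = 1))$X[1:3, 1:3]
#' @export
syntheticSpec <- function(n, m, k1 = 4L, k2 = 4L, noiseLevel = 0,
                          density = 1, seed = 1L) {
    new("SyntheticSpec", n = as.integer(n), m = as.integer(m),
        k1 = as.integer(k1), k2 = as.integer(k2),
        noiseLevel = as.numeric(noiseLevel), density = as.numeric(density),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec: ", object@n, "x", object@m,
        " true ranks (", object@k1, ",", object@k2, ")",
        " noise=", object@noiseLevel, " density=", object@density,
        " seed=", object@seed, "\n", sep = "")
})
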