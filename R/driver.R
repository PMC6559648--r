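# Driver: random initialization, the iteration loop with method dispatch,
# stopping and divergence detection, tracing, and restart orchestration.

# run code with a private RNG stream, leaving the caller's RNG untouched
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Random initialization of the latent matrices
#'
#' Fills U (n x k1), V (m x k2) and S (k1 x k2), in that order, with
#' independent uniform(0, 1) draws from a generator seeded with
#' \code{seed}. The same seed always yields bitwise-identical factors;
#' the caller's RNG state is left untouched.
#'
#' @param n,m data dimensions.
#' @param k1,k2 factorization ranks.
#' @param seed integer seed.
#' @return A [FactorTriple-class].
#' @export
initFactors <- function(n, m, k1, k2, seed) {
    .withSeed(seed, {
        U <- matrix(runif(n * k1), n, k1)
        V <- matrix(runif(m * k2), m, k2)
        S <- matrix(runif(k1 * k2), k1, k2)
        factorTriple(U, S, V)
    })
}

# objective values at or below this are at the floating-point floor of an
# exactly factorizable problem; rounding jitter there is not divergence
.OBJ_FLOOR <- 1e-12
# an "increase" must exceed this relative size to count as oscillation,
# so that last-bit rounding jitter on a plateau is ignored
.UP_TOL <- 1e-9

#' Divergence detection on an optimization trace
#'
#' Inspects the trailing \code{window} objective values and flags the run
#' as diverging when (a) any value is non-finite, (b) the objective
#' increased relative to its predecessor in more than half of the
#' window's steps (oscillation), or (c) the latest value exceeds the
#' window's minimum by more than a factor of 10 (escalation). Monotone
#' non-increasing traces, such as those produced by multiplicative
#' updates and coordinate descent, never trigger it.
#'
#' Two numerical guards keep the detector from misfiring on solved or
#' plateaued runs: objective values at the floating-point floor (latest
#' value below 1e-12) are never flagged, and a step only counts as an
#' increase when it exceeds a 1e-9 relative size, so last-bit rounding
#' jitter on a flat plateau is ignored.
#'
#' @param trace a [factorize()] trace data.frame, a \code{FitResult}, or
#'   a numeric vector of objective values.
#' @param window number of trailing iterations examined (default 20).
#' @return \code{TRUE} if the trace looks divergent.
#' @export
detectDivergence <- function(trace, window = 20L) {
    d <- if (is(trace, "FitResult")) trace@trace$objective
         else if (is.data.frame(trace)) trace$objective
         else as.numeric(trace)
    if (length(d) == 0L) stop("empty trace")
    d <- d[max(1L, length(d) - window + 1L):length(d)]
    if (any(!is.finite(d))) return(TRUE)
    if (d[length(d)] <= .OBJ_FLOOR) return(FALSE)
    if (length(d) >= 2L) {
        rel <- diff(d) / pmax(d[-length(d)], .OBJ_FLOOR)
        if (sum(rel > .UP_TOL) > length(rel) / 2) return(TRUE)
        if (d[length(d)] > 10 * max(min(d), .OBJ_FLOOR)) return(TRUE)
    }
    FALSE
}

#' Train a tri-factorization model
#'
#' Runs the full optimization loop: initializes U, V, S uniformly at
#' random (seeded from \code{cfg}), then repeats the update step of the
#' configured method, recording the relative objective \eqn{D_i} and
#' cumulative wall time after every full iteration. The loop terminates
#' when the stopping rule [checkStop()] fires (status
#' \code{"converged"}), when the iteration cap \code{nStop} is hit
#' (\code{"max_iter_reached"}), or when [detectDivergence()] fires or the
#' objective becomes non-finite (\code{"diverged"}).
#'
#' @param X non-negative data matrix, dense \code{matrix} or
#'   \code{Matrix} sparse; must contain at least one non-zero.
#' @param cfg a [SolverConfig-class].
#' @param k1,k2 factorization ranks.
#' @param init optional [FactorTriple-class] used instead of random
#'   initialization (warm starts).
#' @return A [FitResult-class].
#' @examples
#' X <- makeSynthetic(syntheticSpec(30, 20, seed = 3))$X
#' fit <- factorize(X, solverConfig("cod", nStart = 10, seed = 3), 4, 4)
#' status(fit)
#' @export
factorize <- function(X, cfg, k1, k2, init = NULL) {
    normX2 <- .checkDataMatrix(X)
    stopifnot(k1 >= 1, k2 >= 1)
    F <- if (is.null(init)) initFactors(nrow(X), ncol(X), k1, k2, cfg@seed)
         else init
    .checkShapes(X, F)
    step <- .stepFunction(cfg@method)

    nStop <- cfg@nStop
    objs <- numeric(nStop)
    times <- numeric(nStop)
    dPrev <- relativeObjective(X, F, normX2)
    status <- "max_iter_reached"
    t0 <- proc.time()[["elapsed"]]
    iter <- 0L
    window <- 20L
    while (iter < nStop) {
        iter <- iter + 1L
        F <- step(X, F)
        d <- relativeObjective(X, F, normX2)
        objs[iter] <- d
        times[iter] <- proc.time()[["elapsed"]] - t0
        if (!is.finite(d)) { status <- "diverged"; break }
        if (checkStop(dPrev, d, cfg, iter)) { status <- "converged"; break }
        if (iter >= window &&
            detectDivergence(objs[(iter - window + 1L):iter])) {
            status <- "diverged"; break
        }
        dPrev <- d
    }
    trace <- data.frame(iteration = seq_len(iter),
                        objective = objs[seq_len(iter)],
                        elapsed_seconds = times[seq_len(iter)])
    new("FitResult", factors = F, status = status, iterations = iter,
        finalObjective = objs[iter], trace = trace)
}

#' Multiple restarts from independent random initializations
#'
#' Runs [factorize()] \code{nRestarts} times with seeds \code{cfg@seed},
#' \code{cfg@seed + 1}, ... so that runs are independent yet
#' reproducible.
#'
#' @inheritParams factorize
#' @param nRestarts number of independent runs (>= 1).
#' @return A list of [FitResult-class] objects, one per restart.
#' @seealso [bestRun()], [objectiveSpan()], [meanConvergedIterations()],
#'   [summarizeRestarts()]
#' @export
runRestarts <- function(X, cfg, k1, k2, nRestarts = 10L) {
    stopifnot(nRestarts >= 1)
    lapply(seq_len(nRestarts) - 1L, function(r) {
        cfgR <- cfg
        cfgR@seed <- cfg@seed + r
        factorize(X, cfgR, k1, k2)
    })
}

#' @describeIn runRestarts The run with the lowest final objective.
#' @param fits a list of \code{FitResult} objects.
#' @export
bestRun <- function(fits) fits[[which.min(vapply(fits, finalObjective, 0))]]

#' @describeIn runRestarts Range (min, max) of final objectives across
#'   runs -- the span highlighted around optimization traces.
#' @export
objectiveSpan <- function(fits) range(vapply(fits, finalObjective, 0))

#' @describeIn runRestarts Mean iteration count over converged runs only;
#'   runs that hit the iteration cap or diverged are excluded, and
#'   \code{NA} is returned when no run converged.
#' @export
meanConvergedIterations <- function(fits) {
    ok <- vapply(fits, status, "") == "converged"
    if (!any(ok)) return(NA_real_)
    mean(vapply(fits[ok], iterations, 0L))
}

#' @describeIn runRestarts One-row-per-run summary data.frame.
#' @export
summarizeRestarts <- function(fits) {
    data.frame(
        run = seq_along(fits),
        status = vapply(fits, status, ""),
        iterations = vapply(fits, iterations, 0L),
        finalObjective = vapply(fits, finalObjective, 0),
        runtime_seconds = vapply(fits, function(f)
            f@trace$elapsed_seconds[nrow(f@trace)], 0))
}

#' Export an optimization trace to delimited text
#'
#' Writes one row per iteration with header
#' \code{iteration,objective,elapsed_seconds}.
#'
#' @param fit a [FitResult-class] (or a trace data.frame).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(fit, path) {
    tr <- if (is(fit, "FitResult")) fit@trace else fit
    write.table(tr, path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}
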