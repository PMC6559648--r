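# Benchmark harness: run all methods across synthetic presets with shared
# restart seeds and aggregate iteration counts, runtimes and speed-ups the
# way convergence tables are usually reported -- non-converged runs are
# excluded from averages and flagged instead, so a method that fails on a
# regime cannot bias the means.

.runRuntime <- function(fit) {
    tr <- optTrace(fit)
    tr$elapsed_seconds[nrow(tr)]
}

#' Compare optimization methods across synthetic presets
#'
#' Generates each preset once, then runs every method on it with the same
#' set of restart seeds (so all methods see identical initializations).
#' For each (preset, method) cell the report gives the number of
#' converged runs, mean iterations and mean runtime over converged runs
#' only (\code{NA} when no run converged, the analogue of an "infinity"
#' entry in a convergence table), the best final objective, per-run final
#' objectives, and the iteration speed-up relative to multiplicative
#' update rules (MUR iterations / method iterations, defined only when
#' both converge).
#'
#' @param presets named list of [SyntheticSpec-class] objects (default
#'   [regimePresets()]).
#' @param cfg a [SolverConfig-class]; its method slot is ignored, its
#'   convergence parameters and base seed are shared by all runs.
#' @param nRestarts restarts per (preset, method).
#' @param methods methods to compare.
#' @param k1,k2 fitting ranks; default \code{NULL} uses each preset's
#'   true ranks.
#' @param startGuard \code{"mur-only"} (default) applies the
#'   minimum-iteration guard \code{cfg@nStart} to multiplicative updates
#'   only, whose slow start-up phase can trigger the stopping rule
#'   spuriously; the other methods run with \code{nStart = 1} so their
#'   iteration counts reflect actual convergence (ALS and COD routinely
#'   converge in well under 100 iterations). \code{"all"} applies
#'   \code{cfg@nStart} to every method.
#' @return A data.frame of class \code{BenchReport} with one row per
#'   (preset, method).
#' @export
compareMethods <- function(presets = regimePresets(), cfg = solverConfig(),
                           nRestarts = 10L,
                           methods = c("mur", "als", "pg", "cod"),
                           k1 = NULL, k2 = NULL,
                           startGuard = c("mur-only", "all")) {
    startGuard <- match.arg(startGuard)
    rows <- list()
    for (pname in names(presets)) {
        spec <- presets[[pname]]
        X <- makeSynthetic(spec)$X
        fk1 <- if (is.null(k1)) spec@k1 else k1
        fk2 <- if (is.null(k2)) spec@k2 else k2
        cells <- list()
        for (met in methods) {
            cfgM <- cfg
            cfgM@method <- met
            if (startGuard == "mur-only" && met != "mur")
                cfgM@nStart <- 1L
            fits <- runRestarts(X, cfgM, fk1, fk2, nRestarts)
            ok <- vapply(fits, status, "") == "converged"
            cells[[met]] <- data.frame(
                preset = pname, method = met,
                nRuns = length(fits), nConverged = sum(ok),
                nonConverged = !any(ok),
                meanIterations = if (any(ok))
                    mean(vapply(fits[ok], iterations, 0L)) else NA_real_,
                meanRuntime = if (any(ok))
                    mean(vapply(fits[ok], .runRuntime, 0)) else NA_real_,
                bestObjective = min(vapply(fits, finalObjective, 0)),
                finalObjectives = paste(
                    signif(vapply(fits, finalObjective, 0), 6),
                    collapse = ";"))
        }
        tab <- do.call(rbind, cells)
        murIter <- tab$meanIterations[tab$method == "mur"]
        tab$speedupVsMUR <- if (length(murIter) == 1L && !is.na(murIter))
            murIter / tab$meanIterations else NA_real_
        rows[[pname]] <- tab
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("BenchReport", "data.frame")
    out
}

#' @describeIn compareMethods Write a benchmark report as delimited text.
#' @param report a \code{BenchReport}.
#' @param path output path.
#' @export
writeBenchReport <- function(report, path) {
    write.table(as.data.frame(report), path, sep = ",",
                row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Runtime and iterations as a function of factorization rank
#'
#' Runs [factorize()] on \code{X} for every rank in \code{ranks} (with
#' \code{k1 = k2 = k}) and every method, averaging iterations and runtime
#' over restarts with non-converged runs excluded.
#'
#' @param X non-negative data matrix.
#' @param ranks integer vector of ranks; each must be at most
#'   \code{min(nrow(X), ncol(X))}.
#' @param cfg a [SolverConfig-class] (method slot ignored).
#' @param nRestarts restarts per (rank, method).
#' @param methods methods to sweep.
#' @inheritParams compareMethods
#' @return A data.frame with one row per (rank, method): converged-run
#'   counts, mean iterations, mean runtime, best final objective.
#' @export
rankSweep <- function(X, ranks, cfg = solverConfig(), nRestarts = 3L,
                      methods = c("mur", "als", "pg", "cod"),
                      startGuard = c("mur-only", "all")) {
    startGuard <- match.arg(startGuard)
    if (max(ranks) > min(nrow(X), ncol(X)))
        stop("rank ", max(ranks), " exceeds min(n, m) = ",
             min(nrow(X), ncol(X)))
    rows <- list()
    for (k in ranks) {
        for (met in methods) {
            cfgM <- cfg
            cfgM@method <- met
            if (startGuard == "mur-only" && met != "mur")
                cfgM@nStart <- 1L
            fits <- runRestarts(X, cfgM, k, k, nRestarts)
            ok <- vapply(fits, status, "") == "converged"
            rows[[paste(k, met)]] <- data.frame(
                rank = k, method = met,
                nConverged = sum(ok),
                meanIterations = if (any(ok))
                    mean(vapply(fits[ok], iterations, 0L)) else NA_real_,
                meanRuntime = if (any(ok))
                    mean(vapply(fits[ok], .runRuntime, 0)) else NA_real_,
                bestObjective = min(vapply(fits, finalObjective, 0)))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
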