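test_that("initialization is seeded, shaped, and uniform(0,1)", {
    f1 <- initFactors(5, 4, 2, 3, seed = 99)
    f2 <- initFactors(5, 4, 2, 3, seed = 99)
    expect_identical(factorU(f1), factorU(f2))
    expect_identical(factorS(f1), factorS(f2))
    expect_identical(factorV(f1), factorV(f2))
    expect_equal(dim(factorU(f1)), c(5L, 2L))
    expect_equal(dim(factorS(f1)), c(2L, 3L))
    expect_equal(dim(factorV(f1)), c(4L, 3L))
    big <- initFactors(200, 100, 10, 10, seed = 1)
    expect_true(all(factorU(big) > 0 & factorU(big) < 1))
    # seeding is local: the caller's RNG stream is untouched
    set.seed(1); a <- runif(1)
    set.seed(1); initFactors(3, 3, 2, 2, seed = 77); b <- runif(1)
    expect_identical(a, b)
})

test_that("factorize respects the iteration cap and records the trace", {
    inst <- exactInstance(15, 10, 3, 3, seed = 4)
    cfg <- solverConfig("mur", nStop = 3L, nStart = 1L, seed = 1)
    fit <- factorize(inst$X, cfg, 3, 3)
    expect_equal(status(fit), "max_iter_reached")
    expect_equal(iterations(fit), 3L)
    tr <- optTrace(fit)
    expect_equal(nrow(tr), 3L)
    expect_equal(tr$iteration, 1:3)
    expect_true(all(diff(tr$elapsed_seconds) >= 0))
    expect_true(all(tr$objective >= 0))
})

test_that("identical seed and config give identical traces", {
    inst <- exactInstance(20, 15, 3, 3, seed = 8)
    cfg <- solverConfig("cod", nStop = 40L, nStart = 1L, seed = 5)
    f1 <- factorize(inst$X, cfg, 3, 3)
    f2 <- factorize(inst$X, cfg, 3, 3)
    expect_identical(optTrace(f1)$objective, optTrace(f2)$objective)
    expect_identical(factorU(factors(f1)), factorU(factors(f2)))
})

test_that("divergence detector fires on the right trace shapes", {
    expect_false(detectDivergence(seq(1, 0.1, length.out = 30)))  # decreasing
    expect_true(detectDivergence(c(0.9, 0.5, NaN, 0.4)))          # non-finite
    expect_true(detectDivergence(rep(c(0.5, 5.0), 12)))           # oscillation
    expect_true(detectDivergence(c(seq(0.5, 0.4, length.out = 19), 4.5)))
    # a solved run jittering at the floating-point floor is not divergence
    expect_false(detectDivergence(abs(rep(c(1e-16, 3e-15), 12))))
    # a flat plateau with last-bit jitter is not divergence
    expect_false(detectDivergence(0.14 + rep(c(0, 1e-14), 12)))
    expect_error(detectDivergence(numeric(0)), "empty")
})

test_that("convergence status implies the stopping rule held", {
    inst <- exactInstance(40, 30, 3, 3, seed = 12)
    cfg <- solverConfig("cod", nStart = 20L, seed = 2)
    fit <- factorize(inst$X, cfg, 3, 3)
    expect_equal(status(fit), "converged")
    expect_gte(iterations(fit), 20L)
    d <- optTrace(fit)$objective
    n <- length(d)
    lastChange <- abs(d[n] - d[n - 1]) / d[n - 1]
    expect_true(lastChange < cfg@epsilon || d[n - 1] == 0)
    expect_lt(finalObjective(fit), 1e-3)  # parameter recovery
})

test_that("restarts use consecutive seeds and expose summaries", {
    inst <- exactInstance(25, 20, 3, 3, seed = 21)
    cfg <- solverConfig("cod", nStart = 5L, nStop = 60L, seed = 10)
    fits <- runRestarts(inst$X, cfg, 3, 3, nRestarts = 4)
    expect_length(fits, 4L)
    # restart r reproduces a plain factorize with seed+r
    cfg2 <- cfg; cfg2@seed <- 12L
    expect_identical(optTrace(fits[[3]])$objective,
                     optTrace(factorize(inst$X, cfg2, 3, 3))$objective)
    best <- bestRun(fits)
    objs <- vapply(fits, finalObjective, 0)
    expect_equal(finalObjective(best), min(objs))
    expect_equal(objectiveSpan(fits), range(objs))
    s <- summarizeRestarts(fits)
    expect_equal(nrow(s), 4L)
    expect_named(s, c("run", "status", "iterations", "finalObjective",
                      "runtime_seconds"))
})

test_that("iteration means are computed over converged runs only", {
    mk <- function(st, it) {
        f <- factorTriple(matrix(1), matrix(1), matrix(1))
        new("FitResult", factors = f, status = st, iterations = it,
            finalObjective = 0.5,
            trace = data.frame(iteration = seq_len(it),
                               objective = rep(0.5, it),
                               elapsed_seconds = seq_len(it) * 0.1))
    }
    fits <- list(mk("converged", 40L), mk("max_iter_reached", 50000L),
                 mk("converged", 60L), mk("diverged", 12L))
    expect_equal(meanConvergedIterations(fits), 50)
    expect_true(is.na(meanConvergedIterations(list(mk("diverged", 5L)))))
})

test_that("doubling nStart on a converged configuration is benign", {
    inst <- exactInstance(30, 20, 3, 3, seed = 31)
    cfg1 <- solverConfig("cod", nStart = 30L, seed = 3)
    cfg2 <- solverConfig("cod", nStart = 60L, seed = 3)
    f1 <- factorize(inst$X, cfg1, 3, 3)
    f2 <- factorize(inst$X, cfg2, 3, 3)
    expect_equal(status(f1), "converged")
    expect_equal(status(f2), "converged")
    expect_lt(abs(finalObjective(f1) - finalObjective(f2)), 1e-5)
})

test_that("trace export writes the documented delimited format", {
    inst <- exactInstance(15, 10, 2, 2, seed = 6)
    fit <- factorize(inst$X, solverConfig("mur", nStop = 5L, nStart = 1L), 2, 2)
    path <- tempfile(fileext = ".csv")
    writeTrace(fit, path)
    lines <- readLines(path)
    expect_equal(lines[1], "iteration,objective,elapsed_seconds")
    expect_length(lines, 6L)
    back <- read.csv(path)
    expect_equal(back$objective, optTrace(fit)$objective)
})
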