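# Scalar oracles: 1x1 problems where every update can be done by hand.

test_that("MUR scalar update matches hand arithmetic", {
    # exact factorization: all ratios are 1, factors unchanged
    f <- factorTriple(matrix(2), matrix(1), matrix(2))
    out <- murStep(matrix(4), f)
    expect_equal(tripleDiff(out, f), 0)
    # X=4, U=2, S=1, V=1: U -> 4, then V -> 1, S -> 1; exact in one pass
    out <- murStep(matrix(4), factorTriple(matrix(2), matrix(1), matrix(1)))
    expect_equal(factorU(out), matrix(4))
    expect_equal(factorS(out), matrix(1))
    expect_equal(factorV(out), matrix(1))
    expect_equal(relativeObjective(matrix(4), out), 0)
})

test_that("ALS scalar update solves the subproblems exactly", {
    out <- alsStep(matrix(4), factorTriple(matrix(1), matrix(1), matrix(1)))
    expect_equal(factorU(out), matrix(4))
    expect_equal(factorS(out), matrix(1))
    expect_equal(factorV(out), matrix(1))
})

test_that("PG scalar update reproduces the hand-computed step", {
    # P_u = 2 - (2/2)*4 = -2; eta_u = (-2*(2-4)) / (1*(1*4)) = 1
    # U <- [2 - 1*(-2)]+ = 4, identical to the MUR update here
    out <- pgStep(matrix(4), factorTriple(matrix(2), matrix(1), matrix(1)))
    expect_equal(factorU(out), matrix(4))
})

test_that("COD scalar column update is the 1-D least-squares minimizer", {
    out <- codStep(matrix(4), factorTriple(matrix(2), matrix(1), matrix(1)))
    expect_equal(factorU(out), matrix(4))  # u <- [2 + (4-2)/1]+
})

test_that("all four steps leave an exact factorization fixed", {
    for (seed in 1:6) {
        inst <- exactInstance(12, 9, 3, 3, seed = seed)
        for (step in list(murStep, alsStep, pgStep, codStep))
            expect_lt(tripleDiff(step(inst$X, inst$F), inst$F), 1e-9)
    }
})

test_that("every step preserves non-negativity on random instances", {
    for (seed in 1:10) {
        set.seed(seed)
        inst <- randomInstance(sample(5:25, 1), sample(5:20, 1), 3, 4,
                               seed + 50)
        for (step in list(murStep, alsStep, pgStep, codStep)) {
            out <- step(inst$X, inst$F)
            expect_gte(min(factorU(out)), 0)
            expect_gte(min(factorS(out)), 0)
            expect_gte(min(factorV(out)), 0)
        }
    }
})

test_that("MUR keeps zero factor entries at zero (multiplicative lock)", {
    inst <- randomInstance(10, 8, 3, 3, seed = 2)
    U <- factorU(inst$F); U[4, ] <- 0
    out <- murStep(inst$X, factorTriple(U, factorS(inst$F), factorV(inst$F)))
    expect_equal(factorU(out)[4, ], c(0, 0, 0))
    expect_true(all(is.finite(factorU(out))))
})

test_that("objective never increases across MUR and COD steps", {
    for (seed in 1:15) {
        set.seed(seed)
        inst <- randomInstance(sample(8:30, 1), sample(6:20, 1), 4, 4,
                               seed + 300)
        for (step in list(murStep, codStep)) {
            d0 <- relativeObjective(inst$X, inst$F)
            d1 <- relativeObjective(inst$X, step(inst$X, inst$F))
            expect_lte(d1, d0 + 1e-12)
        }
    }
})

test_that("ALS clips negative unconstrained solutions to exactly zero", {
    # X with strong anti-structure relative to the factors forces some
    # negative least-squares coefficients
    found <- FALSE
    for (seed in 1:20) {
        inst <- randomInstance(10, 8, 3, 3, seed = 400 + seed)
        raw <- (inst$X %*% factorV(inst$F) %*% t(factorS(inst$F))) %*%
            solve(factorS(inst$F) %*% crossprod(factorV(inst$F)) %*%
                  t(factorS(inst$F)))
        if (any(raw < 0)) {
            out <- alsStep(inst$X, inst$F)
            expect_true(all(factorU(out)[raw < 0] == 0))
            found <- TRUE
            break
        }
    }
    expect_true(found)
})

test_that("ALS falls back to a pseudo-inverse on rank-deficient factors", {
    inst <- randomInstance(10, 8, 3, 3, seed = 9)
    U <- factorU(inst$F); U[, 2] <- U[, 1]  # duplicate column
    S <- factorS(inst$F); S[2, ] <- S[1, ]
    F <- factorTriple(U, S, factorV(inst$F))
    expect_warning(out <- alsStep(inst$X, F), "pseudo-inverse")
    expect_true(all(is.finite(factorU(out))))
})

test_that("PG with step size pinned to 1 equals MUR", {
    for (seed in 1:10) {
        inst <- randomInstance(12, 10, 3, 2, seed = 500 + seed)
        expect_lt(tripleDiff(pgStep(inst$X, inst$F, fixedStep = 1),
                             murStep(inst$X, inst$F)), 1e-10)
    }
})

test_that("COD updates match the independent residual-form minimizer", {
    for (seed in 1:8) {
        set.seed(seed)
        inst <- randomInstance(sample(6:20, 1), sample(5:15, 1), 3, 3,
                               seed + 600)
        expect_lt(tripleDiff(codStep(inst$X, inst$F),
                             codOracle(inst$X, inst$F)), 1e-10)
    }
})

test_that("sparse and dense paths of every step agree entrywise", {
    for (seed in 1:5) {
        X <- sparseRandomMatrix(60, 45, density = 0.05, seed = 700 + seed)
        Xs <- Matrix::Matrix(X, sparse = TRUE)
        F <- randomInstance(60, 45, 4, 4, seed + 800)$F
        for (step in list(murStep, alsStep, pgStep, codStep))
            expect_lt(tripleDiff(step(X, F), step(Xs, F)), 1e-8)
    }
})
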