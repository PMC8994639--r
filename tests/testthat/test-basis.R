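test_that("B-spline bases have the requested dimension and sum to one", {
    for (cfg in list(list(dom = c(0, 1), p = 14L),
                     list(dom = c(0, 2.56), p = 27L))) {
        bb <- makeBsplineBasis(cfg$dom, cfg$p)
        t <- seq(cfg$dom[1], cfg$dom[2], length.out = 51)
        B <- evalBasis(bb, t)
        expect_identical(ncol(B), as.integer(cfg$p))
        expect_equal(rowSums(B), rep(1, length(t)))  # partition of unity
        # equally spaced breakpoints, boundary multiplicity = order
        breaks <- unique(bb@knots)
        expect_equal(breaks, seq(cfg$dom[1], cfg$dom[2],
                                 length.out = cfg$p - 4L + 2L))
        expect_identical(sum(bb@knots == cfg$dom[1]), 4L)
    }
    # 27 cubic functions on [0, 2.56] <=> 25 equally spaced knots
    expect_length(unique(makeBsplineBasis(c(0, 2.56), 27L)@knots), 25L)
    expect_error(makeBsplineBasis(c(0, 1), 3L, order = 4L),
                 "invalid configuration")
    expect_error(makeBsplineBasis(c(1, 1), 8L), "invalid configuration")
})

test_that("least-squares fit matches the normal-equations oracle", {
    set.seed(1)
    t <- seq(0, 1, length.out = 101)
    basis <- makeBsplineBasis(c(0, 1), 14L)
    Phi <- evalBasis(basis, t)
    vals <- sapply(1:4, function(k)
        sin(2 * pi * t) + 0.3 * cos(5 * t) * k + rnorm(101, sd = 0.1))
    cs <- CurveSet(vals, t, subject = rep(c("s1", "s2"), each = 2),
                   group = "g1", treatment = rep(c("t1", "t2"), 2))
    co <- fitCoefficients(cs, basis)
    oracle <- solve(crossprod(Phi)) %*% crossprod(Phi, vals)
    expect_equal(unname(coefMatrix(co)), unname(oracle), tolerance = 1e-9)
    # residuals orthogonal to the basis span on the grid
    res <- vals - Phi %*% coefMatrix(co)
    expect_lt(max(abs(crossprod(Phi, res))), 1e-8)
})

test_that("curves in the basis span are recovered exactly", {
    set.seed(2)
    t <- seq(0, 1, length.out = 60)
    basis <- makeBsplineBasis(c(0, 1), 10L)
    Phi <- evalBasis(basis, t)
    Ctrue <- matrix(rnorm(10 * 4), 10, 4)
    cs <- CurveSet(Phi %*% Ctrue, t,
                   subject = rep(c("s1", "s2"), each = 2), group = "g1",
                   treatment = rep(c("t1", "t2"), 2))
    co <- fitCoefficients(cs, basis)
    expect_equal(unname(coefMatrix(co)), Ctrue, tolerance = 1e-8)
    # constant curve reproduced through partition of unity
    cs1 <- CurveSet(matrix(1, 60, 2), t, subject = "s1", group = "g1",
                    treatment = c("t1", "t2"))
    fit1 <- evaluateCurves(fitCoefficients(cs1, basis), t)
    expect_equal(unname(fit1), matrix(1, 60, 2), tolerance = 1e-10)
    # idempotence: refitting fitted values returns identical coefficients
    fitted <- evaluateCurves(co, t)
    co2 <- fitCoefficients(CurveSet(fitted, t,
        subject = rep(c("s1", "s2"), each = 2), group = "g1",
        treatment = rep(c("t1", "t2"), 2)), basis)
    expect_equal(coefMatrix(co2), coefMatrix(co), tolerance = 1e-10)
})

test_that("curve evaluation renders coefficients against the basis", {
    basis <- makeBsplineBasis(c(0, 1), 8L)
    pts <- seq(0, 1, 0.05)
    expect_equal(evaluateCurves(cbind(rep(0, 8)), pts, basis = basis),
                 cbind(rep(0, length(pts))))
    # unit coefficient e_h reproduces phi_h
    e3 <- replace(rep(0, 8), 3, 1)
    expect_equal(evaluateCurves(cbind(e3), pts, basis = basis)[, 1],
                 evalBasis(basis, pts)[, 3])
    expect_error(evaluateCurves(cbind(e3), c(-0.5, 2), basis = basis),
                 "domain")
})

test_that("GCV dimension selection matches a per-candidate recomputation", {
    set.seed(3)
    t <- seq(0, 1, length.out = 80)
    vals <- sapply(1:6, function(k)
        sin(2 * pi * t + k / 3) + rnorm(80, sd = 0.15))
    cs <- CurveSet(vals, t, subject = rep(paste0("s", 1:3), each = 2),
                   group = "g1", treatment = rep(c("t1", "t2"), 3))
    cands <- c(5L, 8L, 12L, 20L, 30L)
    gcv <- sapply(cands, function(p) {
        Phi <- evalBasis(makeBsplineBasis(c(0, 1), p), t)
        H <- Phi %*% solve(crossprod(Phi), t(Phi))
        mean(sapply(1:6, function(k) {
            rss <- sum((vals[, k] - H %*% vals[, k])^2)
            (rss / 80) / (1 - p / 80)^2
        }))
    })
    expect_identical(gcvDimension(cs, cands), cands[which.min(gcv)])
    expect_identical(gcvDimension(cs, 9L), 9L)          # single candidate
    expect_error(gcvDimension(cs, integer(0)), "invalid configuration")
    # noiseless data in the p = 8 span: smallest candidate >= 8 wins
    basis8 <- makeBsplineBasis(c(0, 1), 8L)
    exact <- evalBasis(basis8, t) %*% matrix(rnorm(8 * 4), 8, 4)
    cse <- CurveSet(exact, t, subject = rep(c("s1", "s2"), each = 2),
                    group = "g1", treatment = rep(c("t1", "t2"), 2))
    expect_identical(gcvDimension(cse, c(5L, 6L, 8L, 12L, 16L)), 8L)
})

test_that("basis JSON serialization round-trips", {
    bb <- makeBsplineBasis(c(0, 2.56), 27L)
    path <- tempfile(fileext = ".json")
    writeBasisJSON(bb, path)
    bb2 <- readBasisJSON(path)
    expect_identical(bb2@p, bb@p)
    expect_identical(bb2@order, bb@order)
    expect_equal(bb2@knots, bb@knots)
    expect_equal(bb2@domain, bb@domain)
})

test_that("Fourier alternative reproduces its own span", {
    t <- seq(0, 1, length.out = 50)
    fb <- makeFourierBasis(c(0, 1), 5L)
    Phi <- evalBasis(fb, t)
    expect_identical(dim(Phi), c(50L, 5L))
    Ctrue <- matrix(rnorm(5 * 2), 5, 2)
    cs <- CurveSet(Phi %*% Ctrue, t, subject = "s1", group = "g1",
                   treatment = c("t1", "t2"))
    expect_equal(unname(coefMatrix(fitCoefficients(cs, fb))), Ctrue,
                 tolerance = 1e-8)
})
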