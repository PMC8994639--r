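test_that("fitDmm recovers per-group means and noiseless parameters", {
    set.seed(10)
    co <- randomCoefSet(5, 2, 2, 3)
    wide <- wideResponse(co)
    B <- fitDmm(wide)
    expect_equal(unname(B), unname(rbind(colMeans(wide@Y[1:5, ]),
                                         colMeans(wide@Y[6:10, ]))))
    # one group: grand mean
    co1 <- randomCoefSet(6, 2, 1, 3)
    w1 <- wideResponse(co1)
    expect_equal(unname(fitDmm(w1))[1, ], colMeans(w1@Y))
    # Y = X B0 exactly: recovery
    B0 <- matrix(rnorm(2 * 6), 2)
    w2 <- new("WideResponse", Y = wide@design %*% B0,
              design = wide@design, groups = wide@groups,
              subjects = wide@subjects, p = 3L, m = 2L)
    expect_equal(unname(fitDmm(w2)), B0)
})

test_that("scalar DMM reduces to classical univariate ANOVA", {
    # p = 1, m = 2, g = 2, group test with T = I_2 left out; use the
    # treatment contrast so the reduced response is scalar
    set.seed(11)
    n <- 8
    C <- matrix(rnorm(2 * n * 2), 1)
    co <- makeCoefSet(C, n = n, m = 2, g = 2)
    wide <- wideResponse(co)
    cp <- buildContrasts(2, 2, "interaction")
    ss <- dmmSscp(wide, cp)
    # scalar oracle: two-sample ANOVA on the scaled treatment differences
    z <- wide@Y %*% (cp@T %x% diag(1))
    grp <- wide@groups
    fit <- stats::aov(z ~ grp)
    an <- summary(fit)[[1]]
    expect_equal(c(ss$Sh), an["grp", "Sum Sq"], tolerance = 1e-10)
    expect_equal(c(ss$Se), an["Residuals", "Sum Sq"], tolerance = 1e-10)
    res <- dmmTest(wide, "interaction", "W")
    expect_equal(res@F, an["grp", "F value"], tolerance = 1e-10)
    expect_equal(res@pValue, an["grp", "Pr(>F)"], tolerance = 1e-10)
})

test_that("Sh + Se decomposes the total SSCP about the null fit", {
    set.seed(12)
    co <- randomCoefSet(6, 2, 2, 2)
    wide <- wideResponse(co)
    cp <- buildContrasts(2, 2, "group")  # G spans all between-group contrasts
    ss <- dmmSscp(wide, cp)
    YT <- wide@Y %*% (cp@T %x% diag(2))
    tot <- crossprod(sweep(YT, 2, colMeans(YT)))
    expect_equal(ss$Sh + ss$Se, tot, tolerance = 1e-8)
})

test_that("MANOVA statistics match a brute-force eigen oracle", {
    set.seed(13)
    for (rep_i in 1:20) {
        Sh <- randomSPD(3); Se <- randomSPD(3)
        st <- manovaStatistics(Sh, Se)
        Ei <- solve(Se)
        Es <- with(eigen(Ei, symmetric = TRUE),
                   vectors %*% diag(sqrt(values)) %*% t(vectors))
        lam <- eigen(Es %*% Sh %*% Es, symmetric = TRUE,
                     only.values = TRUE)$values
        expect_equal(unname(st["W"]), prod(1 / (1 + lam)), tolerance = 1e-8)
        expect_equal(unname(st["LH"]), sum(lam), tolerance = 1e-8)
        expect_equal(unname(st["P"]), sum(lam / (1 + lam)),
                     tolerance = 1e-8)
        expect_equal(unname(st["R"]), max(lam), tolerance = 1e-8)
    }
    expect_equal(unname(manovaStatistics(matrix(0, 2, 2), diag(2))),
                 c(1, 0, 0, 0))
    expect_equal(unname(manovaStatistics(matrix(3, 1, 1),
                                         matrix(1, 1, 1))),
                 c(0.25, 3, 0.75, 3))
    expect_error(manovaStatistics(diag(2), matrix(0, 2, 2)), "singular")
})

test_that("all four F-approximations agree with R's MANOVA summary", {
    set.seed(14)
    co <- randomCoefSet(10, 2, 2, 3)
    wide <- wideResponse(co)
    fit <- stats::manova(wide@Y ~ wide@groups)
    for (st in c("W", "P", "LH", "R")) {
        res <- dmmTest(wide, "group", st)
        nm <- c(W = "Wilks", P = "Pillai", LH = "Hotelling-Lawley",
                R = "Roy")[[st]]
        ref <- summary(fit, test = nm)$stats[1, ]
        expect_equal(res@value, unname(ref[2]), tolerance = 1e-8)
        expect_equal(res@F, unname(ref[3]), tolerance = 1e-8)
        expect_equal(res@df1, unname(ref[4]), tolerance = 1e-10)
        expect_equal(res@df2, unname(ref[5]), tolerance = 1e-10)
        expect_equal(res@pValue, unname(ref[6]), tolerance = 1e-8)
    }
    expect_equal(fApproximation("W", 1, d = 3, s = 2, ve = 20)$p, 1)
    expect_error(fApproximation("W", 0.5, d = 3, s = 2, ve = 0),
                 "invalid configuration")
})

test_that("DMM tests are scale and contrast-rotation invariant", {
    set.seed(15)
    co <- randomCoefSet(8, 3, 2, 2, subjectSd = 0.5)
    wide <- wideResponse(co)
    base <- dmmTest(wide, "interaction", "W")
    # scale equivariance
    w2 <- new("WideResponse", Y = 3.7 * wide@Y, design = wide@design,
              groups = wide@groups, subjects = wide@subjects,
              p = wide@p, m = wide@m)
    r2 <- dmmTest(w2, "interaction", "W")
    expect_equal(r2@value, base@value, tolerance = 1e-10)
    expect_equal(r2@pValue, base@pValue, tolerance = 1e-10)
    # orthonormal rotation of T leaves all four statistics unchanged
    cp <- buildContrasts(3, 2, "interaction")
    theta <- 0.7
    Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    cpQ <- new("ContrastPair", G = cp@G, T = cp@T %*% Q,
               hypothesis = "interaction")
    s1 <- dmmSscp(wide, cp); s2 <- dmmSscp(wide, cpQ)
    expect_equal(manovaStatistics(s1$Sh, s1$Se),
                 manovaStatistics(s2$Sh, s2$Se), tolerance = 1e-8)
})

test_that("treatment test with identical blocks sits at the null extreme", {
    set.seed(16)
    n <- 10; p <- 2; m <- 3
    block <- matrix(rnorm(p * n), n, p)
    Y <- cbind(block, block, block)  # identical treatment blocks
    wide <- new("WideResponse", Y = Y,
                design = cbind(rep(1, n)), groups = factor(rep("g1", n)),
                subjects = paste0("s", 1:n), p = as.integer(p),
                m = as.integer(m))
    res <- dmmTest(wide, "treatment", "W")
    expect_equal(res@value, 1, tolerance = 1e-10)
    expect_equal(res@pValue, 1, tolerance = 1e-8)
})

test_that("DMM refuses dimension-infeasible problems", {
    set.seed(17)
    co <- randomCoefSet(2, 3, 1, 3)   # n = 2 <= p*m = 9
    expect_error(dmmTest(co, "treatment"), "n > p\\*m")
})

test_that("paired Hotelling T^2 equals the DMM treatment test (m=2, g=1)", {
    set.seed(18)
    n <- 15; p <- 3
    co <- randomCoefSet(n, 2, 1, p, subjectSd = 1)
    wide <- wideResponse(co)
    D <- wide@Y[, 1:p] - wide@Y[, p + 1:p]
    res <- dmmTest(wide, "treatment", "W")
    expect_equal(res@pValue, hotellingPairedP(D), tolerance = 1e-10)
})
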