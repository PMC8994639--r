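# programmatic fixtures shared across the suite

# CoefficientSet straight from a p x (n*m*g) coefficient matrix
makeCoefSet <- function(C, n, m, g, basis = makeBsplineBasis(c(0, 1), 4)) {
    stopifnot(ncol(C) == n * m * g)
    subject <- paste0("g", rep(seq_len(g), each = n * m), "_s",
                      rep(rep(seq_len(n), each = m), g))
    group <- paste0("g", rep(seq_len(g), each = n * m))
    treatment <- paste0("t", rep(seq_len(m), g * n))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(coefficients = C),
        colData = S4Vectors::DataFrame(subject = subject, group = group,
                                       treatment = treatment))
    new("CoefficientSet", se, basis = basis)
}

randomCoefSet <- function(n, m, g, p, sd = 1, subjectSd = 0) {
    N <- n * m * g
    C <- matrix(rnorm(p * N, sd = sd), p, N)
    if (subjectSd > 0) {
        nsub <- n * g
        eff <- matrix(rnorm(p * nsub, sd = subjectSd), p, nsub)
        C <- C + eff[, rep(seq_len(nsub), each = m)]
    }
    makeCoefSet(C, n, m, g)
}

# independent paired Hotelling T^2 oracle on per-subject difference vectors
hotellingPairedP <- function(D) {
    n <- nrow(D); p <- ncol(D)
    T2 <- n * c(t(colMeans(D)) %*% solve(stats::var(D)) %*% colMeans(D))
    Fst <- (n - p) / (p * (n - 1)) * T2
    stats::pf(Fst, p, n - p, lower.tail = FALSE)
}

randomSPD <- function(d, df = d + 4) {
    A <- matrix(rnorm(d * df), df, d)
    crossprod(A)
}

# tiny well-formed CurveSet on an arbitrary grid
toyCurveSet <- function(n = 2, m = 2, g = 1, R = 25, f = function(t, k)
    sin(pi * t) + 0.1 * k) {
    t <- seq(0, 1, length.out = R)
    N <- n * m * g
    vals <- sapply(seq_len(N), function(k) f(t, k))
    subject <- paste0("g", rep(seq_len(g), each = n * m), "_s",
                      rep(rep(seq_len(n), each = m), g))
    group <- paste0("g", rep(seq_len(g), each = n * m))
    treatment <- paste0("t", rep(seq_len(m), g * n))
    CurveSet(vals, t, subject = subject, group = group,
             treatment = treatment)
}
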