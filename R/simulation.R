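#' Effect functions of the simulation scenarios
#'
#' Returns the closed-form treatment (A), group (B) or interaction (I)
#' effect function for the scenario families M1-M4 of the simulation study
#' (m = 3 treatments, g = 2 groups).  M2 shares M1's effect functions (only
#' the error model changes); M3 replaces the interaction family; M4 swaps
#' the group and interaction families.
#'
#' @param scenario "M1", "M2", "M3" or "M4".
#' @param role "treatment", "group" or "interaction".
#' @param variant "A1".."A3", "B1".."B3" or "I1"/"I2" matching the role.
#' @param i treatment index (1..3), used by treatment/interaction variants.
#' @param j group index (1..2), used by group/interaction variants.
#' @return a function of t.
#' @examples
#' effectFunction("M1", "treatment", "A1")(0.5)  # 0.25
#' @export
effectFunction <- function(scenario, role, variant, i = 1L, j = 1L) {
    key <- paste(scenario, role, variant, sep = ".")
    fam <- switch(scenario, M1 = , M2 = "M1", M3 = "M3", M4 = "M4",
                  stop("invalid configuration: unknown scenario ", scenario))
    f <- switch(role,
        treatment = switch(variant,
            A1 = function(t) t * (1 - t),
            A2 = function(t) t^(i / 5) * (1 - t)^(6 - i / 5),
            A3 = function(t) t^i * (1 - t)^(6 - i),
            NULL),
        group = switch(fam,
            M1 = , M3 = switch(variant,
                B1 = function(t) 0.1 * abs(sin(4 * pi * t)),
                B2 = function(t) (0.05 * j) * abs(sin(4 * pi * t)),
                B3 = function(t) (0.025 * j) * abs(sin(4 * pi * t)),
                NULL),
            M4 = switch(variant,
                B1 = function(t) sin(2 * pi * t^2)^5,
                B2 = function(t) sin(2 * pi * t^2)^(3 + 2 * j),
                B3 = function(t) sin(2 * pi * t^2)^(5 + 2 * j),
                NULL)),
        interaction = switch(fam,
            M1 = switch(variant,
                I1 = function(t) sin(2 * pi * t^2)^5,
                I2 = function(t) sin(2 * pi * t^2)^(5 + 2 * i * j),
                NULL),
            M3 = switch(variant,
                I1 = function(t) sin(pi * t)^13,
                I2 = function(t) sin(pi * t)^(21 - 2 * i * j),
                NULL),
            M4 = switch(variant,
                I1 = function(t) 0.05 * abs(sin(4 * pi * t)),
                I2 = function(t) (0.025 * i * j) * abs(sin(4 * pi * t)),
                NULL)),
        stop("invalid configuration: unknown role ", role))
    if (is.null(f))
        stop("invalid configuration: unknown variant ", key)
    f
}

#' Construct a simulation scenario specification
#'
#' @param scenario "M1", "M2", "M3" or "M4".
#' @param A,B,I effect-function variants.
#' @param sigmaEps error dispersion (standard deviation); the study grid is
#'   \{0.10, 0.20, 0.40\}.
#' @param n per-group sample size (n1 = n2 = n).
#' @param grid argument grid (default 101 equispaced points on [0, 1]).
#' @param errorModel "iid_gaussian" or "brownian"; defaults to "brownian"
#'   for M2 and "iid_gaussian" otherwise.
#' @param sigmaSubject SD of the per-subject random effect gamma_k.
#' @param muMax upper limit of the U(0, muMax) law of mu_k.
#' @param seed integer seed.
#' @return a \linkS4class{ScenarioSpec}.
#' @export
scenarioSpec <- function(scenario = "M1", A = "A1", B = "B1", I = "I1",
                         sigmaEps = 0.10, n = 50L,
                         grid = seq(0, 1, length.out = 101L),
                         errorModel = NULL, sigmaSubject = 0.2,
                         muMax = 0.05, seed = 1L) {
    if (is.null(errorModel))
        errorModel <- if (scenario == "M2") "brownian" else "iid_gaussian"
    new("ScenarioSpec", scenario = scenario, A = A, B = B, I = I,
        sigmaEps = sigmaEps, n = as.integer(n), grid = as.numeric(grid),
        errorModel = errorModel, sigmaSubject = sigmaSubject,
        muMax = muMax, seed = as.integer(seed))
}

# deterministic effect sums alpha_i + beta_j + theta_ij on the grid,
# columns ordered (i, j) treatment-major within group: j = 1..g, i = 1..m
.deterministic_parts <- function(spec, m = 3L, g = 2L) {
    t <- spec@grid
    D <- matrix(0, length(t), m * g)
    for (j in seq_len(g)) for (i in seq_len(m)) {
        a <- effectFunction(spec@scenario, "treatment", spec@A, i, j)(t)
        b <- effectFunction(spec@scenario, "group", spec@B, i, j)(t)
        th <- effectFunction(spec@scenario, "interaction", spec@I, i, j)(t)
        D[, (j - 1L) * m + i] <- a + b + th
    }
    D
}

# raw value matrix for one replicate; columns ordered group-major, subject,
# treatment within subject.  RNG draw order: mu_k, gamma_k, then errors.
.simulate_matrix <- function(spec, m = 3L, g = 2L) {
    t <- spec@grid
    R <- length(t)
    nsub <- g * spec@n
    N <- nsub * m
    D <- .deterministic_parts(spec, m, g)
    mu_k <- runif(nsub, 0, spec@muMax)
    gam <- rnorm(nsub, mu_k, spec@sigmaSubject)
    E <- if (spec@errorModel == "iid_gaussian") {
        matrix(rnorm(R * N, 0, spec@sigmaEps), R, N)
    } else {
        inc <- matrix(rnorm((R - 1L) * N), R - 1L, N) *
            (spec@sigmaEps * sqrt(diff(t)))
        rbind(0, apply(inc, 2, cumsum)) / 20
    }
    # deterministic part: column (j, k, i) uses D[, (j-1)*m + i]
    detIdx <- as.vector(vapply(seq_len(g), function(j)
        rep((j - 1L) * m + seq_len(m), spec@n), integer(m * spec@n)))
    X <- D[, detIdx, drop = FALSE] +
        outer(sin(pi * t), rep(gam, each = m)) + E
    list(X = X, nsub = nsub)
}

#' Simulate one dataset from a scenario
#'
#' Draws curves from the functional mixed model
#' \eqn{x_{ijk}(t) = \alpha_i(t) + \beta_j(t) + \theta_{ij}(t) +
#' \gamma_k \sin(\pi t) + \epsilon_{ijk}(t)} on the discretization grid,
#' with \eqn{\gamma_k \sim N(\mu_k, \sigma_k)}, \eqn{\mu_k \sim U(0,
#' \mu_{max})} drawn once per subject (shared across that subject's m
#' curves), and errors either i.i.d. Gaussian at each grid point or a
#' zero-start Brownian motion with increment SD
#' \eqn{\sigma_\epsilon\sqrt{\Delta t}} scaled by 1/20.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @return a \linkS4class{CurveSet} (m = 3 treatments, g = 2 groups).
#' @export
simulateScenario <- function(spec) {
    stopifnot(is(spec, "ScenarioSpec"))
    set.seed(spec@seed)
    m <- 3L; g <- 2L
    sim <- .simulate_matrix(spec, m, g)
    n <- spec@n
    subject <- paste0("g", rep(seq_len(g), each = n * m), "_s",
                      rep(rep(seq_len(n), each = m), g))
    group <- paste0("g", rep(seq_len(g), each = n * m))
    treatment <- paste0("t", rep(seq_len(m), g * n))
    CurveSet(sim$X, spec@grid, subject = subject, group = group,
             treatment = treatment)
}

# Wilks p-value from SSCP matrices via Rao's approximation; log-determinant
# fast path with a symmetric-eigenproblem fallback
.wilks_p_core <- function(Sh, Se, d, s, ve) {
    W <- exp(.logdet(Se) - .logdet(Se + Sh))
    if (is.na(W)) W <- manovaStatistics(Sh, Se)[["W"]]
    W <- min(W, 1)
    tt <- if (d^2 + s^2 - 5 > 0)
        sqrt((d^2 * s^2 - 4) / (d^2 + s^2 - 5)) else 1
    r <- ve - (d - s + 1) / 2
    u <- (d * s - 2) / 4
    df1 <- d * s
    df2 <- r * tt - 2 * u
    L <- W^(1 / tt)
    pf((1 - L) / L * df2 / df1, df1, df2, lower.tail = FALSE)
}

#' Run a size/power study for a scenario
#'
#' For each replicate: simulate the scenario, fit cubic B-spline
#' coefficients (dimension \code{basisDim}) on the grid, and run the DMM
#' and/or MMM Wilks tests of parallelism (interaction), treatment and group
#' with the standard m = 3, g = 2 contrast matrices.  Reports per-test
#' acceptance proportions (p >= alpha) over the replicates.
#'
#' @param spec a \linkS4class{ScenarioSpec} (its seed fixes the stream).
#' @param reps number of replicates (the study uses 500).
#' @param methods subset of c("dmm", "mmm").
#' @param hypotheses subset of c("interaction", "treatment", "group").
#' @param alpha significance level (0.05).
#' @param basisDim B-spline dimension p (study value 14).
#' @param order spline order.
#' @return data.frame with one row per (method, hypothesis): columns
#'   scenario, A, B, I, sigmaEps, n, method, hypothesis, acceptance,
#'   rejections, reps.
#' @export
runPowerStudy <- function(spec, reps = 500L, methods = c("dmm", "mmm"),
                          hypotheses = c("interaction", "treatment",
                                         "group"),
                          alpha = 0.05, basisDim = 14L, order = 4L) {
    stopifnot(is(spec, "ScenarioSpec"), reps >= 1)
    methods <- match.arg(methods, several.ok = TRUE)
    m <- 3L; g <- 2L
    p <- as.integer(basisDim)
    n <- spec@n
    nsub <- g * n
    if ("dmm" %in% methods && nsub <= p * m) {
        message("DMM skipped: requires n > p*m (n = ", nsub, ", p*m = ",
                p * m, ")")
        methods <- setdiff(methods, "dmm")
    }
    basis <- makeBsplineBasis(range(spec@grid), p, order)
    Phi <- evalBasis(basis, spec@grid)
    qrPhi <- qr(Phi)
    groups <- rep(seq_len(g), each = n)
    design <- cbind(as.numeric(groups == 1L), as.numeric(groups == 2L))
    cps <- lapply(setNames(hypotheses, hypotheses), function(h)
        buildContrasts(m, g, h))
    TkI <- lapply(cps, function(cp) cp@T %x% diag(p))
    XtXi <- diag(1 / c(n, n))
    dfe <- nsub - g
    rej <- matrix(0L, length(methods), length(hypotheses),
                  dimnames = list(methods, hypotheses))
    set.seed(spec@seed)
    for (rep_i in seq_len(reps)) {
        sim <- .simulate_matrix(spec, m, g)
        C <- qr.coef(qrPhi, sim$X)           # p x N
        Y <- t(matrix(C, p * m, nsub))       # nsub x pm, treatment-major
        for (h in seq_along(hypotheses)) {
            cp <- cps[[h]]
            q <- ncol(cp@T); s <- ncol(cp@G)
            YT <- Y %*% TkI[[h]]
            gm <- rowsum(YT, groups) / n
            E <- YT - gm[groups, , drop = FALSE]
            Se <- crossprod(E)
            GB <- crossprod(cp@G, gm)
            mid <- crossprod(cp@G, XtXi %*% cp@G)
            Sh <- crossprod(GB, solve(mid, GB))
            if ("dmm" %in% methods) {
                pv <- .wilks_p_core(Sh, Se, d = p * q, s = s, ve = dfe)
                if (pv < alpha)
                    rej["dmm", h] <- rej["dmm", h] + 1L
            }
            if ("mmm" %in% methods) {
                idx <- seq_len(p)
                Ses <- matrix(0, p, p); Shs <- matrix(0, p, p)
                for (a in seq_len(q)) {
                    ai <- (a - 1L) * p + idx
                    Ses <- Ses + Se[ai, ai]
                    Shs <- Shs + Sh[ai, ai]
                }
                pv <- .wilks_p_core(Shs, Ses, d = p, s = s * q,
                                    ve = q * dfe)
                if (pv < alpha)
                    rej["mmm", h] <- rej["mmm", h] + 1L
            }
        }
    }
    out <- expand.grid(method = methods, hypothesis = hypotheses,
                       stringsAsFactors = FALSE)
    out$rejections <- mapply(function(mt, h) rej[mt, h], out$method,
                             out$hypothesis)
    out$reps <- as.integer(reps)
    out$acceptance <- 1 - out$rejections / reps
    cbind(data.frame(scenario = spec@scenario, A = spec@A, B = spec@B,
                     I = spec@I, sigmaEps = spec@sigmaEps, n = spec@n),
          out[, c("method", "hypothesis", "acceptance", "rejections",
                  "reps")])
}

setMethod("show", "ScenarioSpec", function(object) {
    cat(sprintf(
        "ScenarioSpec %s (%s, %s, %s): sigmaEps = %g, n = %d/group, %s errors, seed %d\n",
        object@scenario, object@A, object@B, object@I, object@sigmaEps,
        object@n, object@errorModel, object@seed))
})
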