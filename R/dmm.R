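#' Arrange basis coefficients as the wide response of the DMM
#'
#' Builds the n x (p*m) matrix whose i-th row stacks subject i's
#' per-treatment coefficient vectors treatment-major (within each treatment
#' block the p basis coefficients), together with the n x g group-membership
#' design matrix.
#'
#' @param coeffs a \linkS4class{CoefficientSet}.
#' @return a \linkS4class{WideResponse}.
#' @export
wideResponse <- function(coeffs) {
    stopifnot(is(coeffs, "CoefficientSet"))
    C <- coefMatrix(coeffs)
    d <- designLabels(coeffs)
    treatments <- sort(unique(d$treatment))
    m <- length(treatments); p <- nrow(C)
    subj <- .subject_order(d$subject, d$group)
    n <- nrow(subj)
    Y <- matrix(0, n, p * m)
    for (s in seq_len(n)) {
        idx <- vapply(treatments, function(tr)
            which(d$subject == subj$subject[s] & d$treatment == tr),
            integer(1))
        Y[s, ] <- as.vector(C[, idx])
    }
    groups <- factor(subj$group, levels = sort(unique(subj$group)))
    design <- outer(as.integer(groups), seq_len(nlevels(groups)),
                    function(a, b) as.numeric(a == b))
    new("WideResponse", Y = Y, design = design, groups = groups,
        subjects = subj$subject, p = p, m = m)
}

#' Fit the doubly multivariate linear model
#'
#' Computes \eqn{\hat B = (X'X)^- X' Y} with a Moore-Penrose generalized
#' inverse; with an indicator design the rows of \eqn{\hat B} are the
#' per-group means of the wide response.
#'
#' @param response a \linkS4class{WideResponse}.
#' @return g x (p*m) matrix of estimated parameters (rows = groups).
#' @export
fitDmm <- function(response) {
    stopifnot(is(response, "WideResponse"))
    X <- response@design
    B <- .pinv(crossprod(X)) %*% crossprod(X, response@Y)
    rownames(B) <- levels(response@groups)
    B
}

# core SSCP computation on the reduced response Y_T = Y (T x I_p):
#   S_e = Y_T' (I - X (X'X)^- X') Y_T          error df = n - rank(X)
#   S_h = (G'B_T)' [G'(X'X)^- G]^{-1} (G'B_T)  with B_T = Bhat (T x I_p)
.dmm_sscp_core <- function(Y, design, G, Tm, p) {
    q <- ncol(Tm)
    YT <- Y %*% (Tm %x% diag(p))
    XtX <- crossprod(design)
    XtXi <- .pinv(XtX)
    BT <- XtXi %*% crossprod(design, YT)
    E <- YT - design %*% BT
    Se <- crossprod(E)
    GB <- crossprod(G, BT)
    mid <- crossprod(G, XtXi %*% G)
    midi <- tryCatch(solve(mid), error = function(e)
        stop("contrast-rank error: G'(X'X)^-G is singular"))
    Sh <- crossprod(GB, midi %*% GB)
    list(Sh = .symmetrize(Sh), Se = .symmetrize(Se),
         dfe = nrow(Y) - qr(design)$rank, q = q, s = ncol(G))
}

#' Hypothesis and error SSCP matrices for the DMM
#'
#' On the reduced response \eqn{Y_T = Y(T \otimes I_p)}: the error matrix is
#' the residual SSCP about the group-mean fit with error df = n - rank(X);
#' the hypothesis matrix is the usual general-linear-hypothesis form
#' \eqn{(G'\hat B_T)'[G'(X'X)^-G]^{-1}(G'\hat B_T)}.  Both are symmetric
#' positive semidefinite of order p*q.
#'
#' @param response a \linkS4class{WideResponse}.
#' @param contrasts a \linkS4class{ContrastPair}.
#' @return list with elements \code{Sh}, \code{Se}, \code{dfe}.
#' @export
dmmSscp <- function(response, contrasts) {
    stopifnot(is(response, "WideResponse"), is(contrasts, "ContrastPair"))
    p <- response@p
    q <- ncol(contrasts@T)
    n <- nrow(response@Y)
    out <- .dmm_sscp_core(response@Y, response@design, contrasts@G,
                          contrasts@T, p)
    if (out$dfe < p * q)
        stop("singularity error: S_e is singular; the DMM needs n > p*q ",
             "(here n = ", n, ", p*q = ", p * q, ")")
    out[c("Sh", "Se", "dfe")]
}

#' Classical MANOVA statistics from SSCP matrices
#'
#' From the eigenvalues \eqn{\lambda_l} of \eqn{S_h S_e^{-1}} (computed via
#' the symmetric form \eqn{S_e^{-1/2} S_h S_e^{-1/2}}; round-off negatives
#' clipped at zero): Wilks \eqn{W = \prod 1/(1+\lambda_l)},
#' Lawley-Hotelling \eqn{LH = \sum \lambda_l},
#' Pillai \eqn{P = \sum \lambda_l/(1+\lambda_l)}, Roy \eqn{R = \max
#' \lambda_l}.
#'
#' @param Sh,Se symmetric SSCP matrices; Se must be positive definite.
#' @return named numeric vector with elements W, LH, P, R.
#' @export
manovaStatistics <- function(Sh, Se) {
    U <- tryCatch(chol(.symmetrize(Se)), error = function(e)
        stop("singularity error: S_e is not positive definite"))
    Ui <- backsolve(U, diag(nrow(U)))
    M <- .symmetrize(crossprod(Ui, Sh %*% Ui))
    lam <- pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0)
    c(W = prod(1 / (1 + lam)), LH = sum(lam),
      P = sum(lam / (1 + lam)), R = max(lam))
}

#' F-approximations for the MANOVA statistics
#'
#' Wilks' lambda uses Rao's F-approximation (exact in the standard small
#' cases); Pillai's and the Lawley-Hotelling traces use their usual
#' approximations, and Roy's maximum root the standard upper-bound F.
#'
#' @param statistic "W", "LH", "P" or "R".
#' @param value the statistic value.
#' @param d dimension of the (reduced) response.
#' @param s hypothesis degrees of freedom (rank of G, times q for the MMM).
#' @param ve error degrees of freedom.
#' @return list with elements \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
fApproximation <- function(statistic = c("W", "LH", "P", "R"), value, d, s,
                           ve) {
    statistic <- match.arg(statistic)
    if (d < 1 || s < 1 || ve < 1)
        stop("invalid configuration: nonpositive degrees of freedom")
    smin <- min(d, s)
    mm <- (abs(d - s) - 1) / 2
    nn <- (ve - d - 1) / 2
    out <- switch(statistic,
        W = {
            tt <- if (d^2 + s^2 - 5 > 0)
                sqrt((d^2 * s^2 - 4) / (d^2 + s^2 - 5)) else 1
            r <- ve - (d - s + 1) / 2
            u <- (d * s - 2) / 4
            df1 <- d * s
            df2 <- r * tt - 2 * u
            L <- value^(1 / tt)
            list(F = (1 - L) / L * df2 / df1, df1 = df1, df2 = df2)
        },
        P = {
            df1 <- smin * (2 * mm + smin + 1)
            df2 <- smin * (2 * nn + smin + 1)
            list(F = (2 * nn + smin + 1) / (2 * mm + smin + 1) *
                     value / (smin - value), df1 = df1, df2 = df2)
        },
        LH = {
            df1 <- smin * (2 * mm + smin + 1)
            df2 <- 2 * (smin * nn + 1)
            list(F = df2 * value / (smin * df1), df1 = df1, df2 = df2)
        },
        R = {
            r <- max(d, s)
            df1 <- r
            df2 <- ve - r + s
            list(F = value * df2 / df1, df1 = df1, df2 = df2)
        })
    if (is.na(out$df2) || out$df2 <= 0)
        stop("invalid configuration: nonpositive denominator df")
    out$p <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
    out
}

#' Doubly multivariate test of a two-way repeated-measures hypothesis
#'
#' Composes the contrast construction, the reduced-model SSCP matrices, the
#' MANOVA statistic and its F-approximation.  Requires n > p*m so that the
#' full error SSCP is nonsingular.
#'
#' @param response a \linkS4class{WideResponse} or
#'   \linkS4class{CoefficientSet}.
#' @param hypothesis "interaction", "group" or "treatment".
#' @param statistic "W" (default), "LH", "P" or "R".
#' @return a \linkS4class{TestResult}.
#' @export
dmmTest <- function(response, hypothesis = c("interaction", "group",
                                             "treatment"),
                    statistic = c("W", "LH", "P", "R")) {
    hypothesis <- match.arg(hypothesis)
    statistic <- match.arg(statistic)
    if (is(response, "CoefficientSet")) response <- wideResponse(response)
    stopifnot(is(response, "WideResponse"))
    n <- nrow(response@Y); p <- response@p; m <- response@m
    if (n <= p * m)
        stop("dimension error: the DMM can only be used when n > p*m ",
             "(here n = ", n, ", p*m = ", p * m,
             "); consider the MMM instead")
    g <- nlevels(response@groups)
    cp <- buildContrasts(m, g, hypothesis)
    ss <- dmmSscp(response, cp)
    if (.degenerate_sscp(ss$Sh, ss$Se, response@Y))
        return(.null_extreme_result("dmm", hypothesis, statistic, ss))
    stats <- manovaStatistics(ss$Sh, ss$Se)
    fa <- fApproximation(statistic, stats[[statistic]],
                         d = p * ncol(cp@T), s = ncol(cp@G), ve = ss$dfe)
    new("TestResult", method = "dmm", hypothesis = hypothesis,
        statistic = statistic, value = unname(stats[[statistic]]),
        F = fa$F, df1 = fa$df1, df2 = fa$df2, pValue = fa$p,
        Sh = ss$Sh, Se = ss$Se,
        details = list(allStatistics = stats, dfe = ss$dfe))
}

# both SSCPs at round-off zero relative to the data (e.g. identical
# treatment blocks): the 0/0 statistic is reported at its null extreme
.degenerate_sscp <- function(Sh, Se, Y) {
    tol <- 1e-12 * max(sum(Y^2), 1)
    sum(abs(Se)) <= tol && sum(abs(Sh)) <= tol
}

.null_extreme_result <- function(method, hypothesis, statistic, ss) {
    new("TestResult", method = method, hypothesis = hypothesis,
        statistic = statistic,
        value = if (statistic == "W") 1 else 0,
        F = 0, df1 = NA_real_, df2 = NA_real_, pValue = 1,
        Sh = ss$Sh, Se = ss$Se,
        details = list(degenerate = TRUE, dfe = ss$dfe))
}

setMethod("show", "TestResult", function(object) {
    cat(sprintf("%s %s test (%s): statistic = %.6g", toupper(object@method),
                object@hypothesis, object@statistic, object@value))
    if (!is.na(object@F))
        cat(sprintf(", F(%.3g, %.3g) = %.4g", object@df1, object@df2,
                    object@F))
    cat(sprintf(", p = %.4g\n", object@pValue))
})

setMethod("show", "WideResponse", function(object) {
    cat(sprintf("WideResponse: n = %d subjects x (p = %d) * (m = %d) | g = %d groups\n",
                nrow(object@Y), object@p, object@m,
                nlevels(object@groups)))
})
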