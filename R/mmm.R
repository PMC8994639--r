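#' Rearrange the wide response for the Mixed Multivariate Model
#'
#' Each subject's pm-vector \eqn{y_i} becomes an m x p block \eqn{Y_i^*}
#' with \eqn{vec((Y_i^*)') = y_i} (rows = treatments, columns = basis
#' coefficients); the blocks are stacked subject-major into the
#' (n*m) x p matrix \eqn{Y^*}.  The operation is exactly invertible.
#'
#' @param response a \linkS4class{WideResponse} or
#'   \linkS4class{CoefficientSet}.
#' @return a \linkS4class{StackedResponse}.
#' @export
rearrangeForMmm <- function(response) {
    if (is(response, "CoefficientSet")) response <- wideResponse(response)
    stopifnot(is(response, "WideResponse"))
    p <- response@p; m <- response@m
    n <- nrow(response@Y)
    Ystar <- matrix(0, n * m, p)
    for (i in seq_len(n))
        Ystar[(i - 1L) * m + seq_len(m), ] <-
            t(matrix(response@Y[i, ], p, m))
    new("StackedResponse", Ystar = Ystar, design = response@design,
        groups = response@groups, subjects = response@subjects,
        p = p, m = m)
}

#' Invert the MMM rearrangement
#'
#' @param stacked a \linkS4class{StackedResponse}.
#' @return a \linkS4class{WideResponse}.
#' @export
wideFromStacked <- function(stacked) {
    stopifnot(is(stacked, "StackedResponse"))
    p <- stacked@p; m <- stacked@m
    n <- nrow(stacked@design)
    Y <- matrix(0, n, p * m)
    for (i in seq_len(n))
        Y[i, ] <- as.vector(t(stacked@Ystar[(i - 1L) * m + seq_len(m), ,
                                            drop = FALSE]))
    new("WideResponse", Y = Y, design = stacked@design,
        groups = stacked@groups, subjects = stacked@subjects, p = p, m = m)
}

# p x p SSCP matrices of the MMM.  Uses the exact identity that
# S_e* = Y*'[(I_n - P_X) x TT']Y* and S_h* = Y*' Upsilon Y* equal the sums
# of the q diagonal p x p blocks of the corresponding reduced-model DMM
# SSCP matrices (checked against the literal Kronecker formulas in the
# test suite).
.mmm_sscp_core <- function(Y, design, G, Tm, p) {
    out <- .dmm_sscp_core(Y, design, G, Tm, p)
    q <- out$q
    sum_blocks <- function(S) {
        acc <- matrix(0, p, p)
        for (a in seq_len(q)) {
            idx <- (a - 1L) * p + seq_len(p)
            acc <- acc + S[idx, idx]
        }
        acc
    }
    list(Sh = sum_blocks(out$Sh), Se = sum_blocks(out$Se),
         dfe = out$q * out$dfe, q = q, s = out$s, dmm = out)
}

#' Hypothesis and error SSCP matrices for the MMM
#'
#' Computes \eqn{S_e^* = Y^{*'}[(I_n - X(X'X)^-X') \otimes TT']Y^*} and
#' \eqn{S_h^* = Y^{*'} \Upsilon Y^*} with
#' \eqn{\Upsilon = (X(X'X)^-G[G'(X'X)^-G]^{-1}G'(X'X)^-X') \otimes TT'};
#' both are p x p symmetric PSD and the error degrees of freedom are
#' q(n - rank(X)).
#'
#' @param stacked a \linkS4class{StackedResponse}.
#' @param contrasts a \linkS4class{ContrastPair}.
#' @return list with elements \code{Sh}, \code{Se}, \code{dfe}.
#' @export
mmmSscp <- function(stacked, contrasts) {
    stopifnot(is(stacked, "StackedResponse"), is(contrasts, "ContrastPair"))
    wide <- wideFromStacked(stacked)
    n <- nrow(wide@Y)
    if (n * stacked@m <= stacked@p)
        stop("dimension error: the MMM can only be used when n*m > p ",
             "(here n*m = ", n * stacked@m, ", p = ", stacked@p, ")")
    out <- .mmm_sscp_core(wide@Y, wide@design, contrasts@G, contrasts@T,
                          stacked@p)
    out[c("Sh", "Se", "dfe")]
}

#' Mixed multivariate test of a two-way repeated-measures hypothesis
#'
#' MANOVA statistics on \eqn{(S_h^*, S_e^*)} with hypothesis degrees of
#' freedom s*q and error degrees of freedom q(n - rank(X)).  Validity
#' assumes multivariate sphericity of the contrast-reduced covariance; see
#' \code{\link{sphericityTest}} and \code{\link{adjustedMmmTest}}.
#'
#' @param stacked a \linkS4class{StackedResponse},
#'   \linkS4class{WideResponse} or \linkS4class{CoefficientSet}.
#' @param hypothesis "interaction", "group" or "treatment".
#' @param statistic "W" (default), "LH", "P" or "R".
#' @return a \linkS4class{TestResult}.
#' @export
mmmTest <- function(stacked, hypothesis = c("interaction", "group",
                                            "treatment"),
                    statistic = c("W", "LH", "P", "R")) {
    hypothesis <- match.arg(hypothesis)
    statistic <- match.arg(statistic)
    if (!is(stacked, "StackedResponse")) stacked <- rearrangeForMmm(stacked)
    g <- nlevels(stacked@groups)
    cp <- buildContrasts(stacked@m, g, hypothesis)
    ss <- mmmSscp(stacked, cp)
    if (.degenerate_sscp(ss$Sh, ss$Se, stacked@Ystar))
        return(.null_extreme_result("mmm", hypothesis, statistic, ss))
    stats <- manovaStatistics(ss$Sh, ss$Se)
    fa <- fApproximation(statistic, stats[[statistic]], d = stacked@p,
                         s = ncol(cp@G) * ncol(cp@T), ve = ss$dfe)
    new("TestResult", method = "mmm", hypothesis = hypothesis,
        statistic = statistic, value = unname(stats[[statistic]]),
        F = fa$F, df1 = fa$df1, df2 = fa$df2, pValue = fa$p,
        Sh = ss$Sh, Se = ss$Se,
        details = list(allStatistics = stats, dfe = ss$dfe))
}

# Omega-hat: covariance (divisor n - rank(X), unbiased) of the
# contrast-reduced per-subject responses after removing group means
.omega_hat <- function(wide, Tm) {
    out <- .dmm_sscp_core(wide@Y, wide@design,
                          diag(nlevels(wide@groups)), Tm, wide@p)
    list(Omega = out$Se / out$dfe, dfe = out$dfe, q = ncol(Tm))
}

.avg_diag_block <- function(Omega, p, q) {
    acc <- matrix(0, p, p)
    for (a in seq_len(q)) {
        idx <- (a - 1L) * p + seq_len(p)
        acc <- acc + Omega[idx, idx]
    }
    acc / q
}

#' Likelihood-ratio test of multivariate sphericity
#'
#' Estimates the covariance \eqn{\hat\Omega} of the contrast-reduced
#' per-subject responses (rows of \eqn{Y(T \otimes I_p)} residualized about
#' the group means, divisor \eqn{\nu = n - rank(X)}), the common block
#' \eqn{\hat\Gamma} as the average of the q diagonal p x p blocks, and the
#' Gaussian LRT statistic \eqn{\nu (q \ln|\hat\Gamma| - \ln|\hat\Omega|)},
#' referred to a chi-squared law with qp(qp+1)/2 - p(p+1)/2 degrees of
#' freedom.
#'
#' @param stacked a \linkS4class{StackedResponse} (or coercible).
#' @param contrasts a \linkS4class{ContrastPair} supplying T.
#' @return a \linkS4class{SphericityResult}.
#' @export
sphericityTest <- function(stacked, contrasts) {
    if (!is(stacked, "StackedResponse")) stacked <- rearrangeForMmm(stacked)
    stopifnot(is(contrasts, "ContrastPair"))
    wide <- wideFromStacked(stacked)
    p <- stacked@p
    oh <- .omega_hat(wide, contrasts@T)
    q <- oh$q
    df <- q * p * (q * p + 1) / 2 - p * (p + 1) / 2
    Gamma <- .avg_diag_block(oh$Omega, p, q)
    if (q == 1L)
        return(new("SphericityResult", statistic = 0, df = 0, pValue = 1,
                   Gamma = Gamma, Omega = oh$Omega))
    ldO <- .logdet(oh$Omega)
    ldG <- .logdet(Gamma)
    if (is.na(ldO) || is.na(ldG))
        stop("singularity error: Omega-hat is singular ",
             "(need residual df > q*p, here df = ", oh$dfe, ")")
    stat <- max(oh$dfe * (q * ldG - ldO), 0)
    new("SphericityResult", statistic = stat, df = df,
        pValue = pchisq(stat, df, lower.tail = FALSE),
        Gamma = Gamma, Omega = oh$Omega)
}

#' Box-type multivariate epsilon from a reduced-response covariance
#'
#' Measures departure from multivariate sphericity
#' \eqn{\Omega = I_q \otimes \Gamma} through the block partial trace: with
#' \eqn{W_{ab} = tr(\hat\Gamma^{-1}\hat\Omega_{ab})/p} (a symmetric PSD
#' q x q matrix equal to \eqn{I_q} under exact sphericity),
#' \eqn{\hat\epsilon = tr(W)^2 / (q\, tr(W^2)) \in [1/q, 1]}, with
#' \eqn{\hat\epsilon = 1} exactly when \eqn{\hat\Omega = I_q \otimes
#' \Gamma}.
#'
#' @param Omega qp x qp covariance of the contrast-reduced response.
#' @param p block dimension.
#' @param q number of contrast directions.
#' @return epsilon in [1/q, 1].
#' @export
boxEpsilon <- function(Omega, p, q) {
    if (q == 1L) return(1)
    Gamma <- .avg_diag_block(Omega, p, q)
    Gi <- tryCatch(solve(Gamma), error = function(e)
        stop("singularity error: average diagonal block is singular"))
    W <- matrix(0, q, q)
    for (a in seq_len(q)) for (b in seq_len(q)) {
        blk <- Omega[(a - 1L) * p + seq_len(p),
                     (b - 1L) * p + seq_len(p), drop = FALSE]
        W[a, b] <- sum(diag(Gi %*% blk)) / p
    }
    W <- .symmetrize(W)
    eps <- sum(diag(W))^2 / (q * sum(W * W))
    min(max(eps, 1 / q), 1)
}

#' Sphericity-adjusted mixed multivariate test
#'
#' Runs the MMM test and multiplies both degrees of freedom of its
#' F-approximation by the Box-type epsilon estimated from the covariance of
#' the contrast-reduced response, compensating for sphericity violations.
#'
#' @inheritParams mmmTest
#' @return a \linkS4class{TestResult} with method "mmm_adjusted"; the
#'   epsilon used is in \code{details$epsilon}.
#' @export
adjustedMmmTest <- function(stacked, hypothesis = c("interaction", "group",
                                                    "treatment"),
                            statistic = c("W", "LH", "P", "R")) {
    hypothesis <- match.arg(hypothesis)
    statistic <- match.arg(statistic)
    if (!is(stacked, "StackedResponse")) stacked <- rearrangeForMmm(stacked)
    res <- mmmTest(stacked, hypothesis, statistic)
    g <- nlevels(stacked@groups)
    cp <- buildContrasts(stacked@m, g, hypothesis)
    wide <- wideFromStacked(stacked)
    oh <- .omega_hat(wide, cp@T)
    eps <- boxEpsilon(oh$Omega, stacked@p, oh$q)
    df1 <- res@df1 * eps
    df2 <- res@df2 * eps
    new("TestResult", method = "mmm_adjusted", hypothesis = hypothesis,
        statistic = statistic, value = res@value, F = res@F,
        df1 = df1, df2 = df2,
        pValue = pf(res@F, df1, df2, lower.tail = FALSE),
        Sh = res@Sh, Se = res@Se,
        details = c(res@details, list(epsilon = eps)))
}

setMethod("show", "StackedResponse", function(object) {
    cat(sprintf(
        "StackedResponse: (n = %d) * (m = %d) rows x p = %d | g = %d groups\n",
        nrow(object@design), object@m, object@p, nlevels(object@groups)))
})

setMethod("show", "SphericityResult", function(object) {
    cat(sprintf(
        "Multivariate sphericity LRT: statistic = %.6g, df = %g, p = %.4g\n",
        object@statistic, object@df, object@pValue))
})
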