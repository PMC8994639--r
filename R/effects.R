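#' Estimate the two-way functional ANOVA effects from basis coefficients
#'
#' Implements the coefficient-mean estimators of the grand mean, treatment,
#' group and interaction effect functions under sum-to-zero identifiability
#' constraints:
#' \deqn{\hat\mu = \bar y_{\ldots},\quad
#'       \hat\alpha_i = \bar y_{i..} - \bar y_{\ldots},\quad
#'       \hat\beta_j = \bar y_{.j.} - \bar y_{\ldots},}
#' \deqn{\hat\theta_{ij} = \bar y_{ij.} - \bar y_{i..} - \bar y_{.j.} +
#'       \bar y_{\ldots},\quad
#'       \hat\epsilon_{ijk} = y_{ijk} - \bar y_{ij.},}
#' where group averaging uses weight 1/n_j within each group and 1/g across
#' groups (and 1/m across treatments), so with unequal group sizes the grand
#' mean is the unweighted average of per-group means.
#'
#' @param coeffs a \linkS4class{CoefficientSet}.
#' @return an \linkS4class{EffectEstimates}.
#' @export
estimateEffects <- function(coeffs) {
    stopifnot(is(coeffs, "CoefficientSet"))
    C <- coefMatrix(coeffs)
    d <- designLabels(coeffs)
    treatments <- sort(unique(d$treatment))
    groups <- sort(unique(d$group))
    m <- length(treatments); g <- length(groups); p <- nrow(C)
    if (any(table(d$group) == 0)) stop("invalid input: empty group")
    # cell means ybar_ij. : p x m x g
    cell <- array(0, dim = c(p, m, g),
                  dimnames = list(NULL, treatments, groups))
    for (i in seq_len(m)) for (j in seq_len(g)) {
        sel <- d$treatment == treatments[i] & d$group == groups[j]
        if (!any(sel)) stop("invalid input: empty cell (", treatments[i],
                            ", ", groups[j], ")")
        cell[, i, j] <- rowMeans(C[, sel, drop = FALSE])
    }
    ybar_i <- apply(cell, c(1, 2), mean)          # p x m, 1/g over groups
    ybar_j <- apply(cell, c(1, 3), mean)          # p x g, 1/m over treatments
    mu <- rowMeans(ybar_i)                        # p
    alpha <- ybar_i - mu
    beta <- ybar_j - mu
    theta <- cell
    for (i in seq_len(m)) for (j in seq_len(g))
        theta[, i, j] <- cell[, i, j] - ybar_i[, i] - ybar_j[, j] + mu
    resid <- C
    for (i in seq_len(m)) for (j in seq_len(g)) {
        sel <- d$treatment == treatments[i] & d$group == groups[j]
        resid[, sel] <- C[, sel, drop = FALSE] - cell[, i, j]
    }
    new("EffectEstimates", mu = mu,
        alpha = matrix(alpha, p, m, dimnames = list(NULL, treatments)),
        beta = matrix(beta, p, g, dimnames = list(NULL, groups)),
        theta = theta, residuals = resid, basis = coeffs@basis,
        treatments = treatments, groups = groups)
}

#' Verify the additive reconstruction of the coefficients
#'
#' Checks that \eqn{y_{ijk} = \hat\mu + \hat\alpha_i + \hat\beta_j +
#' \hat\theta_{ij} + \hat\epsilon_{ijk}} for every curve, to within
#' tolerance.
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @param coeffs the \linkS4class{CoefficientSet} they were estimated from.
#' @param tol absolute tolerance.
#' @return logical.
#' @export
decompositionCheck <- function(estimates, coeffs, tol = 1e-8) {
    C <- coefMatrix(coeffs)
    d <- designLabels(coeffs)
    i <- match(d$treatment, estimates@treatments)
    j <- match(d$group, estimates@groups)
    if (anyNA(i) || anyNA(j) || nrow(C) != length(estimates@mu) ||
        ncol(C) != ncol(estimates@residuals))
        stop("invalid input: shapes do not match")
    recon <- estimates@mu +
        estimates@alpha[, i, drop = FALSE] +
        estimates@beta[, j, drop = FALSE] +
        vapply(seq_along(i), function(k) estimates@theta[, i[k], j[k]],
               numeric(length(estimates@mu))) +
        estimates@residuals
    max(abs(recon - C)) <= tol
}

#' Evaluate an estimated effect function on a grid
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @param effect one of "mu", "alpha", "beta", "theta".
#' @param points evaluation points.
#' @return matrix with one column per effect level (one column for "mu").
#' @export
evaluateEffects <- function(estimates, effect = c("mu", "alpha", "beta",
                                                  "theta"), points) {
    effect <- match.arg(effect)
    B <- evalBasis(estimates@basis, points)
    switch(effect,
        mu = B %*% cbind(estimates@mu),
        alpha = B %*% estimates@alpha,
        beta = B %*% estimates@beta,
        theta = {
            dm <- dim(estimates@theta)
            out <- B %*% matrix(estimates@theta, dm[1])
            colnames(out) <- as.vector(outer(estimates@treatments,
                                             estimates@groups, paste,
                                             sep = ":"))
            out
        })
}

#' Export effect estimates as a data frame (one row per basis coefficient)
#'
#' @param estimates an \linkS4class{EffectEstimates}.
#' @return data.frame with columns effect, level, h (coefficient index),
#'   value.
#' @export
effectsAsDataFrame <- function(estimates) {
    p <- length(estimates@mu)
    rows <- list(data.frame(effect = "mu", level = "", h = seq_len(p),
                            value = estimates@mu))
    for (i in seq_along(estimates@treatments))
        rows[[length(rows) + 1L]] <- data.frame(
            effect = "alpha", level = estimates@treatments[i],
            h = seq_len(p), value = estimates@alpha[, i])
    for (j in seq_along(estimates@groups))
        rows[[length(rows) + 1L]] <- data.frame(
            effect = "beta", level = estimates@groups[j],
            h = seq_len(p), value = estimates@beta[, j])
    for (i in seq_along(estimates@treatments))
        for (j in seq_along(estimates@groups))
            rows[[length(rows) + 1L]] <- data.frame(
                effect = "theta",
                level = paste(estimates@treatments[i],
                              estimates@groups[j], sep = ":"),
                h = seq_len(p), value = estimates@theta[, i, j])
    do.call(rbind, rows)
}

setMethod("show", "EffectEstimates", function(object) {
    cat(sprintf(
        "EffectEstimates: p = %d | m = %d treatments, g = %d groups, %d residual curves\n",
        length(object@mu), ncol(object@alpha), ncol(object@beta),
        ncol(object@residuals)))
})
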