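#' Fit basis coefficients to observed curves by least squares
#'
#' Each curve is projected independently onto the basis: the coefficient
#' vector minimizes the sum of squared deviations between the observed values
#' and \eqn{\Phi(t_r)' y} over the common grid.  The solve uses a QR
#' factorization of the basis matrix.
#'
#' @param curves a \linkS4class{CurveSet}.
#' @param basis a \linkS4class{BasisSystem}; the grid must lie inside its
#'   domain and contain at least p points.
#' @return a \linkS4class{CoefficientSet}.
#' @export
fitCoefficients <- function(curves, basis) {
    stopifnot(is(curves, "CurveSet"), is(basis, "BasisSystem"))
    t <- curveGrid(curves)
    if (length(t) < basis@p)
        stop("underdetermined fit: need at least p grid points (R >= p)")
    Phi <- evalBasis(basis, t)
    qrPhi <- qr(Phi)
    if (qrPhi$rank < basis@p)
        stop("rank-deficient basis matrix on this grid")
    C <- qr.coef(qrPhi, curveMatrix(curves))
    d <- designLabels(curves)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(coefficients = unname(C)),
        colData = S4Vectors::DataFrame(subject = d$subject, group = d$group,
                                       treatment = d$treatment))
    new("CoefficientSet", se, basis = basis)
}

#' Extract the coefficient matrix
#'
#' @param x a \linkS4class{CoefficientSet}.
#' @return p x N numeric matrix (one column per curve).
#' @export
coefMatrix <- function(x) SummarizedExperiment::assay(x, "coefficients")

#' @describeIn coefMatrix the basis the coefficients refer to.
#' @export
basisSystem <- function(x) x@basis

#' Evaluate fitted curves on arbitrary points
#'
#' Returns \eqn{\Phi(t)' y} for each coefficient vector.
#'
#' @param coeffs a \linkS4class{CoefficientSet}, or a numeric matrix/vector
#'   of coefficients (p x N) together with \code{basis}.
#' @param points evaluation points within the basis domain.
#' @param basis required when \code{coeffs} is a plain matrix.
#' @return length(points) x N matrix of curve values.
#' @export
evaluateCurves <- function(coeffs, points, basis = NULL) {
    if (is(coeffs, "CoefficientSet")) {
        basis <- coeffs@basis
        C <- coefMatrix(coeffs)
    } else {
        if (is.null(basis)) stop("basis required for plain coefficients")
        C <- as.matrix(coeffs)
    }
    evalBasis(basis, points) %*% C
}

#' Select the basis dimension by generalized cross-validation
#'
#' For each candidate dimension the per-curve GCV criterion
#' \eqn{(RSS/R) / (1 - p/R)^2} (trace of the least-squares hat matrix = p) is
#' averaged over all curves; the candidate with the smallest average is
#' returned, ties broken by the smaller dimension.
#'
#' @param curves a \linkS4class{CurveSet}.
#' @param candidates integer vector of candidate dimensions (all <= number
#'   of grid points).
#' @param order spline order.
#' @param family basis family.
#' @return the selected dimension (integer).
#' @export
gcvDimension <- function(curves, candidates, order = 4L, family = "bspline") {
    if (length(candidates) == 0)
        stop("invalid configuration: empty candidate list")
    t <- curveGrid(curves)
    R <- length(t)
    if (any(candidates > R))
        stop("invalid configuration: candidates must satisfy R >= p")
    X <- curveMatrix(curves)
    dom <- range(t)
    score <- vapply(candidates, function(p) {
        basis <- if (family == "bspline")
            makeBsplineBasis(dom, p, order) else makeFourierBasis(dom, p)
        Phi <- evalBasis(basis, t)
        qrPhi <- qr(Phi)
        res <- qr.resid(qrPhi, X)
        rss <- colSums(res^2)
        mean((rss / R) / (1 - p / R)^2)
    }, numeric(1))
    ord <- order(score, candidates)
    as.integer(candidates[ord[1]])
}
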