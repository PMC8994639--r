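#' Create a B-spline basis with equally spaced knots
#'
#' Builds a basis of \code{p} B-spline functions of the given order on the
#' domain, with equally spaced interior knots and boundary knots repeated to
#' multiplicity equal to the order.  The number of breakpoints (including the
#' two boundaries) is \code{p - order + 2}, so e.g. 27 cubic functions on
#' [0, 2.56] correspond to 25 equally spaced knots.  B-spline bases form a
#' partition of unity on the domain.
#'
#' @param domain numeric length-2 interval.
#' @param p number of basis functions.
#' @param order spline order (4 = cubic splines, the default).
#' @return a \linkS4class{BasisSystem}.
#' @examples
#' bb <- makeBsplineBasis(c(0, 1), p = 14)
#' rowSums(evalBasis(bb, seq(0, 1, 0.1)))  # all 1
#' @export
makeBsplineBasis <- function(domain, p, order = 4L) {
    p <- as.integer(p); order <- as.integer(order)
    if (length(domain) != 2L || diff(domain) <= 0)
        stop("invalid configuration: domain must be a non-degenerate interval")
    if (order < 1L || p < order)
        stop("invalid configuration: need p >= order >= 1")
    breaks <- seq(domain[1], domain[2], length.out = p - order + 2L)
    knots <- c(rep(domain[1], order - 1L), breaks, rep(domain[2], order - 1L))
    new("BasisSystem", family = "bspline", p = p, order = order,
        knots = knots, domain = as.numeric(domain))
}

#' Create a Fourier basis (minimal alternative)
#'
#' Constant function plus sine/cosine pairs on the domain, truncated to
#' \code{p} functions.
#'
#' @inheritParams makeBsplineBasis
#' @return a \linkS4class{BasisSystem}.
#' @export
makeFourierBasis <- function(domain, p) {
    p <- as.integer(p)
    if (length(domain) != 2L || diff(domain) <= 0)
        stop("invalid configuration: domain must be a non-degenerate interval")
    if (p < 1L) stop("invalid configuration: p must be >= 1")
    new("BasisSystem", family = "fourier", p = p, order = 1L,
        knots = numeric(0), domain = as.numeric(domain))
}

#' Evaluate the basis functions on a set of points
#'
#' @param basis a \linkS4class{BasisSystem}.
#' @param points numeric vector within the basis domain.
#' @return length(points) x p matrix \eqn{\Phi(t)}.
#' @export
evalBasis <- function(basis, points) {
    stopifnot(is(basis, "BasisSystem"))
    if (any(points < basis@domain[1] - 1e-12) ||
        any(points > basis@domain[2] + 1e-12))
        stop("domain error: evaluation points outside the basis domain")
    points <- pmin(pmax(points, basis@domain[1]), basis@domain[2])
    if (basis@family == "bspline") {
        splines::splineDesign(basis@knots, points, ord = basis@order)
    } else {
        L <- diff(basis@domain)
        om <- 2 * pi / L
        B <- matrix(0, length(points), basis@p)
        B[, 1] <- 1
        h <- 1L
        k <- 2L
        while (k <= basis@p) {
            B[, k] <- sin(h * om * (points - basis@domain[1]))
            if (k + 1L <= basis@p)
                B[, k + 1L] <- cos(h * om * (points - basis@domain[1]))
            k <- k + 2L; h <- h + 1L
        }
        B
    }
}

#' Serialize a basis to JSON
#'
#' @param basis a \linkS4class{BasisSystem}.
#' @param path file path.
#' @export
writeBasisJSON <- function(basis, path) {
    jsonlite::write_json(
        list(family = basis@family, p = basis@p, order = basis@order,
             knots = basis@knots, domain = basis@domain),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a basis from JSON
#'
#' @param path file path written by \code{\link{writeBasisJSON}}.
#' @return a \linkS4class{BasisSystem}.
#' @export
readBasisJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("BasisSystem", family = x$family, p = as.integer(x$p),
        order = as.integer(x$order), knots = as.numeric(x$knots),
        domain = as.numeric(x$domain))
}

setMethod("show", "BasisSystem", function(object) {
    cat(sprintf("BasisSystem: %s, p = %d, order = %d, domain [%g, %g]\n",
                object@family, object@p, object@order,
                object@domain[1], object@domain[2]))
})
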