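#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pf pchisq rnorm runif setNames var
#' @importFrom utils read.csv write.csv
NULL

#' BasisSystem: a finite basis of the functional space
#'
#' Describes the basis \eqn{\Phi(t) = (\phi_1(t), \ldots, \phi_p(t))'} onto
#' which discretely observed curves are projected.  B-spline bases use equally
#' spaced interior knots with boundary knots repeated to multiplicity equal to
#' the spline order; a minimal Fourier alternative is provided.
#'
#' @slot family character, "bspline" or "fourier".
#' @slot p integer, number of basis functions.
#' @slot order integer, spline order (4 = cubic); ignored for Fourier.
#' @slot knots numeric, full knot vector (B-splines only).
#' @slot domain numeric length-2, domain endpoints.
#' @export
setClass("BasisSystem",
    representation(family = "character", p = "integer", order = "integer",
                   knots = "numeric", domain = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!object@family %in% c("bspline", "fourier"))
            msg <- c(msg, "family must be 'bspline' or 'fourier'")
        if (length(object@domain) != 2L || diff(object@domain) <= 0)
            msg <- c(msg, "domain must be a non-degenerate interval")
        if (object@p < 1L) msg <- c(msg, "p must be >= 1")
        if (object@family == "bspline") {
            if (object@p < object@order)
                msg <- c(msg, "p must be >= spline order")
            if (is.unsorted(object@knots))
                msg <- c(msg, "knots must be non-decreasing")
        }
        if (is.null(msg)) TRUE else msg
    })

#' CurveSet: discretely observed curves under a repeated-measures design
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"values"}
#' holds one column per sample curve (rows = points of the common grid).
#' \code{colData} carries the \code{subject}, \code{group} and
#' \code{treatment} labels; \code{rowData} column \code{t} holds the grid.
#' Every subject must appear under all treatments (balanced repeated
#' measures) and belong to exactly one group.
#'
#' @export
setClass("CurveSet", contains = "SummarizedExperiment")

#' CoefficientSet: per-curve basis coefficients
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"coefficients"}
#' (\eqn{p \times N}; one column per curve, same colData layout as the
#' \linkS4class{CurveSet} it was fitted from) plus the
#' \linkS4class{BasisSystem} used.
#'
#' @slot basis the BasisSystem the coefficients refer to.
#' @export
setClass("CoefficientSet", contains = "SummarizedExperiment",
    representation(basis = "BasisSystem"))

#' EffectEstimates: estimated two-way functional ANOVA parameters
#'
#' Coefficient-vector representations of the grand mean, treatment main
#' effects, group main effects, interaction effects and per-curve residuals,
#' all with respect to one basis.  Under the sum-to-zero identifiability
#' constraints the effects satisfy \eqn{\sum_i \hat\alpha_i = 0},
#' \eqn{\sum_j \hat\beta_j = 0} and row/column sums of \eqn{\hat\theta_{ij}}
#' vanish, and
#' \eqn{y_{ijk} = \hat\mu + \hat\alpha_i + \hat\beta_j + \hat\theta_{ij} +
#' \hat\epsilon_{ijk}} exactly.
#'
#' @slot mu numeric p-vector.
#' @slot alpha p x m matrix (columns = treatments).
#' @slot beta p x g matrix (columns = groups).
#' @slot theta p x m x g array.
#' @slot residuals p x N matrix, one column per curve.
#' @slot basis the BasisSystem.
#' @slot treatments,groups character labels.
#' @export
setClass("EffectEstimates",
    representation(mu = "numeric", alpha = "matrix", beta = "matrix",
                   theta = "array", residuals = "matrix",
                   basis = "BasisSystem",
                   treatments = "character", groups = "character"))

#' WideResponse: subject-by-(p*m) response for the Doubly Multivariate Model
#'
#' One row per subject; within a row the p-dimensional coefficient vectors
#' are stacked treatment-major (coefficients vary fastest).  The design
#' matrix is the n x g group-membership indicator.
#'
#' @slot Y n x (p*m) numeric matrix.
#' @slot design n x g indicator matrix.
#' @slot groups factor of length n.
#' @slot subjects character subject labels (row order of Y).
#' @slot p,m integer dimensions.
#' @export
setClass("WideResponse",
    representation(Y = "matrix", design = "matrix", groups = "factor",
                   subjects = "character", p = "integer", m = "integer"),
    validity = function(object) {
        msg <- NULL
        n <- nrow(object@Y)
        if (ncol(object@Y) != object@p * object@m)
            msg <- c(msg, "Y must have p*m columns")
        if (nrow(object@design) != n)
            msg <- c(msg, "design must have one row per subject")
        if (!all(rowSums(object@design) == 1))
            msg <- c(msg, "each design row must contain exactly one 1")
        if (is.null(msg)) TRUE else msg
    })

#' StackedResponse: (n*m) x p response for the Mixed Multivariate Model
#'
#' Per-subject m x p blocks \eqn{Y_i^*} satisfying
#' \eqn{vec((Y_i^*)') = y_i}, the i-th row of the wide response.
#'
#' @slot Ystar (n*m) x p numeric matrix, subject-major blocks of m rows.
#' @slot design n x g indicator matrix (one row per subject).
#' @slot groups factor of length n.
#' @slot subjects character subject labels (block order).
#' @slot p,m integer dimensions.
#' @export
setClass("StackedResponse",
    representation(Ystar = "matrix", design = "matrix", groups = "factor",
                   subjects = "character", p = "integer", m = "integer"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@Ystar) != nrow(object@design) * object@m)
            msg <- c(msg, "Ystar must have n*m rows")
        if (ncol(object@Ystar) != object@p)
            msg <- c(msg, "Ystar must have p columns")
        if (is.null(msg)) TRUE else msg
    })

#' ContrastPair: between-group (G) and within-treatment (T) contrasts
#'
#' Encodes a general linear hypothesis \eqn{G' B (T \otimes I_p) = 0} for the
#' doubly multivariate model, equivalently
#' \eqn{(G' \otimes T') B^* = 0} for the mixed multivariate model.
#' T is required to be orthonormal (\eqn{T'T = I}).
#'
#' @slot G g x s matrix of between-group contrast coefficients.
#' @slot T m x q orthonormal matrix of within-treatment contrasts.
#' @slot hypothesis one of "interaction", "group", "treatment".
#' @export
setClass("ContrastPair",
    representation(G = "matrix", T = "matrix", hypothesis = "character"),
    validity = function(object) {
        msg <- NULL
        TT <- crossprod(object@T)
        if (max(abs(TT - diag(ncol(object@T)))) > 1e-8)
            msg <- c(msg, "T must be orthonormal (T'T = I)")
        if (qr(object@G)$rank < ncol(object@G))
            msg <- c(msg, "G must have full column rank")
        if (!object@hypothesis %in% c("interaction", "group", "treatment"))
            msg <- c(msg, "unknown hypothesis tag")
        if (is.null(msg)) TRUE else msg
    })

#' TestResult: outcome of one multivariate test
#'
#' @slot method "dmm", "mmm", "mmm_adjusted" or "permutation".
#' @slot hypothesis hypothesis tag.
#' @slot statistic statistic name ("W", "LH", "P" or "R").
#' @slot value statistic value.
#' @slot F approximating F value (NA for permutation tests).
#' @slot df1,df2 numerator/denominator degrees of freedom.
#' @slot pValue the p-value.
#' @slot Sh,Se hypothesis and error SSCP matrices (diagnostic).
#' @slot details list of method metadata (epsilon, permutation count, ...).
#' @export
setClass("TestResult",
    representation(method = "character", hypothesis = "character",
                   statistic = "character", value = "numeric",
                   F = "numeric", df1 = "numeric", df2 = "numeric",
                   pValue = "numeric", Sh = "matrix", Se = "matrix",
                   details = "list"),
    validity = function(object) {
        msg <- NULL
        if (!is.na(object@pValue) &&
            (object@pValue < 0 || object@pValue > 1))
            msg <- c(msg, "p-value must lie in [0, 1]")
        if (object@statistic == "W" && !is.na(object@value) &&
            (object@value <= 0 || object@value > 1 + 1e-12))
            msg <- c(msg, "Wilks lambda must lie in (0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' SphericityResult: likelihood-ratio test of multivariate sphericity
#'
#' Tests \eqn{H_0: \Omega = I_q \otimes \Gamma} for the covariance of the
#' contrast-reduced response.
#'
#' @slot statistic LRT statistic value.
#' @slot df chi-squared degrees of freedom, qp(qp+1)/2 - p(p+1)/2.
#' @slot pValue asymptotic p-value.
#' @slot Gamma estimated common p x p block.
#' @slot Omega estimated qp x qp covariance.
#' @export
setClass("SphericityResult",
    representation(statistic = "numeric", df = "numeric",
                   pValue = "numeric", Gamma = "matrix", Omega = "matrix"),
    validity = function(object) {
        if (!is.na(object@statistic) && object@statistic < -1e-8)
            "LRT statistic must be non-negative" else TRUE
    })

#' ScenarioSpec: configuration of a simulated two-way design
#'
#' The design is m = 3 treatments by g = 2 groups; treatment (A), group (B)
#' and interaction (I) effect-function variants follow the scenario families
#' M1-M4.  Errors are i.i.d. Gaussian with standard deviation
#' \code{sigmaEps} at each grid point, or a Brownian motion scaled by 1/20
#' whose increments have standard deviation \code{sigmaEps * sqrt(dt)}.
#' Each subject carries a random effect \eqn{\gamma_k \sin(\pi t)} with
#' \eqn{\gamma_k \sim N(\mu_k, \sigma_k)}, \eqn{\mu_k \sim U(0, 0.05)},
#' \eqn{\sigma_k = 0.2}, shared across that subject's m curves.
#'
#' @slot scenario "M1", "M2", "M3" or "M4".
#' @slot A,B,I variant tags ("A1".."A3", "B1".."B3", "I1"/"I2").
#' @slot sigmaEps error dispersion (standard deviation).
#' @slot n per-group sample size (n1 = n2 = n).
#' @slot grid argument grid (default 101 equispaced points on [0, 1]).
#' @slot errorModel "iid_gaussian" or "brownian".
#' @slot sigmaSubject SD of the subject effect gamma_k (0.2).
#' @slot muMax upper limit of the U(0, muMax) law of mu_k (0.05).
#' @slot seed integer seed.
#' @export
setClass("ScenarioSpec",
    representation(scenario = "character", A = "character", B = "character",
                   I = "character", sigmaEps = "numeric", n = "integer",
                   grid = "numeric", errorModel = "character",
                   sigmaSubject = "numeric", muMax = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (!object@scenario %in% c("M1", "M2", "M3", "M4"))
            msg <- c(msg, "scenario must be one of M1-M4")
        if (!object@errorModel %in% c("iid_gaussian", "brownian"))
            msg <- c(msg, "errorModel must be 'iid_gaussian' or 'brownian'")
        if (object@n < 1L) msg <- c(msg, "n must be >= 1")
        if (is.unsorted(object@grid, strictly = TRUE))
            msg <- c(msg, "grid must be strictly increasing")
        if (is.null(msg)) TRUE else msg
    })

#' PermutationPlan: settings of the repeated-measures permutation test
#'
#' @slot nPerm number of permutations F.
#' @slot seed integer seed fixing the permutation stream (NA = leave RNG).
#' @slot statistic statistic tag ("W", "LH", "P", "R").
#' @slot model "dmm" or "mmm".
#' @slot hypothesis hypothesis tag.
#' @slot addOne logical; use the (1 + sum)/(1 + F) p-value variant.
#' @export
setClass("PermutationPlan",
    representation(nPerm = "integer", seed = "integer",
                   statistic = "character", model = "character",
                   hypothesis = "character", addOne = "logical"),
    validity = function(object) {
        msg <- NULL
        if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
        if (!object@statistic %in% c("W", "LH", "P", "R"))
            msg <- c(msg, "statistic must be one of W, LH, P, R")
        if (!object@model %in% c("dmm", "mmm"))
            msg <- c(msg, "model must be 'dmm' or 'mmm'")
        if (is.null(msg)) TRUE else msg
    })
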