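#' Build the contrast matrices for a hypothesis
#'
#' Returns the between-group matrix G (g x s) and the orthonormal
#' within-treatment matrix T (m x q) encoding the general linear hypothesis
#' \eqn{G'B(T \otimes I_p) = 0}:
#' \itemize{
#'   \item interaction (parallelism): G = between-group contrast basis,
#'     T = orthonormal basis of treatment contrasts;
#'   \item group: the same G with T = I_m;
#'   \item treatment: G = I_g with the same contrast T.
#' }
#' For m = 3 the treatment contrast matrix is the one used throughout the
#' simulation study, with columns \eqn{(1/\sqrt2, 0, -1/\sqrt2)'} and
#' \eqn{(-1/\sqrt6, 2/\sqrt6, -1/\sqrt6)'}; for general m an orthonormalized
#' Helmert-type basis is used (all tests are invariant to this choice).
#' For g = 2, G = (1, -1)'; for general g Helmert contrasts.
#'
#' @param m number of treatments.
#' @param g number of groups.
#' @param hypothesis "interaction", "group" or "treatment".
#' @return a \linkS4class{ContrastPair}.
#' @export
buildContrasts <- function(m, g, hypothesis = c("interaction", "group",
                                                "treatment")) {
    if (!is.character(hypothesis) ||
        !hypothesis[1] %in% c("interaction", "group", "treatment"))
        stop("invalid configuration: unknown hypothesis tag")
    hypothesis <- match.arg(hypothesis)
    m <- as.integer(m); g <- as.integer(g)
    if (hypothesis %in% c("treatment", "interaction") && m < 2L)
        stop("invalid configuration: treatment/interaction tests need m >= 2")
    if (hypothesis %in% c("group", "interaction") && g < 2L)
        stop("invalid configuration: group/interaction tests need g >= 2")
    cp <- switch(hypothesis,
        interaction = list(G = .group_contrasts(g),
                           T = .treatment_contrasts(m)),
        group = list(G = .group_contrasts(g), T = diag(m)),
        treatment = list(G = diag(g), T = .treatment_contrasts(m)))
    new("ContrastPair", G = cp$G, T = cp$T, hypothesis = hypothesis)
}

# orthonormal treatment contrasts; the m = 3 matrix is pinned to the form
# used in the simulation study
.treatment_contrasts <- function(m) {
    if (m == 3L)
        return(cbind(c(1, 0, -1) / sqrt(2), c(-1, 2, -1) / sqrt(6)))
    H <- stats::contr.helmert(m)
    qr.Q(qr(H))
}

.group_contrasts <- function(g) {
    if (g == 2L) return(cbind(c(1, -1)))
    stats::contr.helmert(g)
}

setMethod("show", "ContrastPair", function(object) {
    cat(sprintf("ContrastPair (%s): G %d x %d, T %d x %d\n",
                object@hypothesis, nrow(object@G), ncol(object@G),
                nrow(object@T), ncol(object@T)))
})
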