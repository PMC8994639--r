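#' Construct a permutation plan
#'
#' @param nPerm number of permutations F (default 1000).
#' @param seed integer seed for the permutation stream (NA = do not touch
#'   the RNG state).
#' @param statistic "W", "LH", "P" or "R".
#' @param model base model for the statistic, "dmm" or "mmm".
#' @param hypothesis hypothesis tag.
#' @param addOne if TRUE use the guaranteed-positive (1 + sum)/(1 + F)
#'   p-value variant instead of the plain proportion (default FALSE).
#' @return a \linkS4class{PermutationPlan}.
#' @export
permutationPlan <- function(nPerm = 1000L, seed = NA_integer_,
                            statistic = "W", model = "mmm",
                            hypothesis = "treatment", addOne = FALSE) {
    new("PermutationPlan", nPerm = as.integer(nPerm),
        seed = as.integer(seed), statistic = statistic, model = model,
        hypothesis = hypothesis, addOne = addOne)
}

# one statistic value on a wide matrix; Wilks via log-determinants,
# the others via the symmetric eigenproblem
.test_statistic_core <- function(Y, design, G, Tm, p, model, statistic) {
    core <- if (model == "dmm")
        .dmm_sscp_core(Y, design, G, Tm, p)
    else .mmm_sscp_core(Y, design, G, Tm, p)
    # fully degenerate data (e.g. identical curves): both SSCPs vanish and
    # the 0/0 eigenproblem is taken at its null extreme
    tol <- 1e-12 * max(sum(Y^2), 1)
    if (sum(abs(core$Se)) <= tol && sum(abs(core$Sh)) <= tol)
        return(c(W = 1, LH = 0, P = 0, R = 0)[[statistic]])
    if (statistic == "W") {
        w <- exp(.logdet(core$Se) - .logdet(core$Se + core$Sh))
        if (!is.na(w)) return(min(w, 1))
    }
    manovaStatistics(core$Sh, core$Se)[[statistic]]
}

# apply a within-subject treatment reordering (n x m index matrix) and a
# subject reordering to the wide matrix
.permute_wide <- function(Y, p, m, treatmentOrder, subjectOrder) {
    n <- nrow(Y)
    Yp <- Y
    for (s in seq_len(n)) {
        ord <- treatmentOrder[s, ]
        if (!identical(ord, seq_len(m)))
            Yp[s, ] <- Y[s, as.vector(outer(seq_len(p), (ord - 1L) * p,
                                            "+"))]
    }
    Yp[subjectOrder, , drop = FALSE]
}

#' Randomly permute a repeated-measures dataset
#'
#' For each subject independently, the m treatment-labelled coefficient
#' vectors are reordered at random; when there is more than one group, all
#' subjects are then pooled and reassigned without replacement to groups of
#' the original sizes.
#'
#' @param coeffs a \linkS4class{CoefficientSet}.
#' @return a permuted \linkS4class{CoefficientSet}.
#' @export
permuteDataset <- function(coeffs) {
    stopifnot(is(coeffs, "CoefficientSet"))
    C <- coefMatrix(coeffs)
    d <- designLabels(coeffs)
    treatments <- sort(unique(d$treatment))
    m <- length(treatments)
    subj <- .subject_order(d$subject, d$group)
    n <- nrow(subj)
    for (s in subj$subject) {
        idx <- vapply(treatments, function(tr)
            which(d$subject == s & d$treatment == tr), integer(1))
        C[, idx] <- C[, idx[sample.int(m)], drop = FALSE]
    }
    newgroup <- subj$group
    if (length(unique(subj$group)) > 1L)
        newgroup <- subj$group[sample.int(n)]
    d$group <- newgroup[match(d$subject, subj$subject)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(coefficients = C),
        colData = S4Vectors::DataFrame(subject = d$subject,
                                       group = d$group,
                                       treatment = d$treatment))
    new("CoefficientSet", se, basis = coeffs@basis)
}

#' Repeated-measures permutation test
#'
#' Computes the test statistic \eqn{S_0} on the original data and on F
#' permuted datasets (within-subject treatment reordering followed, for
#' several groups, by random reassignment of subjects to groups of the
#' original sizes), and the p-value as the proportion of \eqn{S_f \le S_0}
#' for Wilks' lambda, respectively \eqn{S_f \ge S_0} for the
#' Lawley-Hotelling, Pillai and Roy statistics.
#'
#' @param coeffs a \linkS4class{CoefficientSet} or
#'   \linkS4class{WideResponse}.
#' @param plan a \linkS4class{PermutationPlan}.
#' @param permutations optional list of explicit permutations for exhaustive
#'   enumeration; each element is a list with \code{treatmentOrder} (n x m
#'   integer matrix, row s = new treatment order of subject s) and
#'   \code{subjectOrder} (permutation of 1:n).  When supplied it replaces
#'   the random stream and F = length(permutations).
#' @return a \linkS4class{TestResult} with method "permutation"; the
#'   permuted statistic values are in \code{details$permValues}.
#' @export
permutationTest <- function(coeffs, plan, permutations = NULL) {
    stopifnot(is(plan, "PermutationPlan"))
    wide <- if (is(coeffs, "WideResponse")) coeffs else wideResponse(coeffs)
    Y <- wide@Y; p <- wide@p; m <- wide@m
    n <- nrow(Y)
    g <- nlevels(wide@groups)
    if (plan@hypothesis == "group" && g < 2L)
        stop("invalid configuration: group test undefined for one group")
    cp <- buildContrasts(m, g, plan@hypothesis)
    statfun <- function(Ymat)
        .test_statistic_core(Ymat, wide@design, cp@G, cp@T, p,
                             plan@model, plan@statistic)
    S0 <- statfun(Y)
    if (!is.na(plan@seed)) set.seed(plan@seed)
    nF <- if (is.null(permutations)) plan@nPerm else length(permutations)
    Sf <- rep(NA_real_, nF)
    for (f in seq_len(nF)) {
        if (is.null(permutations)) {
            to <- t(vapply(seq_len(n), function(s) sample.int(m),
                           integer(m)))
            so <- if (g > 1L) sample.int(n) else seq_len(n)
        } else {
            to <- permutations[[f]]$treatmentOrder
            so <- permutations[[f]]$subjectOrder
        }
        Sf[f] <- tryCatch(statfun(.permute_wide(Y, p, m, to, so)),
                          error = function(e) NA_real_)
    }
    bad <- is.na(Sf)
    if (any(bad)) {
        warning("statistic failed on ", sum(bad),
                " permuted dataset(s); excluded from the p-value")
        Sf <- Sf[!bad]
    }
    hits <- if (plan@statistic == "W") sum(Sf <= S0) else sum(Sf >= S0)
    pv <- if (plan@addOne) (1 + hits) / (1 + length(Sf))
          else hits / length(Sf)
    new("TestResult", method = "permutation", hypothesis = plan@hypothesis,
        statistic = plan@statistic, value = S0, F = NA_real_,
        df1 = NA_real_, df2 = NA_real_, pValue = pv,
        Sh = matrix(NA_real_, 0, 0), Se = matrix(NA_real_, 0, 0),
        details = list(model = plan@model, nPerm = length(Sf),
                       permValues = Sf, addOne = plan@addOne))
}
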