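#' Construct a CurveSet
#'
#' @param values R x N numeric matrix of observed curve values (rows = grid
#'   points, one column per curve).
#' @param t strictly increasing grid of argument values (length R).
#' @param subject,group,treatment vectors of length N labelling each curve.
#' @return a \linkS4class{CurveSet}.
#' @examples
#' t <- seq(0, 1, length.out = 21)
#' vals <- sapply(1:4, function(i) sin(pi * t) + 0.1 * i)
#' cs <- CurveSet(vals, t, subject = rep(c("s1", "s2"), each = 2),
#'                group = "g1", treatment = rep(c("tr1", "tr2"), 2))
#' @export
CurveSet <- function(values, t, subject, group, treatment) {
    values <- as.matrix(values)
    N <- ncol(values)
    subject <- rep_len(as.character(subject), N)
    group <- rep_len(as.character(group), N)
    treatment <- rep_len(as.character(treatment), N)
    .check_design(subject, group, treatment)
    if (length(t) != nrow(values))
        stop("grid error: length(t) must equal nrow(values)")
    if (is.unsorted(t, strictly = TRUE))
        stop("grid error: grid must be strictly increasing")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = unname(values)),
        rowData = S4Vectors::DataFrame(t = as.numeric(t)),
        colData = S4Vectors::DataFrame(subject = subject, group = group,
                                       treatment = treatment))
    new("CurveSet", se)
}

# balance: every subject appears under all treatments exactly once and in
# exactly one group
.check_design <- function(subject, group, treatment) {
    tr <- unique(treatment)
    for (s in unique(subject)) {
        sel <- subject == s
        if (length(unique(group[sel])) != 1L)
            stop("balance error: subject ", s, " appears in several groups")
        tt <- treatment[sel]
        if (anyDuplicated(tt) || length(tt) != length(tr) ||
            !setequal(tt, tr))
            stop("balance error: subject ", s,
                 " does not appear under all treatments exactly once")
    }
    invisible(TRUE)
}

#' @describeIn CurveSet grid of argument values.
#' @param x a CurveSet or CoefficientSet.
#' @export
curveGrid <- function(x) SummarizedExperiment::rowData(x)$t

#' @describeIn CurveSet matrix of observed values (rows = grid points).
#' @export
curveMatrix <- function(x) SummarizedExperiment::assay(x, "values")

#' Design labels of a curve or coefficient set
#'
#' @param x a \linkS4class{CurveSet} or \linkS4class{CoefficientSet}.
#' @return data.frame with columns subject, group, treatment.
#' @export
designLabels <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(subject = cd$subject, group = cd$group,
               treatment = cd$treatment, stringsAsFactors = FALSE)
}

#' @describeIn designLabels number of subjects.
#' @export
nSubjects <- function(x) length(unique(designLabels(x)$subject))

#' @describeIn designLabels number of treatments m.
#' @export
nTreatments <- function(x) length(unique(designLabels(x)$treatment))

#' @describeIn designLabels number of groups g.
#' @export
nGroups <- function(x) length(unique(designLabels(x)$group))

#' @describeIn designLabels per-group subject counts n_j.
#' @export
groupSizes <- function(x) {
    d <- designLabels(x)
    first <- !duplicated(d$subject)
    table(d$group[first])
}

#' Read curves from a long-format CSV file
#'
#' Expects columns \code{subject}, \code{group}, \code{treatment}, \code{t},
#' \code{value}, one row per observed point.  Validates that all curves share
#' a common grid and that the design is balanced.
#'
#' @param path CSV file path.
#' @return a \linkS4class{CurveSet}.
#' @export
readCurves <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject", "group", "treatment", "t", "value")
    if (!all(need %in% names(df)))
        stop("input error: file must have columns ",
             paste(need, collapse = ", "))
    key <- paste(df$subject, df$treatment, sep = "\r")
    grids <- split(df$t, key)
    tref <- sort(unique(df$t))
    ok <- vapply(grids, function(tt)
        length(tt) == length(tref) && all(sort(tt) == tref), logical(1))
    if (!all(ok))
        stop("grid error: curves do not share a common grid")
    df <- df[order(df$group, df$subject, df$treatment, df$t), ]
    ucurve <- !duplicated(paste(df$subject, df$treatment, sep = "\r"))
    vals <- matrix(df$value, nrow = length(tref))
    CurveSet(vals, tref, subject = df$subject[ucurve],
             group = df$group[ucurve], treatment = df$treatment[ucurve])
}

#' Write curves to a long-format CSV file
#'
#' @param curves a \linkS4class{CurveSet}.
#' @param path CSV file path.
#' @export
writeCurves <- function(curves, path) {
    d <- designLabels(curves)
    t <- curveGrid(curves)
    V <- curveMatrix(curves)
    df <- data.frame(subject = rep(d$subject, each = length(t)),
                     group = rep(d$group, each = length(t)),
                     treatment = rep(d$treatment, each = length(t)),
                     t = rep(t, ncol(V)), value = as.vector(V))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

setMethod("show", "CurveSet", function(object) {
    d <- designLabels(object)
    cat(sprintf(
        "CurveSet: %d curves on %d grid points | n = %d subjects, m = %d treatments, g = %d groups\n",
        ncol(object), nrow(object), nSubjects(object),
        nTreatments(object), nGroups(object)))
})

setMethod("show", "CoefficientSet", function(object) {
    cat(sprintf(
        "CoefficientSet: p = %d coefficients x %d curves (%s basis) | n = %d, m = %d, g = %d\n",
        nrow(object), ncol(object), object@basis@family,
        nSubjects(object), nTreatments(object), nGroups(object)))
})
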