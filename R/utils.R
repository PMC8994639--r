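# internal numerical helpers

# Moore-Penrose pseudoinverse via SVD; tolerance scaled by machine epsilon
.pinv <- function(A, tol = NULL) {
    s <- svd(A)
    if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
    keep <- s$d > tol
    if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
    s$v[, keep, drop = FALSE] %*%
        (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# log-determinant of a symmetric positive-definite matrix; NA if chol fails
.logdet <- function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(NA_real_)
    2 * sum(log(diag(R)))
}

.symmetrize <- function(S) (S + t(S)) / 2

# stable subject order: order of first appearance, grouped by group label
.subject_order <- function(subject, group) {
    first <- !duplicated(subject)
    data.frame(subject = subject[first], group = group[first],
               stringsAsFactors = FALSE)
}
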