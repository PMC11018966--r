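# Pre-network preprocessing: per-gene ordinary-least-squares residualization
# against age and sex, and an optional variance-quantile gene filter.

#' Residualize expression against age and sex
#'
#' Each gene's profile is replaced by the residuals of an OLS fit on
#' (intercept, age, sex). Residuals have zero mean and are orthogonal to
#' both covariates. Samples missing covariates are dropped with a warning;
#' samples in the covariate table but absent from the expression matrix are
#' ignored.
#'
#' @param expr gene x sample numeric matrix with sample ids as colnames
#' @param cov data.frame with columns sample_id, age, sex
#' @return residual expression matrix (possibly fewer samples), same gene
#'   order
#' @export
residualize <- function(expr, cov) {
  .check_matrix(expr, "expression matrix")
  if (!all(c("sample_id", "age", "sex") %in% names(cov)))
    .stopf("covariate table needs columns sample_id, age, sex")
  if (anyDuplicated(cov$sample_id))
    .stopf("duplicate sample ids in covariate table")
  complete <- stats::complete.cases(cov[, c("age", "sex")])
  if (any(!complete)) {
    .warnf("dropping %d sample(s) with missing covariates: %s",
           sum(!complete),
           paste(utils::head(cov$sample_id[!complete], 5), collapse = ", "))
    cov <- cov[complete, , drop = FALSE]
  }
  missing <- setdiff(colnames(expr), cov$sample_id)
  if (length(missing))
    .stopf("expression sample(s) missing from covariate table: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  keep <- intersect(colnames(expr), cov$sample_id)
  expr <- expr[, keep, drop = FALSE]
  cov <- cov[match(keep, cov$sample_id), , drop = FALSE]

  x <- cbind(intercept = 1, age = cov$age, sex = as.numeric(cov$sex))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}

#' Filter genes by a variance quantile
#'
#' Removes genes whose sample variance falls below the given quantile of
#' all gene variances. Quantile 0 (the default elsewhere in the pipeline)
#' keeps every gene. Gene order is preserved.
#'
#' @param expr gene x sample matrix
#' @param min_variance_quantile quantile in [0, 1)
#' @return filtered expression matrix
#' @export
filter_genes <- function(expr, min_variance_quantile = 0) {
  .check_matrix(expr, "expression matrix")
  q <- min_variance_quantile
  if (!is.numeric(q) || q < 0 || q >= 1)
    .stopf("min_variance_quantile must lie in [0, 1)")
  v <- apply(expr, 1, stats::var)
  thr <- stats::quantile(v, q, names = FALSE)
  keep <- v >= thr
  if (!any(keep)) .stopf("variance filter removed every gene")
  expr[keep, , drop = FALSE]
}
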