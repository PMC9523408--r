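#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value
#'
#' Midranks handle ties. When both groups have at most 8 observations the
#' p-value is exact: all choose(n1+n2, n1) assignments of the pooled midranks
#' to the case group are enumerated and the fraction with a rank-sum statistic
#' at least as far from its null mean as observed is returned. For larger
#' groups the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param case_values,control_values Numeric vectors, each with >= 2 finite
#'   values.
#' @param exact_max Largest per-group size for which the exact enumeration is
#'   used (default 8).
#' @return Two-sided p-value in (0, 1]. Degenerate input (every value
#'   identical in both groups) returns 1.
#' @export
mann_whitney_p <- function(case_values, control_values, exact_max = 8L) {
  x <- case_values
  y <- control_values
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-max(0, z)))
  }
}

#' Call differentially expressed genes in one dataset
#'
#' Per gene, the log2 fold change is mean(case) - mean(control) on the
#' (already log2) matrix, and the p-value is the two-sided Mann-Whitney
#' rank-sum test. A gene is a DEG when |log2fc| > log2(fc_threshold) and
#' p < p_threshold; no multiple-testing correction is applied at this stage.
#'
#' @param dataset An [expression_dataset()] on the log2 scale.
#' @param fc_threshold Linear-scale fold-change gate (default 1.5, i.e.
#'   |log2fc| > log2(1.5) ~ 0.585).
#' @param p_threshold Raw p-value gate (default 0.05).
#' @return `data.frame` with columns `gene`, `log2fc`, `pvalue`, `is_deg`,
#'   one row per gene, in matrix row order. Genes whose test fails get an NA
#'   p-value (with a warning) and `is_deg = FALSE`.
#' @export
call_degs <- function(dataset, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  case_idx <- dataset$labels == "case"
  m <- dataset$matrix
  log2fc <- rowMeans(m[, case_idx, drop = FALSE]) -
    rowMeans(m[, !case_idx, drop = FALSE])
  pvals <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(mann_whitney_p(m[i, case_idx], m[i, !case_idx]),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(pvals))
  if (n_failed)
    warning(n_failed, " gene(s) with failed rank-sum test excluded from DEG set")
  is_deg <- !is.na(pvals) & abs(log2fc) > log2(fc_threshold) & pvals < p_threshold
  data.frame(gene = rownames(m), log2fc = unname(log2fc), pvalue = pvals,
             is_deg = is_deg, row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect per-dataset DEG sets into a disease DEG set
#'
#' A disease's DEG set is the exact intersection of the DEG sets of all its
#' datasets; input and output sizes are reported via `message()`.
#'
#' @param deg_lists List (>= 2) of character vectors of DEG symbols, or of
#'   [call_degs()] tables (the `is_deg` rows are used).
#' @param disease Label attached to the result.
#' @return List of class `DiseaseDegSet`: `disease`, `genes` (sorted
#'   character vector), `provenance` (input sizes). Empty intersection gives
#'   a warning and an empty gene set.
#' @export
intersect_deg_sets <- function(deg_lists, disease = "disease") {
  if (length(deg_lists) < 2L) stop("need at least 2 DEG sets")
  sets <- lapply(deg_lists, function(d) {
    if (is.data.frame(d)) d$gene[d$is_deg] else as.character(d)
  })
  common <- sort(Reduce(intersect, sets))
  sizes <- vapply(sets, length, integer(1))
  message(sprintf("[%s] DEG set sizes %s -> intersection %d",
                  disease, paste(sizes, collapse = "/"), length(common)))
  if (!length(common))
    warning("empty DEG intersection for ", disease)
  structure(list(disease = disease, genes = common, provenance = sizes),
            class = "DiseaseDegSet")
}
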