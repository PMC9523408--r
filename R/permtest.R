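#' Monte-Carlo permutation p-value
#'
#' p = (m + 1) / (n + 1), where n is the number of simulations and m counts
#' null values at least as extreme as the observed statistic (>= for the
#' upper tail, <= for the lower). Ties count toward m; the +1 terms include
#' the observed statistic in the reference distribution, so p is never 0.
#'
#' @param observed Observed scalar statistic.
#' @param null_values Numeric vector of simulated statistics (n >= 1, finite).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return p-value in [1/(n+1), 1].
#' @export
mc_pvalue <- function(observed, null_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!length(null_values)) stop("empty null vector")
  if (!is.finite(observed) || !all(is.finite(null_values)))
    stop("non-finite statistic values")
  m <- if (tail == "upper") sum(null_values >= observed)
       else sum(null_values <= observed)
  (m + 1) / (length(null_values) + 1)
}

#' Permutation null for a two-gene-set statistic
#'
#' Each replicate draws two disjoint gene sets of the observed sizes
#' uniformly without replacement from the background pool, evaluates the
#' statistic, and collects the null distribution. Each replicate is seeded
#' from `seed` plus its index, so runs are reproducible and the first n
#' replicates are unchanged when n grows (stream-stable).
#'
#' @param statistic `function(setA, setB) -> scalar`.
#' @param sizeA,sizeB Sizes of the two resampled sets.
#' @param pool Character vector of background genes (no duplicates,
#'   `sizeA + sizeB <= length(pool)`).
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param observed Observed statistic of the real gene sets; when `NULL` the
#'   result carries `NA` for `observed`/`m`/`pvalue`.
#' @param tail Tail for the p-value.
#' @return Object of class `PermutationResult`: `observed`, `null_values`,
#'   `n` (replicates kept), `m`, `pvalue`, `tail`, `seed`, `n_dropped`.
#'   Replicates whose statistic errors are dropped; more than 1% dropped is
#'   a hard error.
#' @export
permute_statistic <- function(statistic, sizeA, sizeB, pool, n, seed,
                              observed = NULL, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("background pool contains duplicates")
  if (sizeA < 1L || sizeB < 1L) stop("set sizes must be >= 1")
  if (sizeA + sizeB > length(pool))
    stop("pool too small for disjoint sets of sizes ", sizeA, " + ", sizeB)
  if (n < 1L) stop("need at least 1 replicate")
  seed <- as.integer(seed)
  null_values <- numeric(n)
  ok <- logical(n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  for (i in seq_len(n)) {
    set.seed((seed + i) %% 2147483647L)
    idx <- sample.int(length(pool), sizeA + sizeB)
    a <- pool[idx[seq_len(sizeA)]]
    b <- pool[idx[sizeA + seq_len(sizeB)]]
    v <- tryCatch(statistic(a, b), error = function(e) NA_real_)
    if (length(v) == 1L && is.finite(v)) {
      null_values[i] <- v
      ok[i] <- TRUE
    }
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0.01 * n)
    stop(n_dropped, " of ", n, " replicates failed (> 1%)")
  if (n_dropped)
    message(n_dropped, " failed replicate(s) dropped")
  null_values <- null_values[ok]
  res <- list(observed = if (is.null(observed)) NA_real_ else observed,
              null_values = null_values, n = length(null_values),
              m = NA_integer_, pvalue = NA_real_, tail = tail, seed = seed,
              n_dropped = n_dropped)
  if (!is.null(observed)) {
    res$m <- if (tail == "upper") sum(null_values >= observed)
             else sum(null_values <= observed)
    res$pvalue <- mc_pvalue(observed, null_values, tail)
  }
  structure(res, class = "PermutationResult")
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: observed %.4g, n = %d, m = %s, p = %s (%s tail)\n",
              x$observed, x$n, format(x$m), format(x$pvalue), x$tail))
  invisible(x)
}
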