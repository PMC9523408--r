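#' Expression dataset container
#'
#' Bundles a numeric gene-by-sample matrix (log2 intensity for microarray,
#' log2(FPKM+1) for RNA-seq) with per-sample case/control labels, a platform
#' tag and a free-text dataset id. All downstream differential-expression
#' operations consume this container.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene or probe ids),
#'   samples in columns (colnames = sample ids). All values must be finite.
#' @param labels Character vector of `"case"`/`"control"`, either named by
#'   sample id or in column order. At least 2 case and 2 control samples.
#' @param platform One of `"microarray"`, `"rnaseq"`.
#' @param dataset_id Free-text identifier used in logs and reports.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `labels` (named, aligned to columns), `platform`, `dataset_id`.
#' @export
expression_dataset <- function(matrix, labels, platform = c("microarray", "rnaseq"),
                               dataset_id = "dataset") {
  platform <- match.arg(platform)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated gene identifiers in expression matrix: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (!all(is.finite(matrix)))
    stop("expression matrix contains non-finite values")
  labels <- align_labels(labels, colnames(matrix))
  if (sum(labels == "case") < 2L || sum(labels == "control") < 2L)
    stop("need at least 2 case and 2 control samples")
  structure(list(matrix = matrix, labels = labels, platform = platform,
                 dataset_id = dataset_id),
            class = "ExpressionDataset")
}

# Match a case/control label vector to sample ids; every sample must get
# exactly one label.
align_labels <- function(labels, sample_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  bad <- setdiff(labels, c("case", "control"))
  if (length(bad))
    stop("labels must be 'case' or 'control'; got: ", paste(bad, collapse = ", "))
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("samples missing from label spec: ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  } else {
    if (length(labels) != length(sample_ids))
      stop("label vector length ", length(labels), " != sample count ",
           length(sample_ids))
    names(labels) <- sample_ids
  }
  labels
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s): %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, x$platform, nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Read a delimited gene-by-sample expression table
#'
#' Expects a header row of sample ids and a first column of gene (or probe)
#' ids; remaining cells numeric. Values are read as-is, with no transform.
#'
#' @param path Path to a TSV/CSV file.
#' @param labels Case/control assignment: a character vector (see
#'   [expression_dataset()]) or a path to a two-column TSV
#'   (sample_id, group in {case, control}).
#' @param platform,dataset_id Passed to [expression_dataset()].
#' @param sep Field separator; `"\t"` (default) or `","`. Guessed from the
#'   file extension when `NULL`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels, platform = c("microarray", "rnaseq"),
                            dataset_id = basename(path), sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs an id column plus >=1 sample")
  ids <- df[[1L]]
  num <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(num), dim = dim(num)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 ids[bad[1L]], colnames(num)[bad[2L]]))
  }
  dimnames(vals) <- list(ids, colnames(num))
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  expression_dataset(vals, labels, platform = platform, dataset_id = dataset_id)
}

#' Read a two-column sample label table (sample_id, group)
#' @param path TSV with columns sample_id and group (`case`/`control`);
#'   header optional.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (nrow(df) && df[1L, 2L] %in% c("group", "label"))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write an expression matrix (or dataset) as TSV
#' @param x `ExpressionDataset` or numeric matrix.
#' @param path Output path.
#' @param id_col Name for the gene-id column header.
#' @export
write_expression <- function(x, path, id_col = "gene") {
  m <- if (inherits(x, "ExpressionDataset")) x$matrix else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-gene map
#'
#' Probes mapped to more than one gene are ambiguous and removed entirely
#' (with a message), so the returned map is strictly many-probes-to-one-gene.
#'
#' @param path TSV with columns probe_id, gene_symbol; header optional.
#' @return Named character vector: names are probe ids, values gene symbols.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (nrow(df) && tolower(df[1L, 1L]) %in% c("probe", "probe_id"))
    df <- df[-1L, , drop = FALSE]
  df <- unique(df[, 1:2])
  ambiguous <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(ambiguous)) {
    message(length(ambiguous), " ambiguous probe(s) mapped to multiple genes removed")
    df <- df[!(df[[1L]] %in% ambiguous), , drop = FALSE]
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to the same gene are averaged (arithmetic mean per sample);
#' probes absent from the map are dropped. The map must already be free of
#' ambiguous probes (see [read_probe_map()]).
#'
#' @param probe_matrix Numeric matrix with probe ids as rownames.
#' @param probe_map Named character vector probe_id -> gene_symbol.
#' @return Numeric gene-by-sample matrix, one row per gene.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  if (anyDuplicated(names(probe_map)))
    stop("probe_map contains probes mapped to more than one gene")
  keep <- rownames(probe_matrix) %in% names(probe_map)
  if (!any(keep))
    stop("no probes in the matrix are present in the probe map")
  dropped <- sum(!keep)
  if (dropped) message(dropped, " unmapped probe row(s) dropped")
  m <- probe_matrix[keep, , drop = FALSE]
  genes <- unname(probe_map[rownames(m)])
  out <- rowsum(m, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  out
}

#' Log2-transform an expression matrix
#'
#' Each value x becomes log2(x + offset). Microarray intensities are already
#' strictly positive so the conventional offset is 0; FPKM uses +1 to keep
#' zeros finite.
#'
#' @param matrix Numeric matrix, all values >= 0.
#' @param offset Non-negative pseudo-count added before the log.
#' @return Transformed matrix of the same shape.
#' @export
log2_transform <- function(matrix, offset = 0) {
  if (any(matrix < 0)) stop("negative values cannot be log2-transformed")
  if (any(matrix + offset <= 0))
    stop("zero values with offset 0: supply a positive offset")
  log2(matrix + offset)
}

#' Restrict datasets to their common genes
#'
#' Different platforms cover different genes; all cross-dataset analysis is
#' restricted to genes present in every dataset, in a common order.
#'
#' @param datasets List of >= 2 [expression_dataset()] objects.
#' @return List of datasets, each containing exactly the gene intersection in
#'   identical (sorted) order.
#' @export
restrict_to_common_genes <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$matrix)))
  if (!length(common)) stop("datasets share no genes")
  common <- sort(common)
  lapply(datasets, function(d) {
    d$matrix <- d$matrix[common, , drop = FALSE]
    d
  })
}
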