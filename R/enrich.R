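#' Upper-tail hypergeometric probability
#'
#' P(X >= t_overlap) for X ~ Hypergeometric(population `n_background`,
#' successes `m_termsize`, draws `k_interest`): the probability of observing
#' at least that many query genes annotated to a term by chance. Evaluated
#' via `stats::phyper`, which works in log space internally.
#'
#' @param t_overlap Query genes annotated to the term.
#' @param k_interest Query set size (within the background).
#' @param m_termsize Background genes annotated to the term.
#' @param n_background Background size.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper <- function(t_overlap, k_interest, m_termsize, n_background) {
  if (any(c(t_overlap, k_interest, m_termsize, n_background) < 0))
    stop("counts must be non-negative")
  if (t_overlap > min(k_interest, m_termsize) ||
      k_interest > n_background || m_termsize > n_background)
    stop("inconsistent counts: t <= min(k, m) and k, m <= n required")
  stats::phyper(t_overlap - 1, m_termsize, n_background - m_termsize,
                k_interest, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: adjusted_i = min over j with p_j >= p_i (by rank) of
#' p_j * M / rank_j, clipped at 1; input order is preserved.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Term/pathway enrichment of a gene set
#'
#' For every term annotating at least `min_term_size` background genes, the
#' upper-tail hypergeometric p-value of the query/term overlap is computed
#' and BH-adjusted. When a DAG is supplied, gene annotations are first
#' propagated to all ancestor terms (standard ontology enrichment
#' semantics); a flat pathway -> gene map works identically without a DAG.
#'
#' @param query Gene set of interest; genes outside the background are
#'   dropped with a warning.
#' @param annotations Named list gene -> term ids, or an [ontology_dag()]
#'   (its annotations are used and propagated).
#' @param background Character vector of detected genes (the universe).
#' @param dag Optional [ontology_dag()] used to propagate annotations when
#'   `annotations` is a plain list.
#' @param min_term_size Smallest background term size kept (default 3).
#' @param fdr_cut FDR significance cutoff recorded in the output (default
#'   0.05).
#' @return `data.frame` sorted by p-value with columns `term`, `name`,
#'   `t_overlap`, `k_interest`, `m_termsize`, `n_background`, `pvalue`,
#'   `fdr`, `significant`, plus the overlapping genes in `genes`
#'   (comma-separated).
#' @export
enrich_terms <- function(query, annotations, background, dag = NULL,
                         min_term_size = 3L, fdr_cut = 0.05) {
  term_names <- NULL
  if (inherits(annotations, "OntologyDag")) {
    dag <- annotations
    annotations <- dag$annotations
  }
  if (!is.null(dag)) {
    term_names <- dag$term_names
    annotations <- lapply(annotations, function(t) {
      unique(unlist(dag$ancestors[intersect(t, names(dag$ancestors))],
                    use.names = FALSE))
    })
  }
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  if (!length(query)) stop("empty query after restriction to background")
  annotations <- annotations[intersect(names(annotations), background)]
  term2genes <- split(rep(names(annotations),
                          lengths(annotations)),
                      unlist(annotations, use.names = FALSE))
  sizes <- lengths(term2genes)
  term2genes <- term2genes[sizes >= min_term_size]
  if (!length(term2genes))
    return(empty_enrichment())
  n_bg <- length(background)
  k <- length(query)
  rows <- lapply(names(term2genes), function(term) {
    genes <- term2genes[[term]]
    hit <- intersect(query, genes)
    data.frame(term = term,
               name = if (!is.null(term_names) && term %in% names(term_names))
                 unname(term_names[term]) else term,
               t_overlap = length(hit), k_interest = k,
               m_termsize = length(genes), n_background = n_bg,
               pvalue = hypergeom_upper(length(hit), k, length(genes), n_bg),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "name", "t_overlap", "k_interest", "m_termsize",
          "n_background", "pvalue", "fdr", "significant", "genes")]
}

empty_enrichment <- function() {
  data.frame(term = character(), name = character(), t_overlap = integer(),
             k_interest = integer(), m_termsize = integer(),
             n_background = integer(), pvalue = numeric(), fdr = numeric(),
             significant = logical(), genes = character(),
             stringsAsFactors = FALSE)
}

#' Read a flat pathway-to-gene map
#' @param path Two-column TSV (pathway_id, gene); header optional.
#' @return Named list gene -> pathway ids, suitable for [enrich_terms()]
#'   without a DAG.
#' @export
read_pathways <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (nrow(df) && tolower(df[1L, 1L]) %in% c("pathway", "pathway_id", "term"))
    df <- df[-1L, , drop = FALSE]
  lapply(split(df[[1L]], df[[2L]]), unique)
}
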