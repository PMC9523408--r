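#' Semantic similarity between two ontology terms
#'
#' Five measures over the annotation-derived information content (natural
#' log) and the DAG topology:
#' \describe{
#'   \item{resnik}{ic(MICA), unbounded above, 0 at the root.}
#'   \item{lin}{2 ic(MICA) / (ic(t1) + ic(t2)); 0 when the denominator is 0.}
#'   \item{jiang}{1 - min(1, ic(t1) + ic(t2) - 2 ic(MICA)), the distance
#'     mapped into [0, 1].}
#'   \item{rel}{lin weighted by (1 - p(MICA)), discounting similarity that
#'     rests on a very common ancestor.}
#'   \item{wang}{topological S-value measure: each ancestor t of a term
#'     contributes S(t), the maximal product of edge weights (is_a 0.8,
#'     part_of 0.6 by default) along any upward path; similarity is the sum
#'     of shared-ancestor contributions over the sum of all contributions.}
#' }
#' Pairs with no common ancestor (different roots/namespaces) score 0.
#'
#' @param t1,t2 Term ids.
#' @param measure One of `"wang"`, `"resnik"`, `"lin"`, `"jiang"`, `"rel"`.
#' @param dag An [ontology_dag()].
#' @param ic A [compute_ic()] result (unused by `wang`).
#' @param wang_weights Edge weights for the wang measure.
#' @return Numeric similarity; in [0, 1] for all measures except resnik
#'   (>= 0).
#' @export
term_sim <- function(t1, t2, measure = c("wang", "resnik", "lin", "jiang", "rel"),
                     dag, ic = NULL,
                     wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  if (measure == "wang") {
    s1 <- wang_svalues(dag, t1, wang_weights)
    s2 <- wang_svalues(dag, t2, wang_weights)
    common <- intersect(names(s1), names(s2))
    if (!length(common)) return(0)
    return(sum(s1[common] + s2[common]) / (sum(s1) + sum(s2)))
  }
  if (is.null(ic)) stop("IC-based measures need `ic`")
  m <- tryCatch(mica(t1, t2, dag, ic), error = function(e) NULL)
  if (is.null(m)) return(0)
  ic_m <- ic$ic[[m]]
  ic1 <- ic$ic[[t1]]
  ic2 <- ic$ic[[t2]]
  if (measure == "resnik") return(ic_m)
  if (is.na(ic1) || is.na(ic2)) return(0)
  lin <- if (ic1 + ic2 == 0) 0 else 2 * ic_m / (ic1 + ic2)
  switch(measure,
         lin = lin,
         jiang = 1 - min(1, ic1 + ic2 - 2 * ic_m),
         rel = lin * (1 - ic$p[[m]]))
}

# S-values of the wang measure: S(term) = 1; for each ancestor a,
# S(a) = max over in-closure children c of w(c -> a) * S(c). Fixed-point
# relaxation over the (small) ancestor closure; converges in <= depth passes.
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  anc <- dag$ancestors[[term]]
  if (is.null(anc)) stop("term not in DAG: ", term)
  s <- stats::setNames(numeric(length(anc)), anc)
  s[term] <- 1
  repeat {
    changed <- FALSE
    for (t in anc) {
      if (s[[t]] == 0) next
      ps <- dag$parents[[t]]
      if (is.null(ps) || !nrow(ps)) next
      for (j in seq_len(nrow(ps))) {
        p <- ps$parent[j]
        if (!p %in% anc) next
        cand <- s[[t]] * weights[[ps$type[j]]]
        if (cand > s[[p]] + 1e-12) {
          s[[p]] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  s
}

#' Pairwise term similarity matrix
#'
#' @param terms1,terms2 Character vectors of term ids.
#' @inheritParams term_sim
#' @return Numeric matrix `length(terms1) x length(terms2)`.
#' @export
term_sim_matrix <- function(terms1, terms2, measure, dag, ic = NULL,
                            wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  out <- matrix(0, length(terms1), length(terms2),
                dimnames = list(terms1, terms2))
  for (i in seq_along(terms1))
    for (j in seq_along(terms2))
      out[i, j] <- term_sim(terms1[i], terms2[j], measure, dag, ic,
                            wang_weights)
  out
}

#' Aggregate a similarity matrix into one score
#'
#' `bma` (best-match average, the pipeline default) averages every row
#' maximum and every column maximum; `max` takes the matrix maximum; `avg`
#' the matrix mean.
#'
#' @param m Numeric matrix with >= 1 cell.
#' @param combine Aggregation rule.
#' @return Scalar score.
#' @export
combine_sim <- function(m, combine = c("bma", "max", "avg")) {
  combine <- match.arg(combine)
  if (!length(m)) stop("empty similarity matrix")
  switch(combine,
         bma = (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
           (nrow(m) + ncol(m)),
         max = max(m),
         avg = mean(m))
}

#' Gene-gene similarity matrix over annotated genes
#'
#' Gene-level similarity is the best-match average over the two genes' direct
#' term sets. Genes sharing an identical term signature are computed once.
#' Intended as a precomputation for set-level scoring and permutation nulls.
#'
#' @param genes1,genes2 Character vectors of gene symbols; genes without
#'   annotations are dropped (count reported via warning).
#' @inheritParams term_sim
#' @param combine Term-level aggregation (default `"bma"`).
#' @return Numeric matrix over the annotated genes of each input.
#' @export
gene_sim_matrix <- function(genes1, genes2, measure, dag, ic = NULL,
                            combine = "bma",
                            wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  genes1 <- unique(as.character(genes1))
  genes2 <- unique(as.character(genes2))
  ann <- dag$annotations
  keep1 <- genes1 %in% names(ann)
  keep2 <- genes2 %in% names(ann)
  n_drop <- sum(!keep1) + sum(!keep2)
  if (n_drop) warning(n_drop, " unannotated gene(s) dropped")
  genes1 <- genes1[keep1]
  genes2 <- genes2[keep2]
  if (!length(genes1) || !length(genes2))
    stop("a gene set is empty after removing unannotated genes")
  sig1 <- vapply(ann[genes1], function(t) paste(sort(t), collapse = "|"), "")
  sig2 <- vapply(ann[genes2], function(t) paste(sort(t), collapse = "|"), "")
  usig1 <- unique(sig1)
  usig2 <- unique(sig2)
  terms <- sort(unique(unlist(strsplit(c(usig1, usig2), "|", fixed = TRUE))))
  tsm <- term_sim_matrix(terms, terms, measure, dag, ic, wang_weights)
  tl1 <- strsplit(usig1, "|", fixed = TRUE)
  tl2 <- strsplit(usig2, "|", fixed = TRUE)
  core <- matrix(0, length(usig1), length(usig2))
  for (i in seq_along(tl1)) {
    for (j in seq_along(tl2)) {
      core[i, j] <- combine_sim(tsm[tl1[[i]], tl2[[j]], drop = FALSE], combine)
    }
  }
  out <- core[match(sig1, usig1), match(sig2, usig2), drop = FALSE]
  dimnames(out) <- list(genes1, genes2)
  out
}

#' Functional similarity between two gene sets
#'
#' Gene-gene similarities (best-match average over term sets) are aggregated
#' across the set-by-set matrix, by best-match average by default. The score
#' is invariant to gene order and duplication within a set.
#'
#' @param setA,setB Character vectors of gene symbols; must contain at least
#'   one annotated gene each.
#' @inheritParams gene_sim_matrix
#' @param sim_matrix Optional precomputed [gene_sim_matrix()] covering all
#'   genes of both sets (rows and columns indexed by gene); when supplied,
#'   `dag`/`ic` are not consulted. Used to make permutation nulls cheap.
#' @return Scalar similarity score.
#' @export
geneset_sim <- function(setA, setB, measure = "wang", dag = NULL, ic = NULL,
                        combine = "bma", sim_matrix = NULL,
                        wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!is.null(sim_matrix)) {
    a <- intersect(unique(as.character(setA)), rownames(sim_matrix))
    b <- intersect(unique(as.character(setB)), colnames(sim_matrix))
    if (!length(a) || !length(b))
      stop("a gene set is empty after restriction to the similarity matrix")
    return(combine_sim(sim_matrix[a, b, drop = FALSE], combine))
  }
  m <- gene_sim_matrix(setA, setB, measure, dag, ic, combine, wang_weights)
  combine_sim(m, combine)
}
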