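#' Construct an ontology DAG with gene annotations
#'
#' The DAG is rooted (one or more terms with no parent), acyclic, with typed
#' child-to-parent edges (`is_a`, `part_of`). Ancestor closures (each term's
#' ancestors including itself) are precomputed; construction fails on a cycle
#' or on an annotation to an unknown term.
#'
#' @param edges `data.frame` with columns `child`, `parent` and optionally
#'   `type` (`is_a`/`part_of`, default `is_a`).
#' @param annotations Named list: gene symbol -> character vector of directly
#'   annotated term ids. May be empty.
#' @param terms Optional character vector of term ids; defaults to all ids
#'   seen in `edges` plus all annotated terms. Lets isolated roots exist.
#' @param term_names Optional named character vector of human-readable names.
#' @return Object of class `OntologyDag`: `terms`, `edges`, `parents` (list of
#'   per-term data.frames), `ancestors` (closure incl. self), `roots`,
#'   `annotations`, `term_names`.
#' @export
ontology_dag <- function(edges, annotations = list(), terms = NULL,
                         term_names = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  if (is.null(edges$type)) edges$type <- "is_a"
  bad <- setdiff(unique(edges$type), c("is_a", "part_of"))
  if (length(bad)) stop("unsupported edge type(s): ", paste(bad, collapse = ", "))
  edges <- unique(edges[, c("child", "parent", "type")])
  all_terms <- unique(c(terms, edges$child, edges$parent))
  if (!length(all_terms)) stop("empty ontology")
  parents <- split(edges[, c("parent", "type")], factor(edges$child, levels = all_terms))
  roots <- all_terms[vapply(parents, nrow, integer(1)) == 0L]
  if (!length(roots)) stop("ontology has no root (cycle through every term)")

  anc <- compute_ancestor_closure(all_terms, parents)

  unknown <- setdiff(unlist(annotations, use.names = FALSE), all_terms)
  if (length(unknown))
    stop("annotations reference unknown terms: ", paste(unknown, collapse = ", "))
  annotations <- lapply(annotations, function(t) unique(as.character(t)))

  structure(list(terms = all_terms, edges = edges, parents = parents,
                 ancestors = anc, roots = roots, annotations = annotations,
                 term_names = term_names),
            class = "OntologyDag")
}

# Iterative DFS computing each term's ancestor set (including itself);
# detects cycles via the in-progress stack.
compute_ancestor_closure <- function(terms, parents) {
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- stats::setNames(integer(length(terms)), terms)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("cycle in ontology involving term ", t)
    state[[t]] <<- 1L
    ps <- parents[[t]]$parent
    res <- t
    for (p in ps) res <- union(res, visit(p))
    anc[[t]] <<- res
    state[[t]] <<- 2L
    res
  }
  for (t in terms) visit(t)
  anc
}

#' @export
print.OntologyDag <- function(x, ...) {
  cat(sprintf("OntologyDag: %d terms, %d edges, %d root(s), %d annotated gene(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots),
              length(x$annotations)))
  invisible(x)
}

#' Parse a (minimal) OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas: `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are skipped; other
#' relationship types are ignored with a count message. When `namespace` is
#' given, terms outside it are dropped.
#'
#' @param path OBO file path.
#' @param annotations Optional annotation list passed to [ontology_dag()].
#' @param namespace Optional namespace filter, e.g. `"biological_process"`.
#' @return An [ontology_dag()].
#' @export
read_obo <- function(path, annotations = list(), namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  ids <- character()
  names_vec <- character()
  ns_vec <- character()
  edges <- list()
  skipped_rel <- 0L
  for (s in term_starts) {
    nxt <- starts[starts > s]
    block <- lines[(s + 1):(if (length(nxt)) nxt[1] - 1 else length(lines))]
    get1 <- function(key) sub(paste0("^", key, ": *"), "",
                              grep(paste0("^", key, ": "), block, value = TRUE))
    if (length(grep("^is_obsolete: *true", block))) next
    id <- get1("id")[1]
    if (is.na(id) || !length(id)) next
    nm <- get1("name")
    ns <- get1("namespace")
    ids <- c(ids, id)
    names_vec <- c(names_vec, if (length(nm)) nm[1] else id)
    ns_vec <- c(ns_vec, if (length(ns)) ns[1] else NA_character_)
    for (ln in grep("^is_a: ", block, value = TRUE)) {
      parent <- sub(" *!.*$", "", sub("^is_a: *", "", ln))
      edges[[length(edges) + 1L]] <- c(id, parent, "is_a")
    }
    for (ln in grep("^relationship: ", block, value = TRUE)) {
      body <- sub("^relationship: *", "", ln)
      parts <- strsplit(sub(" *!.*$", "", body), " +")[[1]]
      if (identical(parts[1], "part_of")) {
        edges[[length(edges) + 1L]] <- c(id, parts[2], "part_of")
      } else {
        skipped_rel <- skipped_rel + 1L
      }
    }
  }
  if (skipped_rel)
    message(skipped_rel, " non is_a/part_of relationship line(s) ignored")
  edf <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  if (nrow(edf)) names(edf) <- c("child", "parent", "type")
  if (!is.null(namespace)) {
    keep <- ids[!is.na(ns_vec) & ns_vec == namespace]
    edf <- edf[edf$child %in% keep & edf$parent %in% keep, , drop = FALSE]
    annotations <- lapply(annotations, function(t) intersect(t, keep))
    annotations <- annotations[vapply(annotations, length, integer(1)) > 0L]
    ids <- keep
  }
  ontology_dag(edf, annotations = annotations, terms = ids,
               term_names = stats::setNames(names_vec, ids)[ids])
}

#' Read gene-to-term annotations
#'
#' Accepts a two-column TSV (gene, term; header optional) or a GAF 2.x file
#' (17-column, `!` comments; columns 2 = gene symbol and 5 = term are used,
#' rows whose qualifier contains `NOT` are dropped).
#'
#' @param path File path.
#' @return Named list gene -> character vector of term ids.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, integer(1))
  if (all(ncols >= 15L)) {  # GAF
    keep <- !vapply(fields, function(f) grepl("NOT", f[4]), logical(1))
    fields <- fields[keep]
    genes <- vapply(fields, `[`, character(1), 2L)
    terms <- vapply(fields, `[`, character(1), 5L)
  } else {
    if (length(fields) && tolower(fields[[1]][1]) %in% c("gene", "gene_symbol"))
      fields <- fields[-1]
    genes <- vapply(fields, `[`, character(1), 1L)
    terms <- vapply(fields, `[`, character(1), 2L)
  }
  lapply(split(terms, genes), unique)
}

#' Per-term information content from annotation frequency
#'
#' Each gene's annotations are propagated to all ancestors (a gene is counted
#' once per term even when reached via multiple paths); a term's probability
#' is its propagated count divided by the count of its root, and
#' ic(t) = -ln p(t). Terms with zero propagated count have undefined IC and
#' are excluded from IC-based similarity.
#'
#' @param dag An [ontology_dag()] with at least one annotated gene.
#' @return List of class `TermIC`: `ic` and `p` (named numeric over terms,
#'   NA where undefined), `counts`, `n_annotated_genes`.
#' @export
compute_ic <- function(dag) {
  stopifnot(inherits(dag, "OntologyDag"))
  if (!length(dag$annotations)) stop("no annotated genes")
  counts <- stats::setNames(integer(length(dag$terms)), dag$terms)
  for (terms in dag$annotations) {
    closure <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
    counts[closure] <- counts[closure] + 1L
  }
  # denominator: the (largest-count) root reachable from each term
  root_count <- vapply(dag$terms, function(t) {
    r <- intersect(dag$ancestors[[t]], dag$roots)
    if (!length(r)) return(NA_integer_)
    max(counts[r])
  }, integer(1))
  p <- ifelse(counts > 0L & root_count > 0L, counts / root_count, NA_real_)
  ic <- -log(p)
  n_undef <- sum(is.na(ic))
  if (n_undef)
    warning(n_undef, " term(s) with zero annotation count excluded from IC")
  structure(list(ic = ic, p = p, counts = counts,
                 n_annotated_genes = length(dag$annotations)),
            class = "TermIC")
}

#' Most informative common ancestor of two terms
#'
#' Ancestor sets include the terms themselves; among common ancestors with
#' defined IC the one with maximal IC is returned, ties broken by
#' lexicographically smallest id.
#'
#' @param t1,t2 Term ids present in the DAG.
#' @param dag An [ontology_dag()].
#' @param ic A [compute_ic()] result.
#' @return Term id, or an error when the terms share no ancestor (e.g.
#'   different namespaces/roots) — callers treat that pair's similarity as 0.
#' @export
mica <- function(t1, t2, dag, ic) {
  if (!t1 %in% dag$terms || !t2 %in% dag$terms)
    stop("term not in DAG: ", paste(setdiff(c(t1, t2), dag$terms), collapse = ", "))
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  common <- common[!is.na(ic$ic[common])]
  if (!length(common)) stop("no common ancestor for ", t1, " and ", t2)
  vals <- ic$ic[common]
  cand <- common[vals == max(vals)]
  sort(cand)[1L]
}
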