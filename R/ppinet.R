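#' Read a scored protein-interaction table
#'
#' Three whitespace- or tab-delimited columns (protein1, protein2,
#' combined_score), STRING detailed-links dialect accepted; a header row is
#' detected and skipped. Integer 0-1000 scores are auto-detected (maximum
#' > 1) and divided by 1000. Rows whose score falls outside [0, 1] after
#' scaling are rejected with a count message.
#'
#' @param path File path.
#' @return `data.frame` with columns `a`, `b`, `score`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "#")
  if (ncol(df) < 3L) stop("interaction table needs 3 columns")
  if (is.na(suppressWarnings(as.numeric(df[1L, 3L]))))
    df <- df[-1L, , drop = FALSE]
  score <- suppressWarnings(as.numeric(df[[3L]]))
  out <- data.frame(a = df[[1L]], b = df[[2L]], score = score,
                    stringsAsFactors = FALSE)
  if (any(is.na(score))) {
    message(sum(is.na(score)), " row(s) with non-numeric score rejected")
    out <- out[!is.na(out$score), , drop = FALSE]
  }
  if (nrow(out) && max(out$score) > 1) out$score <- out$score / 1000
  bad <- out$score < 0 | out$score > 1
  if (any(bad)) {
    message(sum(bad), " row(s) with score outside [0,1] rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Build the thresholded interaction network over two disease gene sets
#'
#' Keeps edges with both endpoints in `nodesA` union `nodesB` and score
#' strictly greater than the threshold; drops self-loops; stores each pair
#' once in canonical (sorted) order, keeping the maximal score of duplicate
#' rows. All input genes are retained as nodes, isolated ones with degree 0.
#'
#' @param interactions `data.frame` with columns `a`, `b`, `score` (see
#'   [read_interactions()]) — scores in [0, 1]; out-of-range rows are
#'   rejected with a count message.
#' @param nodesA,nodesB Gene sets of the two diseases; genes in both are
#'   tagged `"shared"`.
#' @param threshold Confidence cutoff; strict inequality (default 0.4).
#' @return Object of class `InteractionNetwork`: `edges` (`a`, `b`, `score`,
#'   `cross` flag), `nodes` (`gene`, `disease` in {A, B, shared}),
#'   `threshold`.
#' @export
build_network <- function(interactions, nodesA, nodesB, threshold = 0.4) {
  nodesA <- unique(as.character(nodesA))
  nodesB <- unique(as.character(nodesB))
  all_nodes <- union(nodesA, nodesB)
  if (!length(all_nodes)) stop("no nodes supplied")
  e <- interactions
  bad <- !is.finite(e$score) | e$score < 0 | e$score > 1
  if (any(bad)) {
    message(sum(bad), " malformed interaction row(s) rejected")
    e <- e[!bad, , drop = FALSE]
  }
  e <- e[e$score > threshold & e$a != e$b &
           e$a %in% all_nodes & e$b %in% all_nodes, , drop = FALSE]
  if (nrow(e)) {
    lo <- pmin(e$a, e$b)
    hi <- pmax(e$a, e$b)
    e <- data.frame(a = lo, b = hi, score = e$score, stringsAsFactors = FALSE)
    e <- e[order(e$a, e$b, -e$score), , drop = FALSE]
    e <- e[!duplicated(paste(e$a, e$b, sep = "\r")), , drop = FALSE]
    rownames(e) <- NULL
  }
  disease <- ifelse(all_nodes %in% nodesA & all_nodes %in% nodesB, "shared",
                    ifelse(all_nodes %in% nodesA, "A", "B"))
  nodes <- data.frame(gene = all_nodes, disease = disease,
                      stringsAsFactors = FALSE)
  cross <- (e$a %in% nodesA & e$b %in% nodesB) |
           (e$a %in% nodesB & e$b %in% nodesA)
  # edges within the shared overlap are not cross-disease
  both_shared <- (e$a %in% nodesA & e$a %in% nodesB) &
                 (e$b %in% nodesA & e$b %in% nodesB)
  e$cross <- cross & !both_shared
  structure(list(edges = e, nodes = nodes, threshold = threshold),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes (%d non-isolated), %d edges (score > %g), %d cross-disease\n",
              nrow(x$nodes), length(unique(c(x$edges$a, x$edges$b))),
              nrow(x$edges), x$threshold, sum(x$edges$cross)))
  invisible(x)
}

#' Node degrees, per-disease hub lists and cross-set connectivity
#'
#' Degree counts distinct neighbors. Hubs are the `top_k` highest-degree
#' nodes per disease, ties broken by gene symbol ascending. `cross_edges`
#' counts edges with one endpoint in each disease set. Both the all-input
#' node count and the non-isolated node count are reported, since isolated
#' genes are often excluded from drawn networks.
#'
#' @param net An [build_network()] result.
#' @param top_k Hub list length per disease (default 10).
#' @return List of class `HubReport`: `degrees` (named integer), `hubs`
#'   (data.frame gene/disease/degree), `cross_edges`, `n_edges`,
#'   `n_nodes_total`, `n_nodes_connected`.
#' @export
degree_and_hubs <- function(net, top_k = 10L) {
  stopifnot(inherits(net, "InteractionNetwork"))
  genes <- net$nodes$gene
  deg <- stats::setNames(integer(length(genes)), genes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$a, net$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  node_df <- data.frame(gene = genes, disease = net$nodes$disease,
                        degree = unname(deg[genes]),
                        stringsAsFactors = FALSE)
  hubs <- do.call(rbind, lapply(split(node_df, node_df$disease), function(d) {
    d <- d[order(-d$degree, d$gene), , drop = FALSE]
    utils::head(d, top_k)
  }))
  rownames(hubs) <- NULL
  structure(list(degrees = deg, hubs = hubs,
                 cross_edges = sum(net$edges$cross),
                 n_edges = nrow(net$edges),
                 n_nodes_total = length(genes),
                 n_nodes_connected = sum(deg > 0L)),
            class = "HubReport")
}

#' Permutation test of cross-set connectivity
#'
#' The observed statistic is the number of network edges joining the two
#' disease gene sets. Under the null, two disjoint gene sets of the same
#' sizes are redrawn from the background pool and the induced thresholded
#' network is rebuilt each time; the upper-tail Monte-Carlo p-value
#' ((m+1)/(n+1)) is reported.
#'
#' @param interactions Scored pair table (`a`, `b`, `score`).
#' @param nodesA,nodesB Observed disease gene sets.
#' @param pool Background gene pool (superset of both sets).
#' @param n Number of permutations.
#' @param seed Integer seed.
#' @param threshold Score cutoff, strict (default 0.4).
#' @return A [permute_statistic()] result.
#' @export
connectivity_test <- function(interactions, nodesA, nodesB, pool, n = 1000L,
                              seed = 1L, threshold = 0.4) {
  nodesA <- unique(as.character(nodesA))
  nodesB <- unique(as.character(nodesB))
  pool <- unique(as.character(pool))
  missing <- setdiff(c(nodesA, nodesB), pool)
  if (length(missing))
    stop("pool must contain both gene sets; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  obs_net <- build_network(interactions, nodesA, nodesB, threshold)
  observed <- sum(obs_net$edges$cross)
  # prefilter once: valid above-threshold pool edges, canonical order
  e <- interactions
  e <- e[is.finite(e$score) & e$score > threshold & e$score <= 1 &
           e$a != e$b & e$a %in% pool & e$b %in% pool, , drop = FALSE]
  lo <- pmin(e$a, e$b)
  hi <- pmax(e$a, e$b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  ea <- lo[keep]
  eb <- hi[keep]
  stat <- function(a, b) {
    sum((ea %in% a & eb %in% b) | (ea %in% b & eb %in% a))
  }
  permute_statistic(stat, length(nodesA), length(nodesB), pool, n, seed,
                    observed = observed, tail = "upper")
}

#' Export a network as edge-list TSV, SIF and node-attribute TSV
#'
#' @param net An [build_network()] result.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>.sif` and `<prefix>_nodes.tsv`.
#' @param node_extra Optional data.frame keyed by `gene` with extra node
#'   attributes (e.g. regulation direction) merged into the node table.
#' @return Invisibly, the three paths written.
#' @export
write_network <- function(net, prefix, node_extra = NULL) {
  stopifnot(inherits(net, "InteractionNetwork"))
  edge_path <- paste0(prefix, "_edges.tsv")
  sif_path <- paste0(prefix, ".sif")
  node_path <- paste0(prefix, "_nodes.tsv")
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(if (nrow(net$edges))
               paste(net$edges$a, "pp", net$edges$b) else character(),
             sif_path)
  rep <- degree_and_hubs(net, top_k = nrow(net$nodes))
  nodes <- data.frame(gene = net$nodes$gene, disease = net$nodes$disease,
                      degree = unname(rep$degrees[net$nodes$gene]),
                      stringsAsFactors = FALSE)
  if (!is.null(node_extra)) nodes <- merge(nodes, node_extra, by = "gene",
                                           all.x = TRUE, sort = FALSE)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, sif_path, node_path))
}
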