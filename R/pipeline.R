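#' Assemble and validate a pipeline configuration
#'
#' A configuration bundles the inputs (either in-memory objects or file
#' paths) and the analysis parameters. Defaults mirror the standard
#' workflow: fold-change gate 1.5, raw p gate 0.05, interaction score cutoff
#' 0.4 (strict), all five similarity measures, 10,000 permutations for the
#' similarity null and 1,000 for the connectivity null, top-10 hubs, FDR
#' 0.05.
#'
#' @param datasets Named list of [expression_dataset()] objects (log2
#'   scale), or of lists `list(path=, labels=, platform=)` consumed by
#'   [read_expression()].
#' @param diseases Named list of two character vectors naming each disease's
#'   datasets, e.g. `list(AD = c("ds1","ds2"), diabetes = c("ds3","ds4"))`.
#' @param dag An [ontology_dag()], or a list `list(obo=, annotations=)` of
#'   paths.
#' @param interactions Interaction `data.frame` (`a`,`b`,`score`) or a path
#'   for [read_interactions()].
#' @param fc_threshold,p_threshold DEG gates.
#' @param ppi_threshold Interaction score cutoff (strict >).
#' @param ss_measures Similarity measures to run.
#' @param n_perm_ss,n_perm_net Permutation counts for the similarity and
#'   connectivity nulls.
#' @param top_k_hubs Hub list length per disease.
#' @param fdr_cut Enrichment FDR cutoff.
#' @param seed Integer seed driving both permutation nulls.
#' @param out_dir Output directory for the report and TSV tables; `NULL`
#'   (default) writes nothing.
#' @return Validated config list of class `RunConfig`.
#' @export
run_config <- function(datasets, diseases, dag, interactions,
                       fc_threshold = 1.5, p_threshold = 0.05,
                       ppi_threshold = 0.4,
                       ss_measures = c("wang", "resnik", "lin", "jiang", "rel"),
                       n_perm_ss = 10000L, n_perm_net = 1000L,
                       top_k_hubs = 10L, fdr_cut = 0.05, seed = 1L,
                       out_dir = NULL) {
  cfg <- list(datasets = datasets, diseases = diseases, dag = dag,
              interactions = interactions, fc_threshold = fc_threshold,
              p_threshold = p_threshold, ppi_threshold = ppi_threshold,
              ss_measures = match.arg(ss_measures,
                                      c("wang", "resnik", "lin", "jiang", "rel"),
                                      several.ok = TRUE),
              n_perm_ss = as.integer(n_perm_ss),
              n_perm_net = as.integer(n_perm_net),
              top_k_hubs = as.integer(top_k_hubs), fdr_cut = fdr_cut,
              seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  if (cfg$fc_threshold <= 0 || cfg$p_threshold <= 0 || cfg$ppi_threshold < 0)
    stop("config: thresholds must be positive")
  if (cfg$n_perm_ss < 1L || cfg$n_perm_net < 1L)
    stop("config: permutation counts must be >= 1")
  if (length(cfg$diseases) != 2L || is.null(names(cfg$diseases)))
    stop("config: exactly two named diseases required")
  sizes <- vapply(cfg$diseases, length, integer(1))
  if (any(sizes < 2L))
    stop("config: at least two datasets per disease required")
  missing <- setdiff(unlist(cfg$diseases), names(cfg$datasets))
  if (length(missing))
    stop("config: diseases reference unknown datasets: ",
         paste(missing, collapse = ", "))
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror [run_config()]; `datasets` entries give `path`, `labels` and
#' `platform`; `dag` gives `obo` and `annotations` paths; `interactions` a
#' path. Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML config path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  datasets <- lapply(y$datasets, function(d) {
    read_expression(rel(d$path), rel(d$labels),
                    platform = if (is.null(d$platform)) "microarray" else d$platform,
                    dataset_id = if (is.null(d$id)) basename(d$path) else d$id)
  })
  names(datasets) <- vapply(datasets, function(d) d$dataset_id, "")
  dag <- read_obo(rel(y$dag$obo),
                  annotations = read_annotations(rel(y$dag$annotations)),
                  namespace = y$dag$namespace)
  interactions <- read_interactions(rel(y$interactions))
  args <- y[setdiff(names(y), c("datasets", "dag", "interactions", "diseases"))]
  do.call(run_config, c(list(datasets = datasets,
                             diseases = lapply(y$diseases, unlist),
                             dag = dag, interactions = interactions),
                        args[names(args) %in% names(formals(run_config))]))
}

plog <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Run the full cross-disease similarity pipeline
#'
#' Stages, in order: restrict all datasets to their common genes; call DEGs
#' per dataset; intersect per disease; check the cross-disease DEG overlap;
#' score gene-set semantic similarity for every configured measure with a
#' Monte-Carlo permutation null (random gene sets of the observed sizes
#' drawn from the annotated background); build the thresholded interaction
#' network over the two DEG sets, rank hubs, and test cross-set connectivity
#' with the same permutation scheme; enrich each disease's DEG set and the
#' hub genes against the detected-gene background. Every filter logs
#' before/after counts. A stage failure aborts with a stage-named error;
#' when `out_dir` is set, completed stages are recorded in a `MANIFEST`
#' file and their outputs retained.
#'
#' @param config A [run_config()] (or a YAML path for [read_config()]).
#' @return Run report: nested list with elements `config` (parameters),
#'   `degs`, `disease_sets`, `overlap`, `similarity`, `network`,
#'   `enrichment`. Written as `report.json` plus TSV tables when `out_dir`
#'   is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  out_dir <- config$out_dir
  completed <- character()
  manifest <- function(stage) {
    completed <<- c(completed, stage)
    if (!is.null(out_dir))
      writeLines(completed, file.path(out_dir, "MANIFEST"))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(config = config[c("fc_threshold", "p_threshold",
                                   "ppi_threshold", "ss_measures",
                                   "n_perm_ss", "n_perm_net", "top_k_hubs",
                                   "fdr_cut", "seed")])

  ## -- preprocess -----------------------------------------------------------
  datasets <- stage("preprocess", {
    ds <- config$datasets
    n_before <- vapply(ds, function(d) nrow(d$matrix), integer(1))
    ds <- restrict_to_common_genes(ds)
    plog("preprocess: gene counts %s -> %d common genes",
         paste(n_before, collapse = "/"), nrow(ds[[1]]$matrix))
    ds
  })
  background <- rownames(datasets[[1]]$matrix)
  report$n_background <- length(background)
  manifest("preprocess")

  ## -- differential expression ---------------------------------------------
  deg_tables <- stage("degs", {
    lapply(datasets, function(d) {
      tab <- call_degs(d, config$fc_threshold, config$p_threshold)
      plog("degs: %s -> %d DEGs of %d genes", d$dataset_id, sum(tab$is_deg),
           nrow(tab))
      tab
    })
  })
  report$degs <- lapply(deg_tables, function(t)
    list(n_genes = nrow(t), n_deg = sum(t$is_deg)))
  if (!is.null(out_dir))
    for (id in names(deg_tables))
      utils::write.table(deg_tables[[id]],
                         file.path(out_dir, paste0("deg_", id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  manifest("degs")

  ## -- per-disease intersection --------------------------------------------
  disease_sets <- stage("intersect", {
    sets <- lapply(names(config$diseases), function(dz) {
      intersect_deg_sets(deg_tables[config$diseases[[dz]]], disease = dz)
    })
    names(sets) <- names(config$diseases)
    for (s in sets)
      if (!length(s$genes)) stop("empty DEG set for disease ", s$disease)
    sets
  })
  dzA <- names(config$diseases)[1]
  dzB <- names(config$diseases)[2]
  setA <- disease_sets[[dzA]]$genes
  setB <- disease_sets[[dzB]]$genes
  overlap <- intersect(setA, setB)
  plog("intersect: %s %d genes, %s %d genes, cross-disease overlap %d",
       dzA, length(setA), dzB, length(setB), length(overlap))
  report$disease_sets <- lapply(disease_sets, function(s)
    list(n = length(s$genes), genes = s$genes,
         dataset_sizes = unname(s$provenance)))
  report$overlap <- list(n = length(overlap), genes = overlap)
  if (!is.null(out_dir))
    for (dz in names(disease_sets))
      writeLines(disease_sets[[dz]]$genes,
                 file.path(out_dir, paste0("degset_", dz, ".txt")))
  manifest("intersect")

  ## -- semantic similarity with Monte-Carlo null ---------------------------
  report$similarity <- stage("similarity", {
    dag <- config$dag
    ic <- compute_ic(dag)
    pool <- intersect(background, names(dag$annotations))
    annA <- intersect(setA, pool)
    annB <- intersect(setB, pool)
    plog("similarity: annotated pool %d; %s %d/%d annotated, %s %d/%d",
         length(pool), dzA, length(annA), length(setA), dzB, length(annB),
         length(setB))
    if (!length(annA) || !length(annB))
      stop("a DEG set has no annotated genes")
    res <- list()
    for (measure in config$ss_measures) {
      sm <- suppressWarnings(
        gene_sim_matrix(pool, pool, measure, dag, ic))
      obs <- geneset_sim(annA, annB, sim_matrix = sm)
      perm <- permute_statistic(
        function(a, b) combine_sim(sm[a, b, drop = FALSE], "bma"),
        length(annA), length(annB), pool, config$n_perm_ss, config$seed,
        observed = obs, tail = "upper")
      plog("similarity: %s observed %.3f, p = %.4g (n = %d)", measure, obs,
           perm$pvalue, perm$n)
      res[[measure]] <- list(observed = obs, pvalue = perm$pvalue,
                             n_perm = perm$n,
                             null_mean = mean(perm$null_values),
                             null_values = perm$null_values)
    }
    if (!is.null(out_dir)) {
      ss_tab <- data.frame(measure = names(res),
                           observed = vapply(res, `[[`, 0, "observed"),
                           pvalue = vapply(res, `[[`, 0, "pvalue"),
                           null_mean = vapply(res, `[[`, 0, "null_mean"))
      utils::write.table(ss_tab, file.path(out_dir, "ss_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      null_tab <- as.data.frame(lapply(res, `[[`, "null_values"))
      utils::write.table(null_tab, file.path(out_dir, "ss_null_samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    lapply(res, function(r) r[setdiff(names(r), "null_values")])
  })
  manifest("similarity")

  ## -- interaction network --------------------------------------------------
  report$network <- stage("network", {
    net <- build_network(config$interactions, setA, setB,
                         config$ppi_threshold)
    hubs <- degree_and_hubs(net, config$top_k_hubs)
    conn <- connectivity_test(config$interactions, setA, setB,
                              pool = background, n = config$n_perm_net,
                              seed = config$seed,
                              threshold = config$ppi_threshold)
    plog("network: %d nodes (%d connected), %d edges, %d cross edges, p = %.4g",
         hubs$n_nodes_total, hubs$n_nodes_connected, hubs$n_edges,
         hubs$cross_edges, conn$pvalue)
    if (!is.null(out_dir)) {
      reg <- do.call(rbind, lapply(names(deg_tables), function(id) {
        t <- deg_tables[[id]]
        data.frame(gene = t$gene, dir = ifelse(t$log2fc >= 0, "up", "down"),
                   stringsAsFactors = FALSE)
      }))
      reg <- reg[!duplicated(reg$gene), , drop = FALSE]
      write_network(net, file.path(out_dir, "network"), node_extra = reg)
      utils::write.table(hubs$hubs, file.path(out_dir, "hub_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(n_nodes_total = hubs$n_nodes_total,
         n_nodes_connected = hubs$n_nodes_connected,
         n_edges = hubs$n_edges, cross_edges = hubs$cross_edges,
         connectivity_pvalue = conn$pvalue,
         null_mean = mean(conn$null_values),
         hubs = hubs$hubs)
  })
  manifest("network")

  ## -- enrichment ------------------------------------------------------------
  report$enrichment <- stage("enrichment", {
    queries <- list()
    queries[[dzA]] <- setA
    queries[[dzB]] <- setB
    queries$hubs <- unique(report$network$hubs$gene[
      report$network$hubs$degree > 0])
    res <- lapply(names(queries), function(nm) {
      if (!length(queries[[nm]])) return(empty_enrichment())
      tab <- suppressWarnings(
        enrich_terms(queries[[nm]], config$dag, background,
                     fdr_cut = config$fdr_cut))
      plog("enrichment: %s -> %d terms tested, %d significant at FDR < %g",
           nm, nrow(tab), sum(tab$significant), config$fdr_cut)
      if (!is.null(out_dir))
        utils::write.table(tab,
                           file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
    names(res) <- names(queries)
    res
  })
  manifest("enrichment")

  if (!is.null(out_dir)) {
    json_report <- report
    json_report$enrichment <- lapply(report$enrichment, function(t)
      t[t$significant, setdiff(names(t), "genes"), drop = FALSE])
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest("report")
  invisible(report)
}
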