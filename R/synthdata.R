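#' Synthetic two-disease study scenario
#'
#' Describes a complete synthetic study with known ground truth: two diseases
#' with two case/control datasets each, a planted set of truly differential
#' genes per disease (disjoint between diseases, mirroring real cross-disease
#' comparisons where the DEG overlap is empty), an ontology branch structure
#' that makes the two planted sets functionally coherent (or not), and an
#' interaction table with planted cross-disease edges over a sparse
#' background.
#'
#' Default sample sizes follow the four-dataset design the pipeline targets
#' (12/10 and 22/8 for disease A; 39/18 and 9/54 for disease B, case/control).
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it.
#' @param n_genes Gene universe size.
#' @param n_planted Planted DEGs per disease.
#' @param effect Absolute log2 shift of planted genes in case samples (half
#'   up-, half down-regulated).
#' @param noise_sd Per-observation Gaussian noise sd on the log2 scale.
#' @param sample_sizes List of two lists (`A`, `B`), each holding two
#'   `c(case, control)` pairs.
#' @param n_branches,branch_depth,leaves_per_branch Ontology branch count,
#'   internal chain depth and leaf terms per branch.
#' @param n_annotated_background Background genes annotated to random
#'   branches (the functional background pool).
#' @param shared_branch When `TRUE` (default) both diseases' planted genes
#'   are annotated under the same branch (high expected similarity); when
#'   `FALSE` under different branches.
#' @param ppi_background_p Bernoulli probability of a background interaction
#'   between two pool genes (scores above the 0.4 cutoff).
#' @param planted_cross_degree Planted cross-disease interactions per
#'   planted disease-A gene.
#' @param n_decoy_edges Sub-threshold edges (score <= 0.4) added as decoys.
#' @return Object of class `SyntheticScenario` with the parameters plus the
#'   derived gene universe and ground-truth sets `planted_A`, `planted_B`,
#'   `annotated_background`.
#' @export
synth_scenario <- function(seed = 1L, n_genes = 2000L, n_planted = 50L,
                           effect = 1.0, noise_sd = 0.5,
                           sample_sizes = list(
                             A = list(c(case = 12L, control = 10L),
                                      c(case = 22L, control = 8L)),
                             B = list(c(case = 39L, control = 18L),
                                      c(case = 9L, control = 54L))),
                           n_branches = 4L, branch_depth = 2L,
                           leaves_per_branch = 6L,
                           n_annotated_background = 400L,
                           shared_branch = TRUE,
                           ppi_background_p = 0.01,
                           planted_cross_degree = 2L,
                           n_decoy_edges = 50L) {
  if (2L * n_planted + n_annotated_background > n_genes)
    stop("planted and annotated gene counts exceed the gene universe")
  genes <- sprintf("g%05d", seq_len(n_genes))
  planted_A <- genes[seq_len(n_planted)]
  planted_B <- genes[n_planted + seq_len(n_planted)]
  annotated_background <- genes[2L * n_planted + seq_len(n_annotated_background)]
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_planted = n_planted, effect = effect, noise_sd = noise_sd,
                 sample_sizes = sample_sizes, n_branches = n_branches,
                 branch_depth = branch_depth,
                 leaves_per_branch = leaves_per_branch,
                 n_annotated_background = n_annotated_background,
                 shared_branch = shared_branch,
                 ppi_background_p = ppi_background_p,
                 planted_cross_degree = planted_cross_degree,
                 n_decoy_edges = n_decoy_edges,
                 genes = genes, planted_A = planted_A, planted_B = planted_B,
                 annotated_background = annotated_background),
            class = "SyntheticScenario")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed %% 2147483647L)
  code
}

#' Simulate the four expression datasets of a scenario
#'
#' Per dataset, baseline log2 intensity per gene is Normal(7, 1); planted
#' DEGs of the dataset's disease are shifted by the effect size in case
#' samples (sign alternating up/down); independent Gaussian noise with the
#' scenario's sd is added per observation. Values are already on the log2
#' scale; platform tags alternate rnaseq/microarray within each disease.
#'
#' @param scenario A [synth_scenario()].
#' @return Named list of four [expression_dataset()] objects
#'   (`A1`, `A2`, `B1`, `B2`).
#' @export
make_expression <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  planted <- list(A = sc$planted_A, B = sc$planted_B)
  platforms <- c("rnaseq", "microarray")
  out <- list()
  ds_index <- 0L
  for (disease in c("A", "B")) {
    for (k in 1:2) {
      ds_index <- ds_index + 1L
      sizes <- sc$sample_sizes[[disease]][[k]]
      n_case <- sizes[[1]]
      n_ctrl <- sizes[[2]]
      id <- paste0(disease, k)
      out[[id]] <- with_seed(sc$seed + 1000L * ds_index, {
        baseline <- stats::rnorm(sc$n_genes, mean = 7, sd = 1)
        m <- matrix(stats::rnorm(sc$n_genes * (n_case + n_ctrl),
                                 sd = sc$noise_sd),
                    nrow = sc$n_genes) + baseline
        sign <- rep(c(1, -1), length.out = sc$n_planted)
        rows <- match(planted[[disease]], sc$genes)
        m[rows, seq_len(n_case)] <- m[rows, seq_len(n_case)] +
          sign * sc$effect
        dimnames(m) <- list(sc$genes,
                            c(sprintf("%s_case_%02d", id, seq_len(n_case)),
                              sprintf("%s_ctrl_%02d", id, seq_len(n_ctrl))))
        expression_dataset(m,
                           rep(c("case", "control"), c(n_case, n_ctrl)),
                           platform = platforms[k], dataset_id = id)
      })
    }
  }
  out
}

#' Build the scenario's ontology DAG and annotation map
#'
#' One root; `n_branches` branches, each an is_a chain of `branch_depth`
#' internal terms ending in `leaves_per_branch` leaf terms (every third leaf
#' attached by part_of). Annotated background genes each receive 1-3 random
#' leaves of a single branch, branches filled toward equal annotation totals
#' so per-branch term frequencies (hence information content) are
#' comparable; disease A's planted genes annotate leaves of branch
#' 1, disease B's planted genes leaves of branch 1 (`shared_branch = TRUE`)
#' or branch 2.
#'
#' @param scenario A [synth_scenario()].
#' @return An [ontology_dag()] with annotations attached.
#' @export
make_dag <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  root <- "T:ROOT"
  edges <- list()
  leaves <- list()
  for (b in seq_len(sc$n_branches)) {
    chain <- sprintf("T:B%d_D%d", b, seq_len(sc$branch_depth))
    edges[[length(edges) + 1L]] <- data.frame(
      child = chain, parent = c(root, chain[-length(chain)]),
      type = "is_a", stringsAsFactors = FALSE)
    lv <- sprintf("T:B%d_L%d", b, seq_len(sc$leaves_per_branch))
    edges[[length(edges) + 1L]] <- data.frame(
      child = lv, parent = chain[length(chain)],
      type = ifelse(seq_along(lv) %% 3L == 0L, "part_of", "is_a"),
      stringsAsFactors = FALSE)
    leaves[[b]] <- lv
  }
  ann <- with_seed(sc$seed + 77L, {
    res <- list()
    # background genes fill branches toward equal annotation totals, so the
    # planted branch's term frequencies (hence IC) stay comparable to the
    # background branches'
    branch_totals <- integer(sc$n_branches)
    branch_totals[1L] <- branch_totals[1L] + sc$n_planted
    branch_B <- if (sc$shared_branch) 1L else 2L
    branch_totals[branch_B] <- branch_totals[branch_B] + sc$n_planted
    for (g in sc$annotated_background) {
      b <- which.min(branch_totals)
      branch_totals[b] <- branch_totals[b] + 1L
      res[[g]] <- sample(leaves[[b]], sample(1:3, 1L))
    }
    for (g in sc$planted_A)
      res[[g]] <- sample(leaves[[1L]], sample(1:3, 1L))
    for (g in sc$planted_B)
      res[[g]] <- sample(leaves[[branch_B]], sample(1:3, 1L))
    res
  })
  ontology_dag(do.call(rbind, edges), annotations = ann)
}

#' Simulate the scenario's scored interaction table
#'
#' Background edges between pool genes (planted plus annotated background)
#' appear with probability `ppi_background_p` and scores Uniform(0.41, 1),
#' so the retained density is controlled directly. Each planted disease-A
#' gene is wired to `planted_cross_degree` random planted disease-B genes
#' with scores Uniform(0.9, 1). Decoy edges carry scores Uniform(0.05, 0.4)
#' and must be removed by the 0.4 cutoff.
#'
#' @param scenario A [synth_scenario()].
#' @return `data.frame` with columns `a`, `b`, `score`.
#' @export
make_ppi <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  pool <- c(sc$planted_A, sc$planted_B, sc$annotated_background)
  with_seed(sc$seed + 555L, {
    n <- length(pool)
    n_pairs <- n * (n - 1) / 2
    n_bg <- stats::rbinom(1L, n_pairs, sc$ppi_background_p)
    pairs <- utils::combn(n, 2L)
    pick <- pairs[, sample(n_pairs, n_bg), drop = FALSE]
    bg <- data.frame(a = pool[pick[1L, ]], b = pool[pick[2L, ]],
                     score = stats::runif(n_bg, 0.41, 1),
                     stringsAsFactors = FALSE)
    planted <- do.call(rbind, lapply(sc$planted_A, function(g) {
      if (sc$planted_cross_degree < 1L) return(NULL)
      partners <- sample(sc$planted_B,
                         min(sc$planted_cross_degree, length(sc$planted_B)))
      data.frame(a = g, b = partners,
                 score = stats::runif(length(partners), 0.9, 1),
                 stringsAsFactors = FALSE)
    }))
    decoys <- NULL
    if (sc$n_decoy_edges > 0L) {
      da <- sample(pool, sc$n_decoy_edges, replace = TRUE)
      db <- sample(pool, sc$n_decoy_edges, replace = TRUE)
      keep <- da != db
      decoys <- data.frame(a = da[keep], b = db[keep],
                           score = stats::runif(sum(keep), 0.05, 0.4),
                           stringsAsFactors = FALSE)
    }
    out <- rbind(bg, planted, decoys)
    rownames(out) <- NULL
    out
  })
}
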