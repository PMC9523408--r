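# Shared fixtures, built in code.

# Three-branch toy ontology with hand-checkable annotation counts:
#   R <- b1 <- {t11 (is_a), t12 (part_of)}
#   R <- b2 <- t21
#   R <- b3 <- t31
# Annotations: gA:t11, gB:{t11,t12}, gC:t12, gD:t21, gE:t31, gF:b2
# Propagated counts (6 genes total): t11=2, t12=2, b1=3, t21=1, b2=2,
# t31=1, b3=1, R=6.
toy_dag <- function() {
  edges <- data.frame(
    child  = c("b1", "b2", "b3", "t11", "t12", "t21", "t31"),
    parent = c("R", "R", "R", "b1", "b1", "b2", "b3"),
    type   = c("is_a", "is_a", "is_a", "is_a", "part_of", "is_a", "is_a"),
    stringsAsFactors = FALSE)
  ann <- list(gA = "t11", gB = c("t11", "t12"), gC = "t12",
              gD = "t21", gE = "t31", gF = "b2")
  ontology_dag(edges, annotations = ann)
}

# Small expression dataset with optional planted log2 shifts in case samples.
toy_expression <- function(n_genes = 50, n_case = 5, n_control = 5,
                           shift_genes = character(), shift = 0,
                           noise_sd = 0.3, seed = 1, id = "toy") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * (n_case + n_control), mean = 7, sd = noise_sd),
              nrow = n_genes,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_case + n_control))))
  m[match(shift_genes, genes), seq_len(n_case)] <-
    m[match(shift_genes, genes), seq_len(n_case)] + shift
  expression_dataset(m, rep(c("case", "control"), c(n_case, n_control)),
                     dataset_id = id)
}

# Random rooted DAG for property tests: term i>1 gets 1-2 parents among
# earlier terms; random annotations.
random_dag <- function(seed, n_terms = 15, n_genes = 12) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n_terms))
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
    data.frame(child = terms[i], parent = terms[parents],
               type = sample(c("is_a", "part_of"), length(parents),
                             replace = TRUE, prob = c(0.8, 0.2)),
               stringsAsFactors = FALSE)
  }))
  genes <- sprintf("gene%02d", seq_len(n_genes))
  ann <- lapply(genes, function(g) sample(terms, sample(1:3, 1)))
  names(ann) <- genes
  ontology_dag(edges, annotations = ann)
}

# Independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to the case group and count U (computed by pairwise comparison, not
# rank sums) at least as far from its null mean as observed.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Independent hypergeometric oracle: enumerate all draws of size k from a
# population with m successes and count draws with >= t successes.
hyper_enumeration_oracle <- function(t, k, m, n) {
  pop <- c(rep(1, m), rep(0, n - m))
  combs <- utils::combn(n, k)
  mean(colSums(matrix(pop[combs], nrow = k)) >= t)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Attach sample colnames to a bare matrix (rownames assumed set).
m_named <- function(m, n = ncol(m)) {
  colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}
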