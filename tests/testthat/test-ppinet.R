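test_that("build_network applies a strict threshold and canonical edges", {
  inter <- data.frame(a = c("x", "x", "y", "z", "x"),
                      b = c("y", "y", "x", "z", "w"),
                      score = c(0.4, 0.8, 0.8, 0.9, 0.5))
  net <- quiet(build_network(inter, nodesA = c("x", "z"), nodesB = c("y", "w")))
  # the 0.4 edge is excluded (strict >), the self-loop dropped,
  # (x,y)/(y,x) collapse to one canonical edge
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$a <= net$edges$b))
  expect_equal(sum(net$edges$a == "x" & net$edges$b == "y"), 1L)
  # isolated node z is retained
  expect_true("z" %in% net$nodes$gene)
  rep <- degree_and_hubs(net)
  expect_equal(unname(rep$degrees["z"]), 0L)
  expect_equal(rep$n_nodes_total, 4L)
  expect_equal(rep$n_nodes_connected, 3L)
})

test_that("malformed scores are rejected with a count", {
  inter <- data.frame(a = c("x", "x"), b = c("y", "w"), score = c(1.7, 0.9))
  expect_message(net <- build_network(inter, "x", c("y", "w")), "rejected")
  expect_equal(nrow(net$edges), 1L)
})

test_that("degrees satisfy the handshake lemma and hubs rank by degree then name", {
  set.seed(8)
  genes <- sprintf("n%02d", 1:20)
  inter <- data.frame(a = sample(genes, 60, replace = TRUE),
                      b = sample(genes, 60, replace = TRUE),
                      score = runif(60, 0.5, 1))
  net <- build_network(inter, genes[1:10], genes[11:20])
  rep <- degree_and_hubs(net, top_k = 5)
  expect_equal(sum(rep$degrees), 2L * nrow(net$edges))
  a_hubs <- rep$hubs[rep$hubs$disease == "A", ]
  expect_true(all(diff(a_hubs$degree) <= 0))

  # star graph: center degree 5, leaves 1; ties broken by name
  star <- data.frame(a = "hub", b = paste0("leaf", 1:5), score = 0.9)
  snet <- build_network(star, c("hub", "leaf1"), paste0("leaf", 2:5))
  srep <- degree_and_hubs(snet, top_k = 3)
  expect_equal(unname(srep$degrees["hub"]), 5L)
  expect_true(all(srep$degrees[paste0("leaf", 1:5)] == 1L))
  b_hubs <- srep$hubs[srep$hubs$disease == "B", ]
  expect_identical(b_hubs$gene, c("leaf2", "leaf3", "leaf4"))
})

test_that("cross edges count edges joining the two sets, symmetrically", {
  # path a(A) - b(B) - c(A): both edges cross
  inter <- data.frame(a = c("a", "b"), b = c("b", "c"), score = 0.9)
  net <- build_network(inter, c("a", "c"), "b")
  expect_equal(sum(net$edges$cross), 2L)
  swapped <- build_network(inter, "b", c("a", "c"))
  expect_equal(sum(swapped$edges$cross), 2L)

  empty <- build_network(inter[0, ], c("a", "c"), "b")
  expect_equal(degree_and_hubs(empty)$cross_edges, 0L)
  expect_true(all(degree_and_hubs(empty)$degrees == 0L))
})

test_that("connectivity_test returns p = 1 with no cross-pool edges and is deterministic", {
  pool <- sprintf("p%02d", 1:30)
  none <- data.frame(a = character(), b = character(), score = numeric())
  res <- connectivity_test(none, pool[1:5], pool[6:10], pool, n = 99, seed = 3)
  expect_equal(res$observed, 0)
  expect_true(all(res$null_values == 0))
  expect_equal(res$pvalue, 1)

  set.seed(12)
  inter <- data.frame(a = sample(pool, 40, replace = TRUE),
                      b = sample(pool, 40, replace = TRUE),
                      score = runif(40, 0.5, 1))
  r1 <- connectivity_test(inter, pool[1:5], pool[6:10], pool, n = 99, seed = 5)
  r2 <- connectivity_test(inter, pool[1:5], pool[6:10], pool, n = 99, seed = 5)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$pvalue, r2$pvalue)
})

test_that("planted cross-set wiring over a sparse background is detected", {
  set.seed(77)
  pool <- sprintf("p%03d", 1:200)
  A <- pool[1:12]
  B <- pool[13:24]
  planted <- do.call(rbind, lapply(A, function(g)
    data.frame(a = g, b = sample(B, 3), score = runif(3, 0.9, 1))))
  n_bg <- rbinom(1, length(pool) * (length(pool) - 1) / 2, 0.01)
  bg <- data.frame(a = sample(pool, n_bg, replace = TRUE),
                   b = sample(pool, n_bg, replace = TRUE),
                   score = runif(n_bg, 0.41, 1))
  res <- connectivity_test(rbind(planted, bg), A, B, pool, n = 999, seed = 13)
  expect_gte(res$observed, 30)
  expect_lte(res$pvalue, 0.01)
})

test_that("connectivity p-values are super-uniform under an Erdos-Renyi null", {
  set.seed(99)
  pool <- sprintf("p%03d", 1:60)
  pvals <- vapply(1:40, function(i) {
    n_e <- rbinom(1, 400, 0.15)
    inter <- data.frame(a = sample(pool, n_e, replace = TRUE),
                        b = sample(pool, n_e, replace = TRUE),
                        score = runif(n_e, 0.5, 1))
    sets <- sample(pool, 16)
    connectivity_test(inter, sets[1:8], sets[9:16], pool,
                      n = 99, seed = 1000 + i)$pvalue
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.15)  # 40 runs: generous binomial slack
})

test_that("interaction reader handles STRING-style 0-1000 scores and headers", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score",
               "geneA geneB 900", "geneA geneC 400", "geneB geneC 150"), path)
  tab <- read_interactions(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$score, c(0.9, 0.4, 0.15))
  net <- build_network(tab, c("geneA"), c("geneB", "geneC"))
  expect_equal(nrow(net$edges), 1L)  # only the 0.9 edge survives > 0.4
})

test_that("network export writes edge list, SIF and node attributes", {
  dir <- withr::local_tempdir()
  inter <- data.frame(a = "x", b = "y", score = 0.9)
  net <- build_network(inter, "x", c("y", "z"))
  paths <- write_network(net, file.path(dir, "net"))
  expect_true(all(file.exists(paths)))
  sif <- readLines(file.path(dir, "net.sif"))
  expect_identical(sif, "x pp y")
  nodes <- read.delim(file.path(dir, "net_nodes.tsv"))
  expect_setequal(nodes$gene, c("x", "y", "z"))
  expect_equal(nodes$degree[nodes$gene == "z"], 0L)
})
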