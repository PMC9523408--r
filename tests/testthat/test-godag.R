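# Hand-derived facts about the toy DAG (see helper-fixtures.R):
# propagated counts t11=2, t12=2, b1=3, t21=1, b2=2, t31=1, b3=1, R=6,
# so ic(t11)=ic(t12)=ln 3, ic(b1)=ln 2, ic(t21)=ic(t31)=ln 6, ic(R)=0.
# Wang S-values: S(t11)={t11:1, b1:.8, R:.64}, S(t12)={t12:1, b1:.6, R:.48},
# S(t21)={t21:1, b2:.8, R:.64}.

test_that("information content matches hand propagation on the toy DAG", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  expect_equal(ic$ic[["R"]], 0)
  expect_equal(ic$p[["t11"]], 2 / 6)
  expect_equal(ic$ic[["t11"]], log(3), tolerance = 1e-12)
  expect_equal(ic$ic[["b1"]], log(2), tolerance = 1e-12)  # gB counted once
  expect_equal(ic$ic[["t21"]], log(6), tolerance = 1e-12)

  # 2-term chain: root <- A, genes g1,g2 on A, g3 on root
  dag2 <- ontology_dag(data.frame(child = "A", parent = "root"),
                       annotations = list(g1 = "A", g2 = "A", g3 = "root"))
  ic2 <- compute_ic(dag2)
  expect_equal(ic2$p[["A"]], 2 / 3)
  expect_equal(ic2$ic[["A"]], -log(2 / 3), tolerance = 1e-12)
})

test_that("a gene reaching an ancestor via two paths is counted once", {
  dag <- ontology_dag(
    data.frame(child = c("P1", "P2", "C", "C"),
               parent = c("R", "R", "P1", "P2")),
    annotations = list(g = "C"))
  ic <- compute_ic(dag)
  expect_equal(unname(ic$counts[c("C", "P1", "P2", "R")]), c(1L, 1L, 1L, 1L))
})

test_that("IC is monotonically non-decreasing from parent to child", {
  for (seed in 1:5) {
    dag <- random_dag(seed)
    ic <- suppressWarnings(compute_ic(dag))
    for (i in seq_len(nrow(dag$edges))) {
      child <- dag$edges$child[i]
      parent <- dag$edges$parent[i]
      if (!is.na(ic$ic[[child]]) && !is.na(ic$ic[[parent]]))
        expect_gte(ic$ic[[child]], ic$ic[[parent]] - 1e-12)
    }
  }
})

test_that("mica returns the max-IC common ancestor with lexicographic ties", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  expect_identical(mica("t11", "t11", dag, ic), "t11")   # self-ancestor
  expect_identical(mica("t11", "t12", dag, ic), "b1")
  expect_identical(mica("t11", "t21", dag, ic), "R")     # siblings via root
  expect_identical(mica("t11", "b1", dag, ic), "b1")     # parent/child

  # tie between two equal-IC common ancestors -> smallest id
  dag2 <- ontology_dag(
    data.frame(child = c("Pa", "Pb", "C1", "C1", "C2", "C2"),
               parent = c("R", "R", "Pa", "Pb", "Pa", "Pb")),
    annotations = list(g1 = "C1", g2 = "C2", g3 = "R"))
  ic2 <- compute_ic(dag2)
  expect_equal(ic2$ic[["Pa"]], ic2$ic[["Pb"]])
  expect_identical(mica("C1", "C2", dag2, ic2), "Pa")
})

test_that("all five measures match hand-computed values on the toy DAG", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  terms <- c("t11", "t12", "t21")
  oracle <- list(
    resnik = rbind(c(log(3), log(2), 0),
                   c(log(2), log(3), 0),
                   c(0,      0,      log(6))),
    lin    = rbind(c(1,               log(2) / log(3), 0),
                   c(log(2) / log(3), 1,               0),
                   c(0,               0,               1)),
    jiang  = rbind(c(1,                1 - log(9 / 4), 0),
                   c(1 - log(9 / 4),  1,               0),
                   c(0,               0,               1)),
    rel    = rbind(c(2 / 3,                 log(2) / (2 * log(3)), 0),
                   c(log(2) / (2 * log(3)), 2 / 3,                 0),
                   c(0,                     0,                     5 / 6)),
    wang   = rbind(c(1,           2.52 / 4.52, 1.28 / 4.88),
                   c(2.52 / 4.52, 1,           1.12 / 4.52),
                   c(1.28 / 4.88, 1.12 / 4.52, 1)))
  for (measure in names(oracle)) {
    got <- term_sim_matrix(terms, terms, measure, dag, ic)
    expect_equal(unname(got), unname(oracle[[measure]]), tolerance = 1e-9,
                 info = measure)
  }
})

test_that("wang S-value propagation matches the 3-term chain by hand", {
  dag <- ontology_dag(data.frame(child = c("P", "C"), parent = c("root", "P"),
                                 type = "is_a"),
                      annotations = list(g = "C"))
  expect_equal(term_sim("C", "P", "wang", dag), 3.24 / 4.24, tolerance = 1e-12)
})

test_that("term similarity is symmetric and bounded on random DAGs", {
  for (seed in 1:4) {
    dag <- random_dag(seed)
    ic <- suppressWarnings(compute_ic(dag))
    set.seed(seed)
    pairs <- replicate(8, sample(dag$terms, 2), simplify = FALSE)
    for (p in pairs) {
      for (measure in c("wang", "resnik", "lin", "jiang", "rel")) {
        s12 <- term_sim(p[1], p[2], measure, dag, ic)
        s21 <- term_sim(p[2], p[1], measure, dag, ic)
        expect_equal(s12, s21, tolerance = 1e-12, info = measure)
        expect_gte(s12, 0)
        if (measure != "resnik") expect_lte(s12, 1 + 1e-12)
      }
    }
  }
})

test_that("gene-set similarity honors identity, singleton and disjoint cases", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  s <- c("gA", "gB", "gD")
  for (measure in c("wang", "lin", "jiang"))
    expect_equal(geneset_sim(s, s, measure, dag, ic), 1, tolerance = 1e-9,
                 info = measure)

  # two singletons sharing a single identical term = term self-similarity
  expect_equal(geneset_sim("gA", "gA", "rel", dag, ic),
               term_sim("t11", "t11", "rel", dag, ic))

  # disjoint branches meeting only at the root
  for (measure in c("lin", "jiang", "rel"))
    expect_lt(geneset_sim("gD", "gE", measure, dag, ic), 0.1)
  expect_equal(geneset_sim("gD", "gE", "wang", dag, ic), 1.28 / 4.88,
               tolerance = 1e-9)
  expect_equal(geneset_sim("gD", "gE", "resnik", dag, ic), 0)
})

test_that("gene-set similarity ignores gene order, duplicates and unannotated genes", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  a <- c("gA", "gB")
  b <- c("gC", "gD")
  base <- geneset_sim(a, b, "wang", dag, ic)
  expect_equal(geneset_sim(rev(a), rev(b), "wang", dag, ic), base)
  expect_equal(geneset_sim(c(a, a), b, "wang", dag, ic), base)
  expect_warning(withdrop <- geneset_sim(c(a, "unknown"), b, "wang", dag, ic),
                 "unannotated")
  expect_equal(withdrop, base)
  expect_error(suppressWarnings(geneset_sim(c("nope", "nada"), b, "wang", dag, ic)),
               "empty")
})

test_that("a precomputed gene similarity matrix reproduces direct scoring", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  genes <- c("gA", "gB", "gC", "gD", "gE", "gF")
  sm <- gene_sim_matrix(genes, genes, "lin", dag, ic)
  expect_equal(unname(sm), unname(t(sm)), tolerance = 1e-12)
  expect_equal(geneset_sim(c("gA", "gB"), c("gC", "gD"), sim_matrix = sm),
               geneset_sim(c("gA", "gB"), c("gC", "gD"), "lin", dag, ic),
               tolerance = 1e-12)
})

test_that("OBO and annotation files round-trip through the parsers", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: R", "name: root", "namespace: biological_process", "",
    "[Term]", "id: B1", "name: branch one", "namespace: biological_process",
    "is_a: R ! root", "",
    "[Term]", "id: B2", "name: branch two", "namespace: biological_process",
    "relationship: part_of R ! root",
    "relationship: regulates B1 ! branch one", "",
    "[Term]", "id: OLD", "name: gone", "is_obsolete: true", "is_a: R", "",
    "[Typedef]", "id: part_of"), obo)
  ann_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tB1", "g2\tB2", "g2\tR"), ann_path)
  dag <- quiet(read_obo(obo, annotations = read_annotations(ann_path)))
  expect_setequal(dag$terms, c("R", "B1", "B2"))
  expect_identical(dag$roots, "R")
  expect_identical(dag$edges$type[dag$edges$child == "B2"], "part_of")
  expect_setequal(dag$annotations$g2, c("B2", "R"))
})

test_that("DAG construction rejects cycles and unknown annotation targets", {
  expect_error(ontology_dag(data.frame(child = c("A", "B"), parent = c("B", "A"))),
               "cycle|root")
  expect_error(ontology_dag(data.frame(child = "A", parent = "R"),
                            annotations = list(g = "Z")), "unknown")
})
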