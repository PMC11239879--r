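test_that("annotation propagation closes sets under ancestry", {
  dag <- make_test_dag()
  ann <- propagate_annotations(dag, data.frame(gene = "g1", term = "C"))
  expect_setequal(ann$g1, c("C", "B", "A", "root"))
  expect_length(propagate_annotations(dag, data.frame(gene = character(),
                                                      term = character())),
                0L)
  expect_error(propagate_annotations(dag, data.frame(gene = "g", term = "X")),
               "unknown term")
})

test_that("propagation equals an igraph reachability oracle on random DAGs", {
  for (s in 1:20) {
    dag <- random_dag(12L, seed = s)
    terms <- names(dag$parents)
    picked <- sample(terms, 3L)
    ann <- propagate_annotations(dag, data.frame(gene = "g",
                                                 term = picked))
    expect_identical(ann$g, igraph_closure(dag, picked))
  }
})

test_that("cycles are rejected", {
  expect_error(ontology_dag(list(A = "B", B = "A"),
                            c(A = "BP", B = "BP")), "cycle")
})

test_that("fisher enrichment equals the hypergeometric tail oracle", {
  ## one term annotating 50 of 1000 background genes, 10 of 20 study genes
  genes <- sprintf("g%04d", 1:1000)
  study <- genes[1:20]
  annotated <- c(genes[1:10], genes[21:60])  # k = 10, K = 50
  dag <- ontology_dag(list(T1 = character()), c(T1 = "BP"))
  ann <- propagate_annotations(dag, data.frame(gene = annotated,
                                               term = "T1"))
  row <- fisher_enrich(study, genes, ann, dag, "BP")
  expect_identical(c(row$k, row$K, row$n, row$N), c(10L, 50L, 20L, 1000L))
  expect_equal(row$fisher_p, hyper_tail(10, 50, 20, 1000),
               tolerance = 1e-10)
  ## sample odds ratio
  expect_equal(row$odds_ratio, (10 * (1000 - 50 - 20 + 10)) /
                 ((20 - 10) * (50 - 10)), tolerance = 1e-12)
})

test_that("degenerate enrichment tables behave conventionally", {
  genes <- sprintf("g%02d", 1:30)
  dag <- ontology_dag(list(T1 = character()), c(T1 = "BP"))
  ann_all <- propagate_annotations(dag, data.frame(gene = genes,
                                                   term = "T1"))
  ## a term annotating every background gene: p = 1, odds ratio 1
  row <- fisher_enrich(genes[1:5], genes, ann_all, dag, "BP")
  expect_equal(row$fisher_p, 1)
  expect_equal(row$odds_ratio, 1)
  ## study set = background: all p = 1
  row2 <- fisher_enrich(genes, genes, ann_all, dag, "BP")
  expect_true(all(row2$fisher_p == 1))
  expect_error(fisher_enrich(character(), genes, ann_all, dag, "BP"),
               "empty study")
  expect_error(fisher_enrich("zz", genes, ann_all, dag, "BP"), "subset")
})

test_that("Fisher p matches the oracle across a grid of tables", {
  dag <- ontology_dag(list(T1 = character()), c(T1 = "BP"))
  N <- 200L
  genes <- sprintf("g%03d", 1:N)
  for (K in c(5L, 40L, 120L)) for (k in c(0L, 2L, 5L)) {
    n <- 20L
    annotated <- c(genes[seq_len(k)], genes[n + seq_len(K - k)])
    ann <- propagate_annotations(dag, data.frame(gene = annotated,
                                                 term = "T1"))
    row <- fisher_enrich(genes[1:n], genes, ann, dag, "BP")
    expect_equal(row$fisher_p, hyper_tail(k, K, n, N), tolerance = 1e-10)
  }
})

test_that("ranking and pruning keep the most specific significant terms", {
  dag <- make_test_dag()
  rows <- data.frame(term = c("A", "B", "C", "D"),
                     k = 5L, K = 10L, n = 10L, N = 100L,
                     odds_ratio = c(5, 7, 9, 3),
                     fisher_p = c(1e-4, 1e-4, 1e-4, 2e-3))
  sel <- rank_and_prune(rows, dag, adjust = "none")
  ## chain A -> B -> C all pass: only the leaf C survives pruning
  expect_identical(sel$term[sel$retained], c("C", "D"))
  expect_identical(sel$term, c("C", "B", "A", "D"))  # odds-ratio order
  ## pruning is idempotent
  sel2 <- rank_and_prune(sel[sel$retained, names(rows)], dag,
                         adjust = "none")
  expect_true(all(sel2$retained))
  ## alpha cut and top_n truncation
  expect_identical(nrow(rank_and_prune(rows, dag, top_n = 2L,
                                       adjust = "none")), 2L)
  none <- rank_and_prune(transform(rows, fisher_p = 0.9), dag)
  expect_identical(nrow(none), 0L)
})

test_that("pruning removes only ancestors of retained terms", {
  for (s in 1:10) {
    dag <- random_dag(10L, seed = s + 300)
    terms <- names(dag$parents)
    rows <- data.frame(term = terms, k = 3L, K = 6L, n = 10L, N = 50L,
                       odds_ratio = seq_along(terms),
                       fisher_p = 1e-5)
    sel <- rank_and_prune(rows, dag, adjust = "none")
    anc <- ciliomics:::term_ancestors(dag)
    kept <- sel$term[sel$retained]
    dropped <- sel$term[!sel$retained]
    for (d in dropped)
      expect_true(any(vapply(kept, function(k2) d %in% anc[[k2]], NA)))
    for (k2 in kept)
      expect_false(any(vapply(kept, function(o) k2 %in% anc[[o]], NA)))
  }
})

test_that("ontology files round-trip through the edge-list and OBO readers", {
  edge_tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term\tparent\tnamespace",
               "GO:1\t\tBP", "GO:2\tGO:1\tBP", "GO:3\tGO:2\tBP",
               "GO:9\t\tCC"), edge_tsv)
  dag <- read_ontology_edges(edge_tsv)
  expect_setequal(names(dag$parents), c("GO:1", "GO:2", "GO:3", "GO:9"))
  expect_identical(dag$parents[["GO:3"]], "GO:2")

  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002",
               "namespace: biological_process",
               "is_a: GO:0000001 ! parent term", "",
               "[Typedef]", "id: part_of"), obo)
  dag2 <- read_obo_minimal(obo)
  expect_setequal(names(dag2$parents), c("GO:0000001", "GO:0000002"))
  expect_identical(dag2$parents[["GO:0000002"]], "GO:0000001")
  expect_identical(unname(dag2$namespace), c("BP", "BP"))
})
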