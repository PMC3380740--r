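test_that("OBO parsing builds the DAG and skips obsolete terms", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2",
               "",
               "[Term]",
               "id: R",
               "name: root",
               "namespace: biological_process",
               "",
               "[Term]",
               "id: A",
               "name: a",
               "namespace: biological_process",
               "is_a: R ! root",
               "",
               "[Term]",
               "id: B",
               "name: b",
               "namespace: biological_process",
               "is_a: R ! root",
               "",
               "[Term]",
               "id: OLD",
               "name: gone",
               "is_obsolete: true",
               "",
               "[Typedef]",
               "id: part_of"), f)
  dag <- parse_obo(f)
  expect_equal(nrow(dag$terms), 3)
  expect_equal(nrow(dag$edges), 2)
  expect_false("OLD" %in% dag$terms$id)
  expect_equal(dag$roots, "R")

  # stanza-count oracle: terms = [Term] stanzas minus obsolete ones
  txt <- readLines(f)
  expect_equal(nrow(dag$terms),
               sum(txt == "[Term]") - sum(grepl("^is_obsolete: true", txt)))
})

test_that("OBO writing round-trips through the parser", {
  world <- generate_go_world(list(depth = 3, branching = 2,
                                  n_background_genes = 6,
                                  terms_per_gene = 2), c("gX", "gY"))
  f <- tempfile(fileext = ".obo")
  write_obo(world$dag, f)
  back <- parse_obo(f)
  expect_equal(sort(back$terms$id), sort(world$dag$terms$id))
  expect_equal(nrow(back$edges), nrow(world$dag$edges))
  # relationship lines preserved as typed edges
  expect_setequal(unique(back$edges$type), unique(world$dag$edges$type))
})

test_that("cyclic ontologies are rejected", {
  expect_error(
    go_dag(data.frame(id = c("X", "Y"), name = NA, namespace = "bp"),
           data.frame(child = c("X", "Y"), parent = c("Y", "X"),
                      type = "is_a")),
    "cyclic")
})

test_that("Wang similarity follows the S-value recursion", {
  dag <- toy_dag()
  expect_equal(term_similarity(dag, "A", "A"), 1)
  expect_equal(term_similarity(dag, "A", "B"), 1.6 / 3.6)
  expect_equal(term_similarity(dag, "A", "B"),
               term_similarity(dag, "B", "A"))
  sv <- term_svalues(dag, "A")
  expect_equal(sv[["A"]], 1)
  expect_equal(sv[["R"]], 0.8)

  # part_of edge weight 0.6: hand-computed S-values and similarity
  dag2 <- toy_dag_partof()
  svc <- term_svalues(dag2, "C")
  expect_equal(svc[["C"]], 1)
  expect_equal(svc[["A"]], 0.6)
  expect_equal(svc[["R"]], 0.48)
  # sim(C, A): common ancestors {A, R}
  expect_equal(term_similarity(dag2, "C", "A"),
               (0.6 + 1 + 0.48 + 0.8) / (2.08 + 1.8))

  expect_error(term_similarity(dag, "A", "ZZ"), "unknown term")
})

test_that("similarity is 0 across namespaces and bounded in [0,1]", {
  dag <- go_dag(data.frame(id = c("R1", "A1", "R2", "A2"), name = NA,
                           namespace = c("biological_process",
                                         "biological_process",
                                         "molecular_function",
                                         "molecular_function")),
                data.frame(child = c("A1", "A2"), parent = c("R1", "R2"),
                           type = "is_a"))
  expect_equal(term_similarity(dag, "A1", "A2"), 0)

  world <- generate_go_world(list(depth = 3, branching = 3,
                                  n_background_genes = 4,
                                  terms_per_gene = 2), "g1")
  ids <- world$dag$terms$id
  withr_seed(17, {
    for (i in 1:30) {
      pair <- sample(ids, 2)
      s <- term_similarity(world$dag, pair[1], pair[2])
      expect_gte(s, 0); expect_lte(s, 1)
      expect_lt(s, 1)   # distinct terms in a tree are never identical
    }
  })
})

test_that("term-gene and term-geneset scores are annotation averages", {
  dag <- toy_dag()
  ann <- annotation_map(list(g1 = "A", g2 = c("A", "B"), g3 = "B"), dag)
  expect_equal(term_gene_similarity(dag, "A", "g1", ann), 1)
  expect_equal(term_gene_similarity(dag, "A", "g2", ann),
               (1 + 1.6 / 3.6) / 2)
  expect_error(term_gene_similarity(dag, "A", "missing", ann),
               "no annotations")

  # singleton set reduces to the gene score
  expect_equal(term_geneset_similarity(dag, "A", "g2", ann),
               term_gene_similarity(dag, "A", "g2", ann))
  # plain arithmetic mean over annotated genes
  expect_equal(term_geneset_similarity(dag, "A", c("g1", "g3"), ann),
               (1 + 1.6 / 3.6) / 2)
  # unannotated genes are dropped, not scored zero
  expect_equal(term_geneset_similarity(dag, "A", c("g1", "nope"), ann), 1)
  expect_error(term_geneset_similarity(dag, "A", "nope", ann),
               "no annotated")
  # averaging invariance: identical annotation sets
  ann2 <- annotation_map(list(x = c("A", "B"), y = c("A", "B")), dag)
  expect_equal(term_geneset_similarity(dag, "B", c("x", "y"), ann2),
               term_gene_similarity(dag, "B", "x", ann2))
})

test_that("annotation maps drop unknown terms with a warning", {
  dag <- toy_dag()
  expect_warning(ann <- annotation_map(list(g1 = c("A", "NOPE"),
                                            g2 = "NOPE"), dag),
                 "unknown term")
  expect_equal(ann$g1, "A")
  expect_false("g2" %in% names(ann))
})

test_that("gap score measures relative excess and handles S(t,G)=0", {
  dag <- toy_dag()
  ann <- annotation_map(list(h1 = "A", h2 = "A", b1 = "B", b2 = "B"), dag)
  hg <- c("h1", "h2"); g_all <- c("h1", "h2", "b1", "b2")
  s_hg <- term_geneset_similarity(dag, "A", hg, ann)
  s_g <- term_geneset_similarity(dag, "A", g_all, ann)
  expect_equal(gap_score(dag, "A", hg, g_all, ann), (s_hg - s_g) / s_g)
  # identical sets give zero gap
  expect_equal(gap_score(dag, "A", g_all, g_all, ann), 0)
  expect_gte(gap_score(dag, "B", hg, g_all, ann), -1)

  # a term in a foreign namespace has similarity 0 to every gene
  dag2 <- go_dag(rbind(dag$terms,
                       data.frame(id = "M", name = "mf",
                                  namespace = "molecular_function")),
                 dag$edges)
  ann2 <- annotation_map(list(h1 = "A", b1 = "B"), dag2)
  expect_warning(g <- gap_score(dag2, "M", "h1", c("h1", "b1"), ann2),
                 "gap set to 0")
  expect_equal(g, 0)
})

test_that("gap ranking is deterministic with ties broken by term id", {
  dag <- toy_dag()
  ann <- annotation_map(list(h1 = "A", b1 = "B"), dag)
  one <- rank_terms_by_gap(dag, "h1", c("h1", "b1"), ann, terms = "A")
  expect_equal(one$term, "A")

  # symmetric construction: A and B have equal-magnitude gaps of opposite
  # sign; the root sits between them; ties (none here) would sort by id
  rk <- rank_terms_by_gap(dag, "h1", c("h1", "b1"), ann)
  expect_equal(rk$term[1], "A")
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$gap) <= 0))

  # explicit tie: two marked leaves with identical annotation geometry
  world <- generate_go_world(list(depth = 2, branching = 2,
                                  n_background_genes = 4,
                                  terms_per_gene = 1), "hgA")
  rk2 <- rank_terms_by_gap(world$dag, "hgA", world$all_genes,
                           world$annotations)
  eq <- rk2[abs(rk2$gap - rk2$gap[1]) < 1e-12, ]
  expect_equal(eq$term, sort(eq$term))
})

test_that("marked-subtree enrichment is recovered by the gap ranking", {
  world <- generate_go_world(list(depth = 3, branching = 3,
                                  n_background_genes = 30,
                                  terms_per_gene = 3),
                             c("tf1", "tf2", "tf3"))
  rk <- rank_terms_by_gap(world$dag, c("tf1", "tf2", "tf3"),
                          world$all_genes, world$annotations)
  marked <- rk$gap[rk$term %in% world$marked_terms]
  unmarked <- rk$gap[!rk$term %in% world$marked_terms]
  expect_gt(min(marked), max(unmarked))
  expect_true(all(marked > 0))
})

test_that("reference-term scores reduce and average correctly", {
  dag <- toy_dag()
  ann <- annotation_map(list(g = c("A", "B")), dag)
  expect_equal(gene_to_reference_terms(dag, "g", "A", ann),
               term_gene_similarity(dag, "A", "g", ann))
  expect_equal(gene_to_reference_terms(dag, "g", c("A", "B"), ann),
               mean(c(term_gene_similarity(dag, "A", "g", ann),
                      term_gene_similarity(dag, "B", "g", ann))))
  expect_error(gene_to_reference_terms(dag, "g", character(0), ann),
               "non-empty")
})

test_that("GAF and two-column annotation files are both readable", {
  dag <- toy_dag()
  tsv <- tempfile()
  writeLines(c("g1\tA", "g2\tB"), tsv)
  a1 <- read_annotations(tsv, dag)
  expect_equal(a1$g1, "A")

  gaf <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               paste(c("DB", "ID1", "g1", "", "A", rep("", 12)),
                     collapse = "\t"),
               paste(c("DB", "ID2", "g2", "", "B", rep("", 12)),
                     collapse = "\t")), gaf)
  a2 <- read_annotations(gaf, dag)
  expect_equal(a2$g2, "B")
})
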