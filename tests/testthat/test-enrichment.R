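test_that("annotation propagation follows the true-path rule", {
  dag <- toy_chain_dag()
  annot <- build_annotation(dag, data.frame(gene = c("g1", "g2"),
                                            term = c("C", "B")))
  expect_setequal(annot$gene_to_terms$g1, "C")       # direct map untouched
  expect_setequal(annot$term_to_genes$C, "g1")
  expect_setequal(annot$term_to_genes$A, "g1")
  expect_setequal(annot$term_to_genes$R, c("g1", "g2"))  # root collects everyone

  expect_warning(
    ann2 <- build_annotation(dag, data.frame(gene = c("g1", "g1"),
                                             term = c("A", "ZZ:1"))),
    "ZZ:1"
  )
  expect_false("ZZ:1" %in% names(ann2$term_to_genes))
  expect_error(
    suppressWarnings(build_annotation(dag, data.frame(gene = "g1", term = "ZZ:1"))),
    "no usable"
  )
})

test_that("propagated term sizes are monotone along edges", {
  obo <- simulate_ontology(depth = 3, branching = 3, seed = 21)
  dag <- parse_obo(obo)
  set.seed(21)
  pairs <- simulate_annotations(sprintf("g%02d", 1:40), dag, mean_terms = 2, seed = 21)
  annot <- build_annotation(dag, pairs)
  K <- vapply(annot$term_to_genes, length, 0L)
  for (i in seq_len(nrow(dag$edges))) {
    child <- dag$edges$child[i]; parent <- dag$edges$parent[i]
    kc <- if (child %in% names(K)) K[[child]] else 0L
    kp <- if (parent %in% names(K)) K[[parent]] else 0L
    expect_gte(kp, kc)
  }
})

test_that("hypergeometric tail matches the worked example and enumeration", {
  expect_equal(comorbsim:::hypergeom_tail(4, K = 5, n = 6, N = 20),
               540 / 38760, tolerance = 1e-12)
  expect_equal(comorbsim:::hypergeom_tail(0, K = 5, n = 6, N = 20), 1)

  set.seed(7)
  for (trial in 1:500) {
    N <- sample(4:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(comorbsim:::hypergeom_tail(k, K, n, N),
                 brute_hyper_tail(k, K, n, N), tolerance = 1e-10)
  }
})

test_that("the tail equals the one-sided Fisher exact p on the 2x2 table", {
  set.seed(8)
  for (trial in 1:100) {
    N <- sample(6:25, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
    expect_equal(comorbsim:::hypergeom_tail(k, K, n, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_enrich tests propagated terms with consistent margins", {
  dag <- toy_chain_dag()
  universe <- sprintf("g%02d", 1:20)
  # 5 genes annotated to C (hence A, R); rest to B
  pairs <- data.frame(gene = universe,
                      term = rep(c("C", "B"), c(5, 15)))
  annot <- build_annotation(dag, pairs)
  deg <- c(universe[1:4], universe[6:7])  # 4 of the C genes + 2 B genes
  res <- fisher_enrich(deg, universe, annot, min_term_size = 1)
  row <- res[res$term == "C", ]
  expect_equal(row$k, 4); expect_equal(row$K, 5)
  expect_equal(row$n, 6); expect_equal(row$N, 20)
  expect_equal(row$p, 540 / 38760, tolerance = 1e-12)
  expect_equal(res[res$term == "C", "p"], res[res$term == "A", "p"]) # same genes
  expect_equal(res[res$term == "R", "p"], 1)  # K = N degenerate margin
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(fisher_enrich(c(deg, "outsider"), universe, annot), "outsider")
})

test_that("top_terms orders by p then id and warns when short", {
  res <- data.frame(term = c("GO:0000002", "GO:0000001", "GO:0000009", "GO:0000005"),
                    p = c(0.01, 0.01, 0.001, 0.2), stringsAsFactors = FALSE)
  top <- top_terms(res, 2)
  expect_equal(top$term, c("GO:0000009", "GO:0000001"))
  expect_equal(top_terms(res, 1)$term, "GO:0000009")
  expect_warning(all4 <- top_terms(res, 10), "4")
  expect_equal(nrow(all4), 4)
})

test_that("pathway enrichment shares the machinery and flags significance", {
  universe <- sprintf("g%02d", 1:20)
  deg <- universe[1:6]
  sets <- list(pw_hit = universe[c(1:4, 19, 20)],   # K=6,k=4
               pw_same = universe[c(1:4, 7)],       # K=5,k=4: the worked margins
               pw_off = sprintf("x%02d", 1:5))      # disjoint from universe
  expect_message(res <- pathway_enrich(deg, universe, sets, min_set_size = 1),
                 "disjoint")
  expect_equal(res$p[res$term == "pw_same"], 540 / 38760, tolerance = 1e-12)
  expect_false("pw_off" %in% res$term)
  expect_type(res$significant, "logical")

  # deg = universe: every k equals K and p = 1
  allres <- pathway_enrich(universe, universe, sets[1:2], min_set_size = 1)
  expect_true(all(allres$k == allres$K))
  expect_true(all(allres$p == 1))
})

test_that("GMT and annotation readers parse their formats", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "x.gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3", "pathB\tdesc\tg2", "short\tonly"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("pathA", "pathB"))
  expect_equal(sets$pathA, c("g1", "g2", "g3"))

  tsv <- file.path(dir, "ann.tsv")
  writeLines(c("gene\tterm", "g1\tGO:1", "g1\tGO:1", "g2\tGO:2"), tsv)
  pairs <- read_annotation_pairs(tsv)
  expect_equal(nrow(pairs), 2)  # duplicates collapse

  gaf <- file.path(dir, "ann.gaf")
  gaf_row <- function(gene, term) {
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", "P", "", "",
            "protein", "taxon:9606", "20200101", "DB", "", ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.1", gaf_row("geneX", "GO:0008150"),
               gaf_row("geneY", "GO:0008152")), gaf)
  gp <- read_annotation_pairs(gaf)
  expect_equal(gp$gene, c("geneX", "geneY"))
  expect_equal(gp$term, c("GO:0008150", "GO:0008152"))
})
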