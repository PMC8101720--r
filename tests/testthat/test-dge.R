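make_matrix <- function(values, samples) {
  matrix(values, nrow = 1, dimnames = list("g1", samples))
}

two_group_design <- function(n_case, n_control) {
  setNames(rep(c("case", "control"), c(n_case, n_control)),
           c(sprintf("ca%d", seq_len(n_case)), sprintf("co%d", seq_len(n_control))))
}

test_that("two-group fit recovers closed-form statistics", {
  design <- two_group_design(3, 3)
  m <- make_matrix(c(4, 5, 6, 1, 2, 3), names(design))
  fit <- suppressWarnings(fit_two_group(m, design))
  expect_equal(fit$logFC, 3)
  expect_equal(fit$s2, 1)
  expect_equal(fit$df, 4)

  same <- make_matrix(c(1, 2, 3, 1, 2, 3), names(design))
  expect_equal(suppressWarnings(fit_two_group(same, design))$logFC, 0)

  const <- make_matrix(rep(5, 6), names(design))
  expect_equal(suppressWarnings(fit_two_group(const, design))$s2, 0)
})

test_that("design validation enforces group structure", {
  expect_error(fit_two_group(
    make_matrix(1:4, c("a", "b", "c", "d")),
    setNames(c("case", "case", "case", "control"), c("a", "b", "c", "d"))
  ), "2 samples")
  expect_error(fit_two_group(
    make_matrix(1:4, c("a", "b", "c", "d")),
    setNames(c("case", "case", "sick", "healthy"), c("a", "b", "c", "d"))
  ), "case")
  expect_warning(fit_two_group(
    matrix(rnorm(8), 2, dimnames = list(c("g1", "g2"), letters[1:4])),
    setNames(c("case", "case", "control", "control"), letters[1:4])
  ), "fewer than 5")
})

test_that("d0 = 0 reduces the moderated t to the ordinary two-sample t", {
  design <- two_group_design(3, 3)
  m <- make_matrix(c(4, 5, 6, 1, 2, 3), names(design))
  fit <- suppressWarnings(fit_two_group(m, design))
  res <- suppressWarnings(moderate_and_test(fit, d0 = 0, s02 = 1))
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df_total, 4)
  expect_equal(res$t, 3.674, tolerance = 1e-3)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)

  # property: on random matrices, d0 = 0 equals the classic t for every gene
  set.seed(11)
  design2 <- suppressWarnings(two_group_design(4, 3))
  m2 <- matrix(rnorm(70), 10, 7,
               dimnames = list(sprintf("g%d", 1:10), names(design2)))
  res2 <- suppressWarnings(moderate_and_test(suppressWarnings(fit_two_group(m2, design2)), d0 = 0, s02 = 1))
  for (i in 1:10) {
    tt2 <- t.test(m2[i, 1:4], m2[i, 5:7], var.equal = TRUE)
    expect_equal(res2$t[i], unname(tt2$statistic), tolerance = 1e-12)
  }
})

test_that("the infinite-prior limit shares one variance across genes", {
  design <- suppressWarnings(two_group_design(3, 3))
  set.seed(5)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("g%d", 1:10), names(design)))
  fit <- suppressWarnings(fit_two_group(m, design))
  res <- suppressWarnings(moderate_and_test(fit, d0 = Inf, s02 = 2))
  expect_equal(res$t, fit$logFC / sqrt(2 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
})

test_that("moderation squeezes variances and matches limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(42)
  design <- two_group_design(5, 5)
  m <- matrix(rnorm(500 * 10, sd = rep(sqrt(rchisq(500, 4) / 4), 10)), 500, 10,
              dimnames = list(sprintf("g%d", 1:500), names(design)))
  fit <- fit_two_group(m, design)
  res <- moderate_and_test(fit)

  sq <- limma::squeezeVar(fit$s2, df = fit$df)
  expect_equal(attr(res, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), sq$var.prior, tolerance = 1e-6)

  mm <- stats::model.matrix(~ factor(design[colnames(m)], c("control", "case")))
  efit <- limma::eBayes(limma::lmFit(m, mm))
  expect_equal(res$t, efit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, efit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-variance genes stay finite under moderation and all-zero errors", {
  design <- suppressWarnings(two_group_design(3, 3))
  m <- rbind(g1 = c(4, 5, 6, 1, 2, 3), g2 = rep(2, 6))
  colnames(m) <- names(design)
  fit <- suppressWarnings(fit_two_group(m, design))
  res <- suppressWarnings(moderate_and_test(fit, d0 = 4, s02 = 0.5))
  expect_true(all(is.finite(res$t[fit$s2 > 0])))
  expect_true(is.finite(res$t[2]))  # squeezed variance > 0
  expect_equal(res$t[2], 0)         # logFC = 0 for the constant gene

  allzero <- rbind(g1 = rep(1, 6), g2 = rep(2, 6))
  colnames(allzero) <- names(design)
  expect_error(moderate_and_test(suppressWarnings(fit_two_group(allzero, design))), "zero")
})

test_that("BH adjustment matches brute-force step-up", {
  design <- suppressWarnings(two_group_design(2, 2))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(99)
  for (trial in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
  # adj_p >= p and monotone in the ranks, from an actual fit
  m <- matrix(rnorm(200), 50, 4, dimnames = list(sprintf("g%d", 1:50),
                                                 names(design)))
  res <- suppressWarnings(moderate_and_test(suppressWarnings(fit_two_group(m, design))))
  expect_true(all(res$adj_p >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
  expect_true(all(sign(res$t) == sign(res$logFC) | res$logFC == 0))
})

test_that("DEG selection applies inclusive thresholds on the chosen p column", {
  res <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    logFC = c(1.5, 0.9, -1.2, 1.0, 2.0),
    t = c(3, 2, -3, 2.5, 4),
    p = c(0.04, 0.04, 0.01, 0.05, 0.2),
    adj_p = c(0.2, 0.2, 0.05, 0.25, 0.5),
    stringsAsFactors = FALSE
  )
  degs <- select_degs(res)
  expect_setequal(degs$up, c("a", "d"))  # boundary p = 0.05, logFC = 1.0 included
  expect_equal(degs$down, "c")
  expect_false("b" %in% degs$up)         # |logFC| below the floor
  expect_false("e" %in% degs$up)         # p above the ceiling

  adj <- select_degs(res, use_adjusted = TRUE)
  expect_equal(adj$down, "c")
  expect_equal(adj$up, character(0))

  # lowering the fold-change floor never shrinks the DEG sets
  loose <- select_degs(res, lfc_min = 0.5)
  expect_true(all(degs$up %in% loose$up))
  expect_true(all(degs$down %in% loose$down))
})

test_that("probe collapsing keeps the most discriminating probe per gene", {
  design <- suppressWarnings(two_group_design(3, 3))
  m <- rbind(
    p1 = c(4, 5, 6, 1, 2, 3),          # strong, tight
    p2 = c(4, 1, 6, 3, 0, 3),          # same gene, noisy
    p3 = c(2, 2, 2, 2, 2, 2),          # other gene
    p4 = c(9, 9, 9, 9, 9, 9)           # unmapped
  )
  colnames(m) <- names(design)
  pmap <- c(p1 = "G1", p2 = "G1", p3 = "G2")
  expect_message(out <- suppressWarnings(collapse_probes(m, pmap, design)), "1 unmapped")
  expect_equal(rownames(out), c("G1", "G2"))
  expect_equal(unname(out["G1", ]), unname(m["p1", ]))

  avg <- suppressMessages(collapse_probes(m, pmap, design, method = "mean"))
  expect_equal(unname(avg["G1", 1]), 4)

  ident <- suppressWarnings(collapse_probes(m[1:3, ], c(p1 = "p1", p2 = "p2", p3 = "p3"), design))
  expect_equal(ident[order(rownames(ident)), ], m[1:3, ][order(rownames(m[1:3, ])), ])
  expect_error(collapse_probes(m, c(zz = "G9"), design), "overlap")
})

test_that("expression reader handles ids, NAs and the log-scale heuristic", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "e.tsv")
  df <- data.frame(gene = c("g1", "g2", "g3"),
                   s1 = c(1, NA, 3), s2 = c(2, 5, 6), s3 = c(1, 1, 1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(m <- read_expression(path), "dropping 1")
  expect_equal(rownames(m), c("g1", "g3"))
  m2 <- read_expression(path, impute_missing = TRUE)
  expect_equal(nrow(m2), 3)
  expect_equal(m2["g2", "s1"], 3)  # row mean of the observed values

  big <- data.frame(gene = "g1", s1 = 1000, s2 = 2, s3 = 3)
  write.table(big, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(read_expression(path), "log2")
})
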