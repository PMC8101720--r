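#' Read a log2 expression matrix from TSV
#'
#' Expects the first column to hold probe/gene ids and the header to hold
#' sample ids. Rows containing missing values are dropped (with a message)
#' unless `impute_missing` replaces them by the row mean. A heuristic
#' warning fires when the matrix maximum exceeds 50, which almost always
#' means the intensities were not log2-transformed.
#'
#' @param path TSV file path
#' @param impute_missing replace NAs by the row mean instead of dropping rows
#' @return numeric matrix, rownames = feature ids, colnames = sample ids
#' @export
read_expression <- function(path, impute_missing = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expression table needs >= 2 sample columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    if (impute_missing) {
      for (i in which(apply(m, 1, anyNA))) {
        m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
      }
    } else {
      bad <- apply(m, 1, anyNA)
      message("dropping ", sum(bad), " feature row(s) with missing values")
      m <- m[!bad, , drop = FALSE]
    }
  }
  if (!all(is.finite(m))) stop("non-finite values remain in expression matrix")
  if (max(m) > 50) {
    warning("matrix maximum exceeds 50; input may not be log2-transformed")
  }
  m
}

#' Read a two-column sample design TSV
#'
#' @param path TSV with columns sample id and group; groups must be
#'   `case` and `control`.
#' @return named character vector sample -> group
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("design table needs two columns: sample, group")
  as_design(setNames(as.character(df[[2]]), as.character(df[[1]])))
}

as_design <- function(design) {
  if (is.data.frame(design)) {
    design <- setNames(as.character(design[[2]]), as.character(design[[1]]))
  }
  bad <- setdiff(unique(design), c("case", "control"))
  if (length(bad) > 0) {
    stop("design groups must be 'case'/'control'; found: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(design, levels = c("case", "control")))
  if (any(counts < 2)) stop("each group needs >= 2 samples")
  if (any(counts < 5)) {
    warning("fewer than 5 samples in a group; screening power will be poor")
  }
  design
}

#' Collapse probe-level rows to one row per gene
#'
#' Keeps, for each gene, the probe with the largest absolute ordinary
#' two-sample t-statistic (a provisional unmoderated fit against
#' `design`); alternatives average the probes or keep the most highly
#' expressed one. Probes without a mapping are dropped and counted in a
#' message.
#'
#' @param matrix numeric log2 expression matrix (probes x samples)
#' @param probe_map named character vector probe id -> gene id
#' @param design named group vector (needed for `method = "max_t"`)
#' @param method `"max_t"` (default), `"mean"`, or `"max_mean_expr"`
#' @return gene-level expression matrix
#' @export
collapse_probes <- function(matrix, probe_map, design = NULL,
                            method = c("max_t", "mean", "max_mean_expr")) {
  method <- match.arg(method)
  mapped <- intersect(rownames(matrix), names(probe_map))
  if (length(mapped) == 0) stop("no probe ids overlap the probe map")
  dropped <- nrow(matrix) - length(mapped)
  if (dropped > 0) message("dropping ", dropped, " unmapped probe(s)")
  m <- matrix[mapped, , drop = FALSE]
  genes <- probe_map[mapped]

  if (method == "mean") {
    out <- rowsum(m, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    return(out[order(rownames(out)), , drop = FALSE])
  }

  score <- if (method == "max_t") {
    if (is.null(design)) stop("method 'max_t' needs the design")
    fit <- fit_two_group(m, design)
    denom <- sqrt(fit$s2 * (1 / fit$n_case + 1 / fit$n_control))
    abs(ifelse(denom > 0, fit$logFC / denom, ifelse(fit$logFC != 0, Inf, 0)))
  } else {
    rowMeans(m)
  }
  keep <- vapply(split(seq_along(genes), genes), function(idx) {
    idx[which.max(score[idx])]
  }, 0L)
  out <- m[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-gene two-group linear fit
#'
#' Ordinary least squares for the two-group design: per gene, the log2
#' fold change (case mean minus control mean), pooled residual variance
#' and residual degrees of freedom `n_case + n_control - 2`.
#'
#' @param matrix numeric log2 expression matrix (genes x samples)
#' @param design named character vector sample -> `"case"`/`"control"`
#'   covering every column, or a two-column data.frame
#' @return data.frame with columns `gene`, `logFC`, `s2`, `df`,
#'   `n_case`, `n_control`
#' @export
fit_two_group <- function(matrix, design) {
  design <- as_design(design)
  missing <- setdiff(colnames(matrix), names(design))
  if (length(missing) > 0) {
    stop("design does not cover sample(s): ", paste(missing, collapse = ", "))
  }
  grp <- design[colnames(matrix)]
  case <- matrix[, grp == "case", drop = FALSE]
  ctrl <- matrix[, grp == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  mu1 <- rowMeans(case); mu2 <- rowMeans(ctrl)
  ss <- rowSums((case - mu1)^2) + rowSums((ctrl - mu2)^2)
  df <- n1 + n2 - 2
  data.frame(
    gene = rownames(matrix),
    logFC = mu1 - mu2,
    s2 = ss / df,
    df = df,
    n_case = n1,
    n_control = n2,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Invert the trigamma function by Newton iteration (used by the
# method-of-moments prior fit).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate the variance-prior hyperparameters
#'
#' Method-of-moments fit of the scaled inverse chi-square prior on the
#' per-gene residual variances, matching the mean and variance of
#' `log(s2)` to the log-F model: with `e = log(s2) - digamma(df/2) +
#' log(df/2)`, the excess spread `var(e) - trigamma(df/2)` identifies the
#' prior degrees of freedom `d0` through the trigamma function, and the
#' centred mean identifies the prior variance `s02`. Zero variances are
#' excluded from the moment fit (with a warning); no excess spread means
#' an infinite prior (complete shrinkage to a common variance).
#'
#' @param s2 per-gene residual variances
#' @param df shared residual degrees of freedom
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior variance)
#' @export
estimate_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (!any(pos)) stop("all residual variances are zero; cannot moderate")
  if (any(!pos)) warning(sum(!pos), " zero residual variance(s) excluded from prior fit")
  if (length(s2) < 10) warning("fewer than 10 genes; hyperparameter estimates unstable")
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-tests
#'
#' Squeezes each gene's residual variance toward the prior,
#' `s2_post = (d0 * s02 + df * s2) / (d0 + df)`, forms the moderated
#' t-statistic on the squeezed variance, computes two-sided p-values on
#' `d0 + df` degrees of freedom and applies Benjamini-Hochberg adjustment
#' across all genes. With `d0 = 0` the result is the ordinary two-sample
#' t-test; as `d0` grows all genes share the prior variance. Zero-variance
#' genes get a finite moderated t whenever `d0 > 0`.
#'
#' @param fits output of [fit_two_group()]
#' @param d0,s02 optional hyperparameter overrides; by default both are
#'   estimated by [estimate_variance_prior()]. Set `d0 = 0` for ordinary
#'   t-tests.
#' @return data.frame with columns `gene`, `logFC`, `t`, `p`, `adj_p`,
#'   `df_total`, plus the hyperparameters as attributes `d0` and `s02`
#' @export
moderate_and_test <- function(fits, d0 = NULL, s02 = NULL) {
  stopifnot(is.data.frame(fits),
            all(c("gene", "logFC", "s2", "df", "n_case", "n_control") %in% names(fits)))
  df <- fits$df[1]
  if (is.null(d0) || is.null(s02)) {
    prior <- estimate_variance_prior(fits$s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, nrow(fits))
  } else if (d0 == 0) {
    fits$s2
  } else {
    (d0 * s02 + df * fits$s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / fits$n_case + 1 / fits$n_control))
  t <- ifelse(se > 0, fits$logFC / se,
              ifelse(fits$logFC == 0, 0, sign(fits$logFC) * Inf))
  df_total <- d0 + df
  p <- 2 * pt(-abs(t), df = df_total)
  out <- data.frame(
    gene = fits$gene,
    logFC = fits$logFC,
    t = t,
    p = p,
    adj_p = p.adjust(p, method = "BH"),
    df_total = df_total,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Select differentially expressed genes
#'
#' Applies the screening filter: a gene is a DEG when its p-value is at
#' most `p_max` and its absolute log2 fold change at least `lfc_min`
#' (both bounds inclusive). Raw p-values are the operative default; set
#' `use_adjusted` to filter on BH-adjusted p instead.
#'
#' @param results output of [moderate_and_test()]
#' @param p_max p-value ceiling (default 0.05)
#' @param lfc_min absolute log2-fold-change floor (default 1.0)
#' @param use_adjusted filter on `adj_p` instead of raw `p`
#' @return list with character vectors `up` and `down` (gene ids)
#' @export
select_degs <- function(results, p_max = 0.05, lfc_min = 1.0, use_adjusted = FALSE) {
  stopifnot(p_max > 0, lfc_min >= 0)
  p <- if (use_adjusted) results$adj_p else results$p
  sig <- p <= p_max
  list(
    up = results$gene[sig & results$logFC >= lfc_min],
    down = results$gene[sig & results$logFC <= -lfc_min]
  )
}

#' Run the full differential-expression screen
#'
#' Convenience wrapper: optional probe collapsing, two-group fit,
#' empirical-Bayes moderation and DEG selection.
#'
#' @inheritParams fit_two_group
#' @inheritParams select_degs
#' @param probe_map optional named vector probe -> gene for collapsing
#' @return list with `table` (the per-gene results), `degs` (up/down
#'   lists) and `matrix` (the gene-level matrix used)
#' @export
run_dge <- function(matrix, design, probe_map = NULL,
                    p_max = 0.05, lfc_min = 1.0, use_adjusted = FALSE) {
  if (!is.null(probe_map)) {
    matrix <- collapse_probes(matrix, probe_map, design)
  }
  fits <- fit_two_group(matrix, design)
  res <- moderate_and_test(fits)
  list(table = res, degs = select_degs(res, p_max, lfc_min, use_adjusted),
       matrix = matrix)
}
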