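#' Simulate a toy ontology as OBO text
#'
#' Generates a rooted `branching`-ary tree of the given depth (depth 0 =
#' root only; depth 2 with branching 2 gives the 7-term binary tree) and
#' optionally adds random "diamond" shortcut edges from a term to a
#' non-ancestor term closer to the root, preserving acyclicity. All edges
#' are `is_a`; output is valid OBO text that round-trips through
#' [parse_obo()].
#'
#' @param depth tree depth in edge levels (>= 0)
#' @param branching children per internal node (>= 1)
#' @param seed integer RNG seed (fixed seed gives byte-identical text)
#' @param n_diamonds number of extra shortcut edges to attempt (default:
#'   one per 10 terms)
#' @param namespace namespace tag written into every term
#' @param prefix term id prefix
#' @return character scalar of OBO text
#' @export
simulate_ontology <- function(depth, branching, seed = 1,
                              n_diamonds = NULL, namespace = "biological_process",
                              prefix = "TOY") {
  stopifnot(depth >= 0, branching >= 1)
  n <- sum(branching^(0:depth))
  ids <- sprintf("%s:%07d", prefix, seq_len(n))
  parent_idx <- integer(n)  # 0 = root
  level <- integer(n)
  nxt <- 2L
  queue <- 1L
  while (nxt <= n) {
    node <- queue[1]; queue <- queue[-1]
    for (b in seq_len(branching)) {
      if (nxt > n) break
      parent_idx[nxt] <- node
      level[nxt] <- level[node] + 1L
      queue <- c(queue, nxt)
      nxt <- nxt + 1L
    }
  }
  edges <- data.frame(child = ids[parent_idx > 0],
                      parent = ids[parent_idx[parent_idx > 0]],
                      stringsAsFactors = FALSE)

  if (is.null(n_diamonds)) n_diamonds <- n %/% 10
  if (n_diamonds > 0 && n > 2) {
    set.seed(seed)
    anc_of <- function(i) {  # strict tree ancestors by index
      out <- integer(0)
      while (parent_idx[i] > 0) { i <- parent_idx[i]; out <- c(out, i) }
      out
    }
    deep <- which(level >= 2)
    if (length(deep) == 0) n_diamonds <- 0
    for (d in seq_len(n_diamonds)) {
      i <- deep[sample.int(length(deep), 1)]
      shallower <- setdiff(which(level < level[i]), c(anc_of(i), i))
      if (length(shallower) == 0) next
      j <- shallower[sample.int(length(shallower), 1)]
      edges <- rbind(edges, data.frame(child = ids[i], parent = ids[j],
                                       stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
  }

  stanza <- function(i) {
    ps <- edges$parent[edges$child == ids[i]]
    c("[Term]",
      paste0("id: ", ids[i]),
      paste0("name: term ", i),
      paste0("namespace: ", namespace),
      if (length(ps) > 0) paste0("is_a: ", ps),
      "")
  }
  paste(c("format-version: 1.2", "",
          unlist(lapply(seq_len(n), stanza))), collapse = "\n")
}

#' Simulation settings for a two-group expression experiment
#'
#' @param n_genes number of genes
#' @param n_case,n_control samples per group
#' @param n_de number of planted differentially expressed genes
#' @param lfc planted log2 effect size; sign drawn with equal probability
#'   per gene unless `effect_sd > 0`, in which case effects are drawn
#'   from Normal(+/- lfc, effect_sd)
#' @param sigma residual standard deviation on the log2 scale (> 0)
#' @param effect_sd spread of per-gene effects (0 = constant shift)
#' @param seed integer RNG seed
#' @return a `simulation_spec` list
#' @export
simulation_spec <- function(n_genes = 1000, n_case = 5, n_control = 5,
                            n_de = 100, lfc = 2, sigma = 0.5,
                            effect_sd = 0, seed = 1) {
  stopifnot(n_de <= n_genes, sigma > 0, n_case >= 2, n_control >= 2,
            lfc >= 0, effect_sd >= 0)
  structure(list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 n_de = n_de, lfc = lfc, sigma = sigma,
                 effect_sd = effect_sd, seed = seed),
            class = "simulation_spec")
}

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' Emulates the statistical structure of a case/control microarray
#' comparison: per-gene baselines ~ Normal(7, 1) on the log2 scale,
#' i.i.d. Normal(0, sigma^2) residual noise, and `n_de` planted genes
#' whose case-group mean is shifted by +/- `lfc`. The truth table records
#' the planted genes and signs.
#'
#' @param spec a [simulation_spec()]
#' @return list with `matrix` (genes x samples), `design` (named vector
#'   sample -> group) and `truth` (data.frame gene, lfc)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  genes <- sprintf("gene%05d", seq_len(spec$n_genes))
  samples <- c(sprintf("case%02d", seq_len(spec$n_case)),
               sprintf("ctrl%02d", seq_len(spec$n_control)))
  design <- setNames(rep(c("case", "control"), c(spec$n_case, spec$n_control)),
                     samples)
  baseline <- rnorm(spec$n_genes, mean = 7, sd = 1)
  m <- matrix(rnorm(spec$n_genes * length(samples), sd = spec$sigma),
              nrow = spec$n_genes,
              dimnames = list(genes, samples)) + baseline
  effects <- numeric(0)
  if (spec$n_de > 0) {
    planted <- sample(genes, spec$n_de)
    signs <- sample(c(-1, 1), spec$n_de, replace = TRUE)
    effects <- setNames(signs * spec$lfc, planted)
    if (spec$effect_sd > 0) {
      effects <- effects + rnorm(spec$n_de, sd = spec$effect_sd)
    }
    m[planted, design == "case"] <- m[planted, design == "case"] + effects
  }
  truth <- data.frame(gene = as.character(names(effects)), lfc = unname(effects),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene), , drop = FALSE]
  rownames(truth) <- NULL
  list(matrix = m, design = design, truth = truth, seed = spec$seed)
}

#' Simulate gene-to-term annotations
#'
#' Each gene receives `Poisson(mean_terms) + 1` terms drawn without
#' replacement (when possible) from a leaf-biased distribution: leaves
#' carry three times the weight of internal terms, mimicking the
#' tendency of curated annotation to use specific terms.
#'
#' @param genes character vector of gene ids
#' @param dag an [ontology_dag()]
#' @param mean_terms mean number of extra terms per gene (>= 0)
#' @param seed integer RNG seed
#' @return data.frame with columns `gene`, `term`
#' @export
simulate_annotations <- function(genes, dag, mean_terms = 1, seed = 1) {
  stopifnot(length(genes) > 0, mean_terms >= 0)
  ids <- dag$terms$id[!dag$terms$obsolete]
  if (length(ids) == 0) stop("ontology has no usable terms")
  is_leaf <- !(ids %in% dag$edges$parent)
  w <- ifelse(is_leaf, 3, 1)
  set.seed(seed)
  rows <- lapply(genes, function(g) {
    k <- min(rpois(1, mean_terms) + 1L, length(ids))
    data.frame(gene = g, term = sample(ids, k, prob = w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated experiment to disk
#'
#' Emits the plain-text inputs the pipeline consumes: expression TSV,
#' design TSV, truth TSV and (optionally) annotation TSV and OBO text.
#'
#' @param sim output of [simulate_expression()]
#' @param dir output directory (created if needed)
#' @param annotations optional data.frame from [simulate_annotations()]
#' @param obo_text optional OBO string from [simulate_ontology()]
#' @param prefix file-name prefix
#' @return named character vector of the files written, invisibly
#' @export
write_simulation <- function(sim, dir, annotations = NULL, obo_text = NULL,
                             prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(expr = file.path(dir, paste0(prefix, "_expr.tsv")),
             design = file.path(dir, paste0(prefix, "_design.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  expr_df <- data.frame(gene = rownames(sim$matrix), sim$matrix,
                        check.names = FALSE)
  write.table(expr_df, files["expr"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(sim$design), group = unname(sim$design)),
              files["design"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotations)) {
    files["annotations"] <- file.path(dir, paste0(prefix, "_annotations.tsv"))
    write.table(annotations, files["annotations"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(obo_text)) {
    files["obo"] <- file.path(dir, paste0(prefix, ".obo"))
    writeLines(obo_text, files["obo"])
  }
  invisible(files)
}
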