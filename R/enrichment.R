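#' Build direct and propagated annotation maps
#'
#' From a table of (gene, term) pairs, constructs the direct gene-to-term
#' map and the term-to-gene map after true-path propagation: a gene
#' annotated to a term is implicitly annotated to all the term's
#' ancestors (following admitted relations only). Pairs naming terms
#' absent from the DAG are dropped with a warning.
#'
#' @param dag an [ontology_dag()]
#' @param pairs data.frame whose first two columns are gene id and term
#'   id, or a named list gene -> term ids
#' @return an `annotation_map`: list with `gene_to_terms` (direct, named
#'   list) and `term_to_genes` (propagated, named list)
#' @export
build_annotation <- function(dag, pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(
      gene = rep(names(pairs), lengths(pairs)),
      term = unlist(pairs, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2)
  genes <- as.character(pairs[[1]])
  terms <- as.character(pairs[[2]])
  known <- terms %in% dag$terms$id[!dag$terms$obsolete]
  if (any(!known)) {
    warning("dropping ", sum(!known), " annotation(s) to unknown term(s): ",
            paste(unique(terms[!known]), collapse = ", "))
    genes <- genes[known]; terms <- terms[known]
  }
  if (length(genes) == 0) stop("no usable annotations after filtering")

  gene_to_terms <- lapply(split(terms, genes), unique)

  # true-path propagation: each annotated term pushes its genes to the
  # whole (reflexive) ancestor closure
  term_to_genes <- new.env(parent = emptyenv())
  closure_cache <- new.env(parent = emptyenv())
  for (i in seq_along(genes)) {
    tm <- terms[i]
    anc <- if (exists(tm, envir = closure_cache, inherits = FALSE)) {
      get(tm, envir = closure_cache)
    } else {
      a <- ancestor_closure(dag, tm)
      assign(tm, a, envir = closure_cache)
      a
    }
    for (a in anc) {
      cur <- if (exists(a, envir = term_to_genes, inherits = FALSE)) {
        get(a, envir = term_to_genes)
      } else character(0)
      assign(a, c(cur, genes[i]), envir = term_to_genes)
    }
  }
  tg <- lapply(as.list(term_to_genes), unique)
  structure(list(gene_to_terms = gene_to_terms, term_to_genes = tg),
            class = "annotation_map")
}

#' Read gene-term annotation pairs
#'
#' Accepts either a two-column TSV (gene, term) or a GAF 2.x file, in
#' which case columns 2 (object id) and 5 (term id) are used and comment
#' lines starting with `!` are skipped.
#'
#' @param path file path
#' @return data.frame with columns `gene`, `term`
#' @export
read_annotation_pairs <- function(path) {
  first <- readLines(path, n = 50, warn = FALSE)
  gaf <- any(grepl("^!gaf-version", first)) ||
    length(strsplit(first[!grepl("^!", first)][1], "\t")[[1]]) >= 15
  if (gaf) {
    df <- read.delim(path, header = FALSE, comment.char = "!",
                     stringsAsFactors = FALSE)
    out <- data.frame(gene = df[[2]], term = df[[5]], stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    out <- data.frame(gene = as.character(df[[1]]), term = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

hypergeom_tail <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeom(N genes, K annotated, n drawn)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

enrich_core <- function(deg, universe, sets, min_set_size) {
  deg <- unique(as.character(deg))
  universe <- unique(as.character(universe))
  offenders <- setdiff(deg, universe)
  if (length(offenders) > 0) {
    stop("DEG(s) outside the universe: ", paste(offenders, collapse = ", "))
  }
  N <- length(universe)
  n <- length(deg)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(members, deg))
    data.frame(term = id, k = k, K = K, n = n, N = N,
               p = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      adj_p = numeric(0), stringsAsFactors = FALSE))
  }
  rows$adj_p <- p.adjust(rows$p, method = "BH")
  rows[order(rows$p, rows$term), , drop = FALSE]
}

#' GO over-representation analysis (one-sided Fisher / hypergeometric)
#'
#' For every term whose propagated annotation covers at least
#' `min_term_size` universe genes, tests whether DEGs are over-represented
#' among the term's genes: `p = P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)` where `N` is the universe size, `K` the
#' term's annotated genes, `n` the DEG count and `k` their intersection.
#' This one-sided tail is identical to the one-sided Fisher's exact test
#' on the corresponding 2x2 table. BH adjustment is applied across all
#' tested terms.
#'
#' @param deg character vector of DEG ids (must be a subset of `universe`)
#' @param universe character vector of all measured genes
#' @param annot an `annotation_map` from [build_annotation()]
#' @param min_term_size smallest annotated-set size tested (default 3)
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `adj_p`, ordered by `p` then term id
#' @export
fisher_enrich <- function(deg, universe, annot, min_term_size = 3) {
  stopifnot(inherits(annot, "annotation_map"), min_term_size >= 1)
  enrich_core(deg, universe, annot$term_to_genes, min_term_size)
}

#' Top enriched terms
#'
#' Orders results by raw p ascending with ties broken by term id
#' (lexicographic ascending) and returns the first `k`. Asking for more
#' terms than exist returns everything with a warning.
#'
#' @param results output of [fisher_enrich()] or [pathway_enrich()]
#' @param k how many terms (default 5)
#' @return the first `k` rows after ordering
#' @export
top_terms <- function(results, k = 5) {
  stopifnot(k >= 1)
  ord <- results[order(results$p, results$term), , drop = FALSE]
  if (nrow(ord) < k) {
    warning("only ", nrow(ord), " term(s) available; returning all")
    return(ord)
  }
  head(ord, k)
}

#' Pathway over-representation analysis
#'
#' The same hypergeometric machinery as [fisher_enrich()] applied to flat
#' pathway gene sets (no DAG propagation). Pathways disjoint from the
#' universe are skipped with a message. Rows with `adj_p <= alpha` carry
#' `significant = TRUE`.
#'
#' @inheritParams fisher_enrich
#' @param gene_sets named list pathway -> character vector of genes
#'   (e.g. from [read_gmt()])
#' @param min_set_size smallest pathway (intersected with the universe) tested
#' @param alpha adjusted-p significance cutoff for the flag (default 0.05)
#' @return data.frame as [fisher_enrich()] plus a `significant` column
#' @export
pathway_enrich <- function(deg, universe, gene_sets, min_set_size = 3,
                           alpha = 0.05) {
  overlap <- vapply(gene_sets, function(s) length(intersect(s, universe)), 0L)
  if (any(overlap == 0)) {
    message("skipping ", sum(overlap == 0), " pathway(s) disjoint from the universe")
    gene_sets <- gene_sets[overlap > 0]
  }
  out <- enrich_core(deg, universe, gene_sets, min_set_size)
  out$significant <- out$adj_p <= alpha
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes. Empty member
#' lists are dropped.
#'
#' @param path GMT file path
#' @return named list set name -> character vector of genes
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) return(NULL)
    setNames(list(unique(parts[-(1:2)])), parts[1])
  })
  sets <- unlist(sets[!vapply(sets, is.null, TRUE)], recursive = FALSE)
  if (is.null(sets) || length(sets) == 0) stop("no usable gene sets in GMT file")
  sets
}
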