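#' Semantic-contribution policy
#'
#' Edge weights ("semantic participation" factors) used when propagating a
#' focal term's contribution to its ancestors. Each traversed edge
#' multiplies the contribution by the weight of its relation, so values
#' must lie strictly inside (0, 1): this guarantees contributions decay
#' along paths and aggregate semantic values stay finite. Defaults follow
#' the convention of the Wang measure: `is_a` = 0.8, `part_of` = 0.6.
#'
#' @param weights named numeric vector mapping relation label to a factor
#'   in (0, 1).
#' @return an object of class `semsim_policy`
#' @export
semsim_policy <- function(weights = c(is_a = 0.8, part_of = 0.6)) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be a named numeric vector (relation -> factor)")
  }
  if (any(weights <= 0 | weights >= 1)) {
    stop("every contribution factor must lie strictly in (0, 1)")
  }
  structure(list(weights = weights), class = "semsim_policy")
}

policy_weight <- function(policy, relation) {
  w <- policy$weights[relation]
  if (anyNA(w)) {
    stop("no contribution factor configured for relation(s): ",
         paste(unique(relation[is.na(w)]), collapse = ", "))
  }
  unname(w)
}

#' Semantic contributions of a term's ancestors
#'
#' Dynamic program over the ancestor sub-DAG of `focal`. The focal term
#' contributes 1 to itself; every ancestor `t` receives the maximum, over
#' its children `t'` lying on a path from the focal term, of
#' `w_e * S(t')`, where `w_e` is the contribution factor of the edge
#' relation. The aggregate semantic value `sv` is the sum of all
#' contributions (the focal term included), hence `sv >= 1`.
#'
#' @param dag an [ontology_dag()]
#' @param focal a term id in `dag`
#' @param policy a [semsim_policy()]
#' @return an object of class `svalue_table`: list with `focal`, `s`
#'   (named numeric vector of contributions in (0, 1], `s[focal] == 1`)
#'   and `sv` (their sum).
#' @examples
#' obo <- c("[Term]", "id: R", "name: root", "",
#'          "[Term]", "id: A", "name: a", "is_a: R", "",
#'          "[Term]", "id: C", "name: c", "is_a: A")
#' dag <- parse_obo(paste(obo, collapse = "\n"))
#' compute_s_values(dag, "C", semsim_policy())  # s = C:1, A:0.8, R:0.64
#' @export
compute_s_values <- function(dag, focal, policy = semsim_policy()) {
  closure <- ancestor_closure(dag, focal)
  ord <- closure[order(dag$topo_index[closure])]  # children before parents
  s <- setNames(numeric(length(ord)), ord)
  s[focal] <- 1
  for (a in ord) {
    if (a == focal) next
    kids <- dag$children_of[[a]]
    kids <- kids[kids %in% ord]
    # every child of an ancestor that itself lies in the closure is on a
    # focal -> a path, so all qualify
    s[a] <- max(policy_weight(policy, names(kids)) * s[kids])
  }
  structure(list(focal = focal, s = s, sv = sum(s)), class = "svalue_table")
}

#' @export
print.svalue_table <- function(x, ...) {
  cat("svalue_table for", x$focal, "- sv =", format(x$sv), "\n")
  print(x$s)
  invisible(x)
}

# Internal: compute (and cache) svalue tables for many terms at once.
svalue_tables <- function(dag, terms, policy) {
  terms <- unique(terms)
  setNames(lapply(terms, compute_s_values, dag = dag, policy = policy), terms)
}

term_similarity_from_tables <- function(tx, ty) {
  shared <- intersect(names(tx$s), names(ty$s))
  if (length(shared) == 0) return(0)
  sum(tx$s[shared] + ty$s[shared]) / (tx$sv + ty$sv)
}

#' Wang-style similarity of two ontology terms
#'
#' Shared-ancestor contributions of the two terms divided by the sum of
#' their aggregate semantic values. Both closures are reflexive, so
#' `term_similarity(x, x) == 1`; values always lie in \[0, 1\] because a
#' shared ancestor's contributions appear in both denominator sums.
#'
#' @inheritParams compute_s_values
#' @param x,y term ids in `dag`
#' @return similarity in \[0, 1\]
#' @export
term_similarity <- function(dag, x, y, policy = semsim_policy()) {
  tx <- compute_s_values(dag, x, policy)
  ty <- compute_s_values(dag, y, policy)
  term_similarity_from_tables(tx, ty)
}

bma_from_simmat <- function(m) {
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}

#' Best-match-average similarity of two term sets
#'
#' For every term of one set take its best match in the other set; average
#' the best matches over both directions:
#' `(sum_i max_j sim(t1i, t2j) + sum_j max_i sim(t1i, t2j)) / (l + m)`.
#' Symmetric in the order of the two sets; identical sets give 1.
#'
#' @inheritParams compute_s_values
#' @param set1,set2 non-empty character vectors of term ids in `dag`
#' @return similarity in \[0, 1\]
#' @export
set_similarity_bma <- function(dag, set1, set2, policy = semsim_policy()) {
  set1 <- unique(as.character(set1)); set2 <- unique(as.character(set2))
  if (length(set1) == 0 || length(set2) == 0) {
    stop("set_similarity_bma requires two non-empty term sets")
  }
  tabs <- svalue_tables(dag, c(set1, set2), policy)
  m <- matrix(0, length(set1), length(set2), dimnames = list(set1, set2))
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      m[i, j] <- term_similarity_from_tables(tabs[[set1[i]]], tabs[[set2[j]]])
    }
  }
  bma_from_simmat(m)
}

#' Functional similarity of two genes from their GO annotations
#'
#' Best-match-average similarity over the two genes' *direct* annotation
#' sets. Annotations are deliberately not propagated to ancestors here:
#' propagation would let the ontology root dominate every best match.
#' (Enrichment analysis, by contrast, does propagate; the two choices are
#' independent.)
#'
#' @inheritParams compute_s_values
#' @param annotations named list: gene id -> character vector of term ids
#' @param g1,g2 gene ids present in `annotations` with at least one term
#' @return similarity in \[0, 1\]
#' @export
gene_similarity <- function(dag, annotations, g1, g2, policy = semsim_policy()) {
  for (g in c(g1, g2)) {
    if (is.null(annotations[[g]]) || length(annotations[[g]]) == 0) {
      stop("gene has no annotation: ", g)
    }
  }
  set_similarity_bma(dag, annotations[[g1]], annotations[[g2]], policy)
}

#' Pairwise similarity matrix over named term sets
#'
#' Computes the best-match-average similarity for every pair of entities
#' (datasets, genes, diseases), each represented by a non-empty set of
#' ontology terms. Singleton-vs-singleton comparisons reduce to plain
#' term similarity.
#'
#' @inheritParams compute_s_values
#' @param entities named list: entity label -> non-empty character vector
#'   of term ids
#' @param level one of `"deg"`, `"go_terms"`, `"do_terms"` — recorded as
#'   metadata describing what the entities' term sets represent
#' @return a `similarity_matrix`: symmetric numeric matrix with unit
#'   diagonal, entity labels as dimnames, and a `level` attribute
#' @export
similarity_matrix <- function(dag, entities, policy = semsim_policy(),
                              level = c("deg", "go_terms", "do_terms")) {
  level <- match.arg(level)
  if (is.null(names(entities)) || any(names(entities) == "")) {
    stop("entities must be a named list")
  }
  empties <- names(entities)[vapply(entities, length, 0L) == 0]
  if (length(empties) > 0) {
    stop("entity with empty term set: ", paste(empties, collapse = ", "))
  }
  labels <- names(entities)
  n <- length(entities)
  all_terms <- unique(unlist(entities))
  tabs <- svalue_tables(dag, all_terms, policy)

  pair_sim <- function(s1, s2) {
    m <- matrix(0, length(s1), length(s2))
    for (i in seq_along(s1)) {
      for (j in seq_along(s2)) {
        m[i, j] <- term_similarity_from_tables(tabs[[s1[i]]], tabs[[s2[j]]])
      }
    }
    bma_from_simmat(m)
  }

  v <- diag(1, n)
  dimnames(v) <- list(labels, labels)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sij <- pair_sim(unique(entities[[i]]), unique(entities[[j]]))
        v[i, j] <- sij
        v[j, i] <- sij
      }
    }
  }
  structure(v, level = level, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (level =", attr(x, "level"), ")\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Write a similarity matrix as TSV plus a metadata sidecar
#'
#' The matrix goes to `<path>` with labels as first row and column; the
#' level and dimensions go to `<path>.meta.json`.
#'
#' @param x a `similarity_matrix`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_similarity_matrix <- function(x, path) {
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(level = attr(x, "level"), n = nrow(x), labels = rownames(x))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
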