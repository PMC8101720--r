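#' @importFrom stats var rnorm rpois p.adjust pt phyper as.dist hclust setNames
#' @importFrom utils read.delim write.table head
NULL

#' Construct an ontology DAG
#'
#' Builds the validated directed-acyclic-graph container used by the
#' semantic-similarity engine. Users normally obtain one from
#' [parse_obo()]; this constructor is exported for programmatic DAG
#' assembly (e.g. in simulations).
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete` (logical). `id` must be unique.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#'   Every endpoint must be a non-obsolete term id.
#' @return An object of class `ontology_dag` with components `terms`,
#'   `edges`, `roots` (ids with no parents), parent/child adjacency lists
#'   and a cached topological order (children before parents).
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace", "obsolete") %in% names(terms)))
  stopifnot(is.data.frame(edges), all(c("child", "parent", "relation") %in% names(edges)))
  terms$id <- as.character(terms$id)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids: ", paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges$relation <- as.character(edges$relation)

  active <- terms$id[!terms$obsolete]
  bad <- setdiff(unique(c(edges$child, edges$parent)), active)
  if (length(bad) > 0) {
    stop("edge endpoint(s) not among non-obsolete terms: ", paste(bad, collapse = ", "))
  }
  if (any(terms$obsolete & terms$id %in% c(edges$child, edges$parent))) {
    stop("obsolete terms must not carry edges")
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = active, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    if (length(cyc) == 0) { # self-loop
      cyc <- edges$child[edges$child == edges$parent][1]
    }
    stop("ontology graph contains a cycle involving: ", paste(cyc, collapse = " -> "))
  }
  # topological order with every child preceding its parents
  topo <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]

  parents_of <- lapply(split(seq_len(nrow(edges)), edges$child), function(i) {
    setNames(edges$parent[i], edges$relation[i])
  })
  children_of <- lapply(split(seq_len(nrow(edges)), edges$parent), function(i) {
    setNames(edges$child[i], edges$relation[i])
  })
  roots <- setdiff(active, names(parents_of))

  structure(
    list(
      terms = terms,
      edges = edges,
      roots = roots,
      parents_of = parents_of,
      children_of = children_of,
      topo_order = topo,
      topo_index = setNames(seq_along(topo), topo)
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),", nrow(x$edges), "edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Number of terms in a DAG
#' @param dag an `ontology_dag`
#' @param include_obsolete count obsolete terms too?
#' @return integer count
#' @export
n_terms <- function(dag, include_obsolete = TRUE) {
  if (include_obsolete) nrow(dag$terms) else sum(!dag$terms$obsolete)
}

#' Parse an OBO ontology file into a validated DAG
#'
#' Reads OBO 1.2/1.4 flat-file text (the distribution format of the Gene
#' Ontology and the Disease Ontology) and returns the term DAG. Only
#' `[Term]` stanzas are considered; `is_a` and `relationship` tags supply
#' edges. Obsolete terms are retained (flagged) but stripped of edges.
#' Edges pointing at terms absent from the file after filtering — e.g.
#' cross-ontology references — are dropped with a warning.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @param namespace_filter if non-NULL, keep only terms whose `namespace`
#'   tag equals this string (e.g. `"biological_process"`).
#' @param admitted_relations edge relation labels to keep. Defaults to
#'   `is_a` and `part_of`; all other OBO relations are dropped because the
#'   semantic-contribution policy assigns them no weight.
#' @return an [ontology_dag()]
#' @seealso [ancestor_closure()], [compute_s_values()]
#' @export
parse_obo <- function(path, namespace_filter = NULL,
                      admitted_relations = c("is_a", "part_of")) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }

  stanza <- NA_character_   # current stanza type
  cur <- NULL               # accumulating tag list for current [Term]
  cur_line <- NA_integer_
  term_list <- list()

  flush_term <- function(cur, cur_line) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$id)) {
      stop("malformed [Term] stanza starting at line ", cur_line, ": missing id tag")
    }
    cur
  }

  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[i])
    if (ln == "" ) next
    if (grepl("^\\[", ln)) {
      t <- flush_term(cur, cur_line)
      if (!is.null(t)) term_list[[length(term_list) + 1L]] <- t
      cur <- NULL
      if (!grepl("^\\[[A-Za-z]+\\]$", ln)) {
        stop("malformed stanza header at line ", i, ": '", ln, "'")
      }
      stanza <- sub("^\\[([A-Za-z]+)\\]$", "\\1", ln)
      if (stanza == "Term") {
        cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                    obsolete = FALSE, parents = character(0), relations = character(0))
        cur_line <- i
      }
      next
    }
    if (is.na(stanza) || stanza != "Term") next  # header block / Typedef: skip
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed tag line ", i, " in [Term] stanza: '", ln, "'")
    }
    tag <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- val
    else if (tag == "is_obsolete" && identical(val, "true")) cur$obsolete <- TRUE
    else if (tag == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) stop("malformed relationship tag at line ", i, ": '", ln, "'")
      cur$parents <- c(cur$parents, parts[2])
      cur$relations <- c(cur$relations, parts[1])
    }
    # other tags (def, synonym, xref, ...) are ignored
  }
  t <- flush_term(cur, cur_line)
  if (!is.null(t)) term_list[[length(term_list) + 1L]] <- t

  if (length(term_list) == 0) stop("no [Term] stanzas found")

  terms <- data.frame(
    id = vapply(term_list, `[[`, "", "id"),
    name = vapply(term_list, `[[`, "", "name"),
    namespace = vapply(term_list, `[[`, "", "namespace"),
    obsolete = vapply(term_list, `[[`, FALSE, "obsolete"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id(s) in OBO: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  if (!is.null(namespace_filter)) {
    terms <- terms[!is.na(terms$namespace) & terms$namespace == namespace_filter, ,
                   drop = FALSE]
    term_list <- Filter(function(t) t$id %in% terms$id, term_list)
  }

  edges <- do.call(rbind, lapply(term_list, function(t) {
    if (t$obsolete || length(t$parents) == 0) return(NULL)
    data.frame(child = t$id, parent = t$parents, relation = t$relations,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }

  keep_rel <- edges$relation %in% admitted_relations
  edges <- edges[keep_rel, , drop = FALSE]

  active <- terms$id[!terms$obsolete]
  known <- edges$parent %in% active & edges$child %in% active
  if (any(!known)) {
    warning(sum(!known), " edge(s) referencing terms outside the loaded ontology dropped")
    edges <- edges[known, , drop = FALSE]
  }
  rownames(edges) <- NULL
  ontology_dag(terms, edges)
}

#' Reflexive ancestor closure of a term
#'
#' All terms reachable from `term` by following child-to-parent edges,
#' including `term` itself. The closure is reflexive because the aggregate
#' semantic value of a term sums contributions over its ancestors
#' *and* itself (its own contribution is 1); without reflexivity
#' self-similarity would fall below 1.
#'
#' @param dag an [ontology_dag()]
#' @param term a term id present in `dag`
#' @return character vector of term ids (unordered), always containing `term`
#' @export
ancestor_closure <- function(dag, term) {
  if (!term %in% dag$terms$id) stop("unknown term id: ", term)
  seen <- new.env(parent = emptyenv())
  frontier <- term
  assign(term, TRUE, envir = seen)
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (p in dag$parents_of[[v]]) {
        if (!exists(p, envir = seen, inherits = FALSE)) {
          assign(p, TRUE, envir = seen)
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  ls(seen)
}

#' Descendant closure of a term (reflexive)
#' @inheritParams ancestor_closure
#' @return character vector of ids of `term` and all its descendants
#' @export
descendant_closure <- function(dag, term) {
  if (!term %in% dag$terms$id) stop("unknown term id: ", term)
  seen <- new.env(parent = emptyenv())
  frontier <- term
  assign(term, TRUE, envir = seen)
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (ch in dag$children_of[[v]]) {
        if (!exists(ch, envir = seen, inherits = FALSE)) {
          assign(ch, TRUE, envir = seen)
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- nxt
  }
  ls(seen)
}

#' Export a DAG as Graphviz DOT text
#'
#' Plain-text rendering hook for term DAGs; nodes listed in `highlight`
#' are annotated with their score (e.g. enrichment significance).
#'
#' @param dag an [ontology_dag()]
#' @param highlight named numeric vector, names = term ids to annotate.
#'   Unknown ids are ignored with a warning.
#' @return a single character string of DOT source
#' @export
export_dot <- function(dag, highlight = numeric(0)) {
  ids <- dag$terms$id[!dag$terms$obsolete]
  if (length(highlight) > 0) {
    unknown <- setdiff(names(highlight), ids)
    if (length(unknown) > 0) {
      warning("highlight id(s) not in DAG ignored: ", paste(unknown, collapse = ", "))
      highlight <- highlight[setdiff(names(highlight), unknown)]
    }
  }
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  node_lines <- vapply(ids, function(id) {
    lab <- dag$terms$name[match(id, dag$terms$id)]
    if (id %in% names(highlight)) {
      sprintf("  %s [label=%s, score=%g, style=filled];",
              q(id), q(paste0(id, "\\n", lab, "\\nscore=", signif(highlight[[id]], 4))),
              highlight[[id]])
    } else {
      sprintf("  %s [label=%s];", q(id), q(paste0(id, "\\n", lab)))
    }
  }, "")
  edge_lines <- sprintf("  %s -> %s [label=%s];",
                        q(dag$edges$child), q(dag$edges$parent), q(dag$edges$relation))
  paste(c("digraph ontology {", node_lines, edge_lines, "}"), collapse = "\n")
}
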