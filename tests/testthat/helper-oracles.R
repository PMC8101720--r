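# Shared fixtures and independent brute-force oracles.

obo_lines <- function(...) paste(c(...), collapse = "\n")

# 4-term toy: chain C is_a A is_a R, plus sibling B is_a R
toy_chain_dag <- function() {
  parse_obo(obo_lines(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "is_a: R", "",
    "[Term]", "id: B", "name: b", "is_a: R", "",
    "[Term]", "id: C", "name: c", "is_a: A"
  ))
}

# diamond: D -> {B, C} -> R
toy_diamond_dag <- function() {
  parse_obo(obo_lines(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: B", "name: b", "is_a: R", "",
    "[Term]", "id: C", "name: c", "is_a: R", "",
    "[Term]", "id: D", "name: d", "is_a: B", "is_a: C"
  ))
}

random_dag <- function(n_terms, seed, p_extra = 0.15) {
  # random rooted DAG: each non-root term gets one parent among earlier
  # terms plus optional extra parents (earlier index => closer to root,
  # so the graph is acyclic by construction)
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    ps <- unique(c(sample.int(i - 1, 1),
                   which(runif(i - 1) < p_extra)))
    child <- c(child, rep(ids[i], length(ps)))
    parent <- c(parent, ids[ps])
  }
  terms <- data.frame(id = ids, name = ids, namespace = "test",
                      obsolete = FALSE, stringsAsFactors = FALSE)
  rel <- sample(c("is_a", "part_of"), length(child), replace = TRUE)
  edges <- data.frame(child = child, parent = parent, relation = rel,
                      stringsAsFactors = FALSE)
  ontology_dag(terms, edges)
}

# oracle: transitive reachability by repeated edge joins
brute_ancestors <- function(dag, term) {
  out <- term
  repeat {
    nxt <- unique(c(out, dag$edges$parent[dag$edges$child %in% out]))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# oracle: S value of each ancestor = max over ALL focal->ancestor paths of
# the product of edge weights, by exhaustive path enumeration
brute_s_values <- function(dag, focal, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- new.env(parent = emptyenv())
  recurse <- function(node, prod) {
    cur <- if (exists(node, envir = s, inherits = FALSE)) get(node, envir = s) else -Inf
    if (prod > cur) assign(node, prod, envir = s)
    idx <- which(dag$edges$child == node)
    for (i in idx) {
      recurse(dag$edges$parent[i], prod * weights[[dag$edges$relation[i]]])
    }
  }
  recurse(focal, 1)
  vals <- unlist(as.list(s))
  vals[order(names(vals))]
}

# oracle: hypergeometric upper tail by direct enumeration of choose() terms
brute_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# oracle: Benjamini-Hochberg step-up, computed literally from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  adj
}
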