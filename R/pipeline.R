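#' Default neurodegenerative-disease term set
#'
#' The eight Disease Ontology identifiers of the diseases studied as
#' Alzheimer comorbidities: Alzheimer's disease (AD), Parkinson's disease
#' (PD), Huntington's disease (HD), amyotrophic lateral sclerosis (ALS),
#' spinal muscular atrophy (SMA), Lewy body dementia (LBD),
#' frontotemporal dementia (FTD) and multiple sclerosis (MS).
#'
#' @return named character vector disease label -> DOID
#' @export
default_disease_terms <- function() {
  c(AD = "DOID:10652", PD = "DOID:14330", HD = "DOID:12858",
    ALS = "DOID:332", SMA = "DOID:12377", LBD = "DOID:12217",
    FTD = "DOID:9255", MS = "DOID:2377")
}

#' Disease-term similarity matrix
#'
#' Pairwise Wang-style term similarity of disease terms on the Disease
#' Ontology DAG. With the default weights this is the disease-level
#' proximity matrix of the pipeline.
#'
#' @param do_dag the Disease Ontology as an [ontology_dag()]
#' @param diseases named character vector label -> DO term id (defaults
#'   to [default_disease_terms()])
#' @param policy a [semsim_policy()]
#' @return a `similarity_matrix` with level `"do_terms"`
#' @export
do_similarity_matrix <- function(do_dag, diseases = default_disease_terms(),
                                 policy = semsim_policy()) {
  missing <- diseases[!diseases %in% do_dag$terms$id]
  if (length(missing) > 0) {
    stop("DO term(s) absent from the ontology: ", paste(missing, collapse = ", "))
  }
  similarity_matrix(do_dag, as.list(diseases), policy, level = "do_terms")
}

#' Cross-disease DEG overlap table
#'
#' Genes differentially expressed in datasets of at least two different
#' diseases. When a reference disease is named (e.g. `"AD"`), a gene must
#' appear in at least one reference dataset *and* one non-reference
#' dataset; otherwise membership in any two datasets qualifies. Rows are
#' ordered by dataset count descending, then gene id.
#'
#' @param deg_sets named list dataset name -> character vector of DEGs
#' @param diseases optional named character vector dataset name -> disease
#'   label
#' @param reference optional reference disease label
#' @return data.frame with columns `gene`, `n_datasets`, `datasets`
#'   (comma-separated)
#' @export
deg_overlap <- function(deg_sets, diseases = NULL, reference = NULL) {
  if (length(deg_sets) < 2) stop("need at least two DEG sets")
  membership <- lapply(deg_sets, unique)
  genes <- unique(unlist(membership))
  rows <- lapply(genes, function(g) {
    ds <- names(membership)[vapply(membership, function(s) g %in% s, TRUE)]
    if (!is.null(diseases) && !is.null(reference)) {
      dz <- unique(diseases[ds])
      if (!(reference %in% dz && length(setdiff(dz, reference)) > 0)) return(NULL)
    } else {
      if (length(ds) < 2) return(NULL)
    }
    data.frame(gene = g, n_datasets = length(ds),
               datasets = paste(sort(ds), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(0), n_datasets = integer(0),
                      datasets = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(-out$n_datasets, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average-linkage dendrogram of a similarity matrix, in Newick text
#'
#' Agglomerative clustering on the dissimilarity `d = 1 - similarity`
#' (clipped to \[0, 1\]); node heights are the merge heights of the
#' clustering. Default linkage is average (UPGMA).
#'
#' @param sim a `similarity_matrix` (or symmetric numeric matrix with
#'   dimnames) of at least 2 entities
#' @param linkage `"average"`, `"complete"` or `"single"`
#' @return Newick string (terminated by `;`) with branch lengths
#' @export
cluster_dendrogram <- function(sim, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- unclass(sim)
  if (nrow(m) < 2) stop("need at least 2 entities to cluster")
  if (max(abs(m - t(m))) > 1e-9) stop("similarity matrix is not symmetric")
  d <- pmin(pmax(1 - m, 0), 1)
  hc <- hclust(as.dist(d), method = linkage)
  ape::write.tree(ape::as.phylo(hc))
}

#' Describe one disease dataset for the pipeline
#'
#' @param name unique dataset label (convention: disease code + accession,
#'   e.g. `"AD01_SIM"`)
#' @param disease disease label (used for overlap grouping)
#' @param do_term DO identifier of the disease
#' @param expr,design file paths of the expression and design TSVs
#' @param probe_map optional probe-to-gene TSV path
#' @return a `disease_dataset` list
#' @export
disease_dataset <- function(name, disease, do_term, expr, design,
                            probe_map = NULL) {
  structure(list(name = name, disease = disease, do_term = do_term,
                 expr = expr, design = design, probe_map = probe_map),
            class = "disease_dataset")
}

#' Assemble and validate a pipeline configuration
#'
#' @param datasets list of [disease_dataset()] descriptors (or plain
#'   lists with the same fields)
#' @param go_obo path to the GO OBO file (biological_process is used)
#' @param annotations path to gene-term annotation pairs (TSV or GAF)
#' @param do_obo optional path to the Disease Ontology OBO
#' @param gmt optional pathway GMT path
#' @param out_dir output directory
#' @param p_max,lfc_min,use_adjusted DEG thresholds (see [select_degs()])
#' @param top_k_terms enriched terms kept per dataset (default 5)
#' @param weights semantic contribution factors (see [semsim_policy()])
#' @param linkage dendrogram linkage method
#' @param restrict_top_terms if TRUE, the DEG-level similarity uses only
#'   DEGs annotated to the dataset's top enriched terms
#' @param reference_disease disease label treated as the index disease in
#'   the overlap table (default: disease of the first dataset)
#' @param min_term_size smallest annotated term tested for enrichment
#' @param skip_failed drop datasets whose screen fails instead of aborting
#' @param seed integer seed recorded in the manifest (reserved for
#'   resampling extensions)
#' @return a validated `run_config`
#' @export
run_config <- function(datasets, go_obo, annotations, do_obo = NULL,
                       gmt = NULL, out_dir = "comorbsim_out",
                       p_max = 0.05, lfc_min = 1.0, use_adjusted = FALSE,
                       top_k_terms = 5, weights = c(is_a = 0.8, part_of = 0.6),
                       linkage = "average", restrict_top_terms = FALSE,
                       reference_disease = NULL, min_term_size = 3,
                       skip_failed = FALSE, seed = 1) {
  stopifnot(length(datasets) >= 1, p_max > 0, lfc_min >= 0, top_k_terms >= 1)
  datasets <- lapply(datasets, function(d) {
    d <- as.list(d)
    req <- c("name", "disease", "do_term", "expr", "design")
    if (!all(req %in% names(d))) {
      stop("dataset descriptor missing field(s): ",
           paste(setdiff(req, names(d)), collapse = ", "))
    }
    d
  })
  nm <- vapply(datasets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  for (f in c(vapply(datasets, `[[`, "", "expr"),
              vapply(datasets, `[[`, "", "design"),
              go_obo, annotations, do_obo, gmt)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
  }
  if (is.null(reference_disease)) reference_disease <- datasets[[1]]$disease
  structure(list(datasets = datasets, go_obo = go_obo, annotations = annotations,
                 do_obo = do_obo, gmt = gmt, out_dir = out_dir,
                 p_max = p_max, lfc_min = lfc_min, use_adjusted = use_adjusted,
                 top_k_terms = top_k_terms, weights = weights, linkage = linkage,
                 restrict_top_terms = restrict_top_terms,
                 reference_disease = reference_disease,
                 min_term_size = min_term_size,
                 skip_failed = skip_failed, seed = seed),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; relative file paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  y$datasets <- lapply(y$datasets, function(d) {
    d$expr <- fix(d$expr); d$design <- fix(d$design)
    if (!is.null(d$probe_map)) d$probe_map <- fix(d$probe_map)
    d
  })
  for (f in c("go_obo", "annotations", "do_obo", "gmt")) {
    if (!is.null(y[[f]])) y[[f]] <- fix(y[[f]])
  }
  if (!is.null(y$weights)) y$weights <- unlist(y$weights)
  do.call(run_config, y)
}

#' Run the full comorbidity-proximity pipeline
#'
#' Per dataset: differential-expression screen, DEG selection, GO
#' over-representation and top-term extraction. Across datasets: the
#' three-level similarity matrices (union of the DEGs' GO annotation
#' sets; top enriched GO terms; DO terms), the cross-disease DEG overlap
#' table, optional pathway enrichment, and average-linkage dendrograms
#' for every matrix with at least two entities. All outputs are written
#' to `config$out_dir` as plain text plus a machine-readable manifest;
#' outputs are deterministic, so identical configurations yield
#' byte-identical files.
#'
#' Datasets with no DEGs at the configured thresholds are excluded from
#' the DEG-level and GO-term-level matrices with a warning.
#'
#' @param config a [run_config()] (or path to a YAML file)
#' @return invisibly, a list with the per-dataset results, the three
#'   similarity matrices, the overlap table and the manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  logf <- file(out("run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  logmsg <- function(...) writeLines(paste0(...), logf)

  policy <- semsim_policy(config$weights)
  go_dag <- parse_obo(config$go_obo, namespace_filter = "biological_process")
  annot_pairs <- read_annotation_pairs(config$annotations)
  annot <- build_annotation(go_dag, annot_pairs)
  gene_sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
  logmsg("ontology: ", n_terms(go_dag), " terms; annotations: ",
         nrow(annot_pairs), " pairs")

  per_dataset <- list()
  for (ds in config$datasets) {
    res <- tryCatch({
      m <- read_expression(ds$expr)
      design <- read_design(ds$design)
      probe_map <- NULL
      if (!is.null(ds$probe_map)) {
        pm <- read.delim(ds$probe_map, stringsAsFactors = FALSE)
        probe_map <- setNames(as.character(pm[[2]]), as.character(pm[[1]]))
      }
      dge <- run_dge(m, design, probe_map, config$p_max, config$lfc_min,
                     config$use_adjusted)
      degs <- sort(unique(c(dge$degs$up, dge$degs$down)))
      universe <- rownames(dge$matrix)
      enr <- if (length(degs) > 0) {
        fisher_enrich(degs, universe, annot, config$min_term_size)
      } else NULL
      top <- if (!is.null(enr) && nrow(enr) > 0) {
        suppressWarnings(top_terms(enr, config$top_k_terms))
      } else NULL
      pw <- if (!is.null(gene_sets) && length(degs) > 0) {
        pathway_enrich(degs, universe, gene_sets, config$min_term_size)
      } else NULL
      list(name = ds$name, disease = ds$disease, do_term = ds$do_term,
           table = dge$table, degs = degs, up = dge$degs$up,
           down = dge$degs$down, universe = universe,
           enrichment = enr, top_terms = top, pathways = pw)
    }, error = function(e) {
      if (!config$skip_failed) {
        stop("dataset '", ds$name, "' failed: ", conditionMessage(e))
      }
      warning("dataset '", ds$name, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) per_dataset[[ds$name]] <- res
  }
  if (length(per_dataset) == 0) stop("no dataset produced results")

  # per-dataset outputs
  for (r in per_dataset) {
    write.table(r$table, out(paste0(r$name, "_dge.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(r$up, out(paste0(r$name, "_degs_up.txt")))
    writeLines(r$down, out(paste0(r$name, "_degs_down.txt")))
    if (!is.null(r$enrichment)) {
      write.table(r$enrichment, out(paste0(r$name, "_go_enrichment.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(r$pathways)) {
      write.table(r$pathways, out(paste0(r$name, "_pathways.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logmsg(r$name, ": ", length(r$up), " up / ", length(r$down), " down DEGs; ",
           if (is.null(r$enrichment)) 0 else nrow(r$enrichment), " terms tested")
  }

  # DEG-level term sets: union of (direct) GO annotations of each
  # dataset's DEGs, optionally restricted to genes annotated to the
  # dataset's top enriched terms
  deg_term_sets <- list()
  for (r in per_dataset) {
    genes <- r$degs
    if (isTRUE(config$restrict_top_terms) && !is.null(r$top_terms)) {
      in_top <- unique(unlist(lapply(r$top_terms$term,
                                     function(t) annot$term_to_genes[[t]])))
      genes <- intersect(genes, in_top)
    }
    terms <- unique(unlist(annot$gene_to_terms[genes]))
    if (length(terms) > 0) deg_term_sets[[r$name]] <- terms
  }
  excluded <- setdiff(names(per_dataset), names(deg_term_sets))
  if (length(excluded) > 0) {
    warning("dataset(s) without annotated DEGs excluded from the DEG-level matrix: ",
            paste(excluded, collapse = ", "))
  }

  go_term_sets <- list()
  for (r in per_dataset) {
    if (!is.null(r$top_terms) && nrow(r$top_terms) > 0) {
      go_term_sets[[r$name]] <- r$top_terms$term
    }
  }

  matrices <- list()
  if (length(deg_term_sets) >= 1) {
    matrices$deg <- similarity_matrix(go_dag, deg_term_sets, policy, "deg")
  }
  if (length(go_term_sets) >= 1) {
    matrices$go_terms <- similarity_matrix(go_dag, go_term_sets, policy, "go_terms")
  }
  if (!is.null(config$do_obo)) {
    do_dag <- parse_obo(config$do_obo)
    diseases <- vapply(per_dataset, `[[`, "", "do_term")
    matrices$do_terms <- do_similarity_matrix(do_dag, diseases, policy)
  }

  for (lv in names(matrices)) {
    write_similarity_matrix(matrices[[lv]], out(paste0("similarity_", lv, ".tsv")))
    if (nrow(matrices[[lv]]) >= 2) {
      writeLines(cluster_dendrogram(matrices[[lv]], config$linkage),
                 out(paste0("dendrogram_", lv, ".nwk")))
    }
  }

  overlap <- if (length(per_dataset) >= 2) {
    deg_overlap(lapply(per_dataset, `[[`, "degs"),
                diseases = vapply(per_dataset, `[[`, "", "disease"),
                reference = config$reference_disease)
  } else {
    data.frame(gene = character(0), n_datasets = integer(0),
               datasets = character(0), stringsAsFactors = FALSE)
  }
  write.table(overlap, out("deg_overlap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package = "comorbsim",
    seed = config$seed,
    thresholds = list(p_max = config$p_max, lfc_min = config$lfc_min,
                      use_adjusted = config$use_adjusted,
                      top_k_terms = config$top_k_terms,
                      min_term_size = config$min_term_size),
    weights = as.list(config$weights),
    linkage = config$linkage,
    datasets = lapply(per_dataset, function(r) {
      list(name = r$name, disease = r$disease, do_term = r$do_term,
           n_up = length(r$up), n_down = length(r$down),
           n_universe = length(r$universe))
    }),
    matrices = names(matrices)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  logmsg("wrote ", length(matrices), " similarity matrices; overlap rows: ",
         nrow(overlap))

  invisible(list(datasets = per_dataset, matrices = matrices,
                 overlap = overlap, manifest = manifest))
}
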