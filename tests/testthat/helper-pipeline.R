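# Build a small synthetic multi-dataset study on disk and return its
# run_config. Datasets 1 and 2 (AD, PD) share every planted DE gene;
# dataset 3 (MS) has a disjoint planted set.
make_toy_study <- function(dir, seed = 1, n_genes = 150, n_de = 12,
                           gmt = FALSE, do_obo = TRUE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  shared <- genes[seq_len(n_de)]
  distinct <- genes[seq(n_de + 1, 2 * n_de)]

  plant <- function(base_seed, planted) {
    sim <- simulate_expression(simulation_spec(
      n_genes = n_genes, n_de = 0, sigma = 0.5, seed = base_seed))
    sim$matrix[planted, sim$design == "case"] <-
      sim$matrix[planted, sim$design == "case"] + 2
    sim$truth <- data.frame(gene = planted, lfc = 2, stringsAsFactors = FALSE)
    sim
  }
  sims <- list(
    AD01_SIM = plant(seed, shared),
    PD01_SIM = plant(seed + 1, shared),
    MS01_SIM = plant(seed + 2, distinct)
  )
  meta <- list(AD01_SIM = c("AD", "DOID:10652"),
               PD01_SIM = c("PD", "DOID:14330"),
               MS01_SIM = c("MS", "DOID:2377"))
  datasets <- lapply(names(sims), function(nm) {
    files <- write_simulation(sims[[nm]], dir, prefix = nm)
    disease_dataset(name = nm, disease = meta[[nm]][1], do_term = meta[[nm]][2],
                    expr = files[["expr"]], design = files[["design"]])
  })

  obo <- simulate_ontology(depth = 3, branching = 3, seed = seed)
  go_path <- file.path(dir, "go.obo")
  writeLines(obo, go_path)
  dag <- parse_obo(obo)
  ann <- simulate_annotations(genes, dag, mean_terms = 2, seed = seed)
  ann_path <- file.path(dir, "annotations.tsv")
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gmt_path <- NULL
  if (gmt) {
    gmt_path <- file.path(dir, "pathways.gmt")
    writeLines(c(
      paste(c("shared_pathway", "na", shared), collapse = "\t"),
      paste(c("background_pathway", "na", genes[101:140]), collapse = "\t")
    ), gmt_path)
  }

  run_config(datasets = datasets, go_obo = go_path, annotations = ann_path,
             do_obo = if (do_obo) synthetic_do_path() else NULL,
             gmt = gmt_path, out_dir = file.path(dir, "out"), seed = seed, ...)
}
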