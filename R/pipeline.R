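#' Load pipeline inputs from files
#'
#' Reads a directory of structure entries plus the FASTA, interaction and
#' optional variant tables into the in-memory form the pipeline consumes.
#'
#' @param entries_dir Directory of PDB/mmCIF entry files.
#' @param fasta FASTA of protein sequences.
#' @param interactions Interaction TSV (see [read_interactions()]).
#' @param variants Optional variant TSV (see [read_variants()]).
#' @return List with `proteins`, `library` (all entry chains),
#'   `interactions`, `variants`.
#' @export
load_inputs <- function(entries_dir, fasta, interactions, variants = NULL) {
  files <- sort(list.files(entries_dir, pattern = "\\.(pdb|cif)$",
                           full.names = TRUE))
  library_chains <- list()
  for (f in files) {
    library_chains <- c(library_chains, read_structure(f))
  }
  list(proteins = read_fasta_proteins(fasta),
       library = unname(library_chains),
       interactions = read_interactions(interactions),
       variants = if (!is.null(variants)) read_variants(variants) else NULL)
}

#' Run the full complex-modeling pipeline
#'
#' Classifies interactions, selects structure elements, clusters modelable
#' sub-networks, assembles models from every starting point, detects and
#' types interfaces, and flags indirect interactions.  Optionally writes
#' per-model PDB files (with JSON provenance sidecars), an interface TSV
#' and an alternative-interface TSV to `out_dir`.
#'
#' @param inputs Result of [load_inputs()] (or an equivalently shaped
#'   list).
#' @param out_dir Optional output directory.
#' @param mode Anchor selection mode, `"degree"` (default) or `"random"`.
#' @param seed Seed for `mode = "random"`.
#' @param min_identity Homology threshold (default 0.25).
#' @param detect Logical: run interface detection/typing (default TRUE;
#'   skipping saves the surface-area computation when only assembly is
#'   needed).
#' @return List with `dataset` (elements + category tally), `networks`,
#'   `models` (per network, deduplicated), `interfaces` (typed, per
#'   model), `indirect` (flags per model), `alternatives`
#'   (alternative-interface records per model).
#' @export
run_pipeline <- function(inputs, out_dir = NULL, mode = "degree", seed = 1L,
                         min_identity = 0.25, detect = TRUE) {
  dataset <- build_element_dataset(inputs$interactions, inputs$proteins,
                                   inputs$library, min_identity)
  networks <- cluster_subnetworks(dataset$elements)
  models <- list(); interfaces <- list(); indirect <- list()
  alternatives <- list()
  mi <- 0L
  for (net in networks) {
    for (model in build_all_models(net, mode = mode, seed = seed)) {
      mi <- mi + 1L
      mid <- sprintf("M%03d", mi)
      models[[mid]] <- model
      if (detect) {
        ifs <- detect_interfaces(model)
        ifs <- type_interfaces(model, ifs, inputs$interactions)
        interfaces[[mid]] <- ifs
        indirect[[mid]] <- flag_indirect(model, ifs, inputs$interactions)
      }
      alternatives[[mid]] <- model$alternative_records
    }
  }
  out <- list(dataset = dataset, networks = networks, models = models,
              interfaces = interfaces, indirect = indirect,
              alternatives = alternatives)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_element_dataset(dataset, file.path(out_dir, "elements.json"))
    write_subnetworks(networks,
                      tsv_path = file.path(out_dir, "subnetworks.tsv"),
                      json_path = file.path(out_dir, "subnetworks.json"))
    for (mid in names(models)) {
      write_complex(models[[mid]], file.path(out_dir, paste0(mid, ".pdb")))
      if (detect && length(interfaces[[mid]]) > 0) {
        write_interface_table(interfaces[[mid]],
                              file.path(out_dir, paste0(mid,
                                                        "_interfaces.tsv")),
                              flags = indirect[[mid]], model_id = mid)
      }
    }
    alt_rows <- do.call(rbind, lapply(names(alternatives), function(mid) {
      recs <- alternatives[[mid]]
      if (length(recs) == 0) return(NULL)
      do.call(rbind, lapply(recs, function(r)
        data.frame(model = mid, owner = r$owner, partner_a = r$partner_a,
                   partner_b = r$partner_b, stringsAsFactors = FALSE)))
    }))
    if (!is.null(alt_rows)) {
      utils::write.table(alt_rows,
                         file.path(out_dir, "alternative_interfaces.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
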