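# Theoretical maximum accessible areas (Angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide; used to turn absolute residue SASA into
# relative accessibility.  (Tien et al. 2013 theoretical values.)
.MAX_ACC <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
              E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
              M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
              Y = 263, V = 174, X = 200)

#' Amino-acid variant record
#'
#' @param accession Protein accession the variant belongs to.
#' @param position 1-based sequence position.
#' @param ref_aa,alt_aa One-letter reference and alternate amino acids.
#' @param var_class One of `polymorphism`, `disease`, `unclassified`.
#' @return Object of class `variant_record`.
#' @export
variant_record <- function(accession, position, ref_aa, alt_aa, var_class) {
  position <- as.integer(position)
  if (position < 1) stop("position must be >= 1")
  var_class <- match.arg(var_class,
                         c("polymorphism", "disease", "unclassified"))
  structure(list(accession = as.character(accession), position = position,
                 ref_aa = as.character(ref_aa), alt_aa = as.character(alt_aa),
                 var_class = var_class),
            class = "variant_record")
}

#' Read a variant table
#'
#' TSV with header columns `accession`, `position`, `ref_aa`, `alt_aa`,
#' `var_class`.
#'
#' @param path TSV path.
#' @return List of [variant_record()].
#' @export
read_variants <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    variant_record(tab$accession[i], tab$position[i], tab$ref_aa[i],
                   tab$alt_aa[i], tab$var_class[i]))
}

#' Extrapolate a model to homologous subunit combinations
#'
#' Each subunit may be substituted by any of its homologues (identity above
#' 0.25 to the original); the Cartesian product over per-subunit homologue
#' lists yields the extrapolated model variants, `prod(list sizes)` in
#' total.  Lists are expected to include the original protein (a proteome
#' scan trivially retrieves it); a subunit with an empty list keeps the
#' original only.  Substituted sequences are remapped onto the subunit's
#' template chain by alignment; no remodeling is performed.
#'
#' @param model A `complex_model`.
#' @param homologue_map Named list: accession -> character vector of
#'   homologous accessions.
#' @param proteins Named list of [protein_entry()] (needed to realign
#'   substituted sequences; may be omitted when only counting).
#' @return List of model variants: each `list(assignment, maps)` where
#'   `assignment` maps subunit ID -> accession and `maps` maps subunit
#'   ID -> (target position -> template residue) lookup.  The original
#'   combination comes first.
#' @export
extrapolate_models <- function(model, homologue_map, proteins = NULL) {
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  orig <- vapply(model$subunits, function(s) s$protein, character(1))
  lists <- lapply(seq_along(ids), function(i) {
    h <- homologue_map[[orig[i]]]
    if (is.null(h) || length(h) == 0) orig[i]
    else unique(c(orig[i], setdiff(h, orig[i])))
  })
  grid <- expand.grid(lapply(lists, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    assignment <- setNames(vapply(seq_along(ids), function(i)
      lists[[i]][[grid[r, i]]], character(1)), ids)
    maps <- setNames(lapply(seq_along(ids), function(i) {
      acc <- assignment[[i]]
      sub <- model$subunits[[i]]
      if (acc == orig[i] || is.null(proteins)) return(sub$target_map)
      aln <- align_pair(proteins[[acc]]$sequence,
                        chain_sequence(sub$chain))
      .target_map(aln, sub$chain)
    }), ids)
    list(assignment = assignment, maps = maps)
  })
}

#' Classify the molecular environment of one residue position
#'
#' The position is mapped through the subunit's target-to-template
#' alignment.  Unmapped positions (gapped columns) and template residues
#' without coordinates are `disordered`.  Mapped residues with relative
#' accessibility (residue SASA on the isolated subunit divided by the
#' residue type's Gly-X-Gly maximum) below 0.1 are `interior`.  Exposed
#' residues belonging to a detected interface's residue set are
#' `interface` (carrying the interface's type as subtype); the rest are
#' `surface`.
#'
#' @param model A `complex_model`.
#' @param subunit Subunit ID or index.
#' @param position 1-based position in the target protein sequence.
#' @param interfaces Result of [type_interfaces()] (or
#'   [detect_interfaces()]) for this model.
#' @param target_map Optional override of the subunit's position map (used
#'   for extrapolated homologues).
#' @param isolated_sasa Optional precomputed [sasa()] table of the isolated
#'   subunit chain (caching across many variants).
#' @return List with `environment` and `interface_subtype` (`NA` unless
#'   environment is `interface`).
#' @export
classify_environment <- function(model, subunit, position, interfaces,
                                 target_map = NULL, isolated_sasa = NULL) {
  i <- .subunit_index(model, subunit)
  sub <- model$subunits[[i]]
  if (is.null(target_map)) target_map <- sub$target_map
  res_idx <- target_map[as.character(position)]
  if (length(res_idx) == 0 || is.na(res_idx)) {
    return(list(environment = "disordered",
                interface_subtype = NA_character_))
  }
  res_row <- match(res_idx, sub$chain$residues$seq_index)
  if (is.na(res_row) || !sub$chain$residues$has_coords[res_row]) {
    return(list(environment = "disordered",
                interface_subtype = NA_character_))
  }
  if (is.null(isolated_sasa)) isolated_sasa <- sasa(sub$chain)
  area <- isolated_sasa$area[match(res_idx, isolated_sasa$seq_index)]
  aa <- sub$chain$residues$aa[res_row]
  mx <- .MAX_ACC[aa]
  if (is.na(mx)) mx <- .MAX_ACC[["X"]]
  if (area / mx < 0.1) {
    return(list(environment = "interior", interface_subtype = NA_character_))
  }
  subtype_rank <- c(experimental = 1, model_predicted = 2,
                    model_suggested = 3)
  best <- NA_character_
  for (f in interfaces) {
    hit <- (f$subunit_a == sub$subunit_id && res_idx %in% f$residues_a) ||
           (f$subunit_b == sub$subunit_id && res_idx %in% f$residues_b)
    if (hit) {
      ty <- if (is.na(f$type)) "model_suggested" else f$type
      if (is.na(best) || subtype_rank[ty] < subtype_rank[best]) best <- ty
    }
  }
  if (!is.na(best)) {
    return(list(environment = "interface", interface_subtype = best))
  }
  list(environment = "surface", interface_subtype = NA_character_)
}

#' Map a variant table onto a model
#'
#' Convenience wrapper classifying every variant whose accession matches a
#' placed (or extrapolated) subunit.  A variant hitting interfaces in
#' several subunits or models is counted once with subtype priority
#' experimental > model_predicted > model_suggested.
#'
#' @param model A `complex_model`.
#' @param interfaces Typed interfaces for the model.
#' @param variants List of [variant_record()].
#' @param assignment Optional named vector subunit ID -> accession
#'   (defaults to the model's own proteins).
#' @param maps Optional named list of position maps per subunit (for
#'   extrapolated assignments).
#' @return `data.frame`: `accession`, `position`, `var_class`,
#'   `environment`, `interface_subtype`.
#' @export
map_variants <- function(model, interfaces, variants, assignment = NULL,
                         maps = NULL) {
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  if (is.null(assignment)) {
    assignment <- setNames(vapply(model$subunits, function(s) s$protein,
                                  character(1)), ids)
  }
  sasa_cache <- setNames(vector("list", length(ids)), ids)
  rank <- c(interface = 1, interior = 2, surface = 3, disordered = 4)
  strank <- c(experimental = 1, model_predicted = 2, model_suggested = 3)
  rows <- lapply(variants, function(v) {
    hit_ids <- ids[assignment == v$accession]
    if (length(hit_ids) == 0) return(NULL)
    best <- NULL
    for (sid in hit_ids) {
      if (is.null(sasa_cache[[sid]])) {
        sasa_cache[[sid]] <<- sasa(
          model$subunits[[.subunit_index(model, sid)]]$chain)
      }
      env <- classify_environment(
        model, sid, v$position, interfaces,
        target_map = if (!is.null(maps)) maps[[sid]] else NULL,
        isolated_sasa = sasa_cache[[sid]])
      if (is.null(best) ||
          rank[env$environment] < rank[best$environment] ||
          (env$environment == "interface" &&
             best$environment == "interface" &&
             strank[env$interface_subtype] <
               strank[best$interface_subtype])) {
        best <- env
      }
    }
    data.frame(accession = v$accession, position = v$position,
               var_class = v$var_class, environment = best$environment,
               interface_subtype = best$interface_subtype,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(), position = integer(),
                      var_class = character(), environment = character(),
                      interface_subtype = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Environment enrichment tests
#'
#' For every environment and every variant class other than the baseline,
#' the observed count is compared with the count expected if the class
#' followed the baseline class's distribution over environments
#' (chi-squared test on the 2x2 table class-in-cell / class-elsewhere vs
#' baseline-in-cell / baseline-elsewhere, without continuity correction).
#'
#' @param assignments `data.frame` from [map_variants()] (columns
#'   `var_class`, `environment`).
#' @param baseline_class The reference class (default `"polymorphism"`).
#' @return `data.frame`: `var_class`, `environment`, `observed`,
#'   `expected`, `p_value`, `test`.  Cells with a zero baseline margin are
#'   skipped with a message.
#' @export
enrichment_tests <- function(assignments, baseline_class = "polymorphism") {
  stopifnot(length(unique(assignments$var_class)) >= 2)
  envs <- c("interface", "surface", "interior", "disordered")
  base <- assignments[assignments$var_class == baseline_class, ]
  nb <- nrow(base)
  rows <- list()
  for (cls in setdiff(unique(assignments$var_class), baseline_class)) {
    cur <- assignments[assignments$var_class == cls, ]
    nc <- nrow(cur)
    for (e in envs) {
      b_in <- sum(base$environment == e)
      c_in <- sum(cur$environment == e)
      if (nb == 0 || (b_in + c_in) == 0) {
        message("skipping cell ", cls, "/", e, ": zero margin")
        next
      }
      expected <- nc * b_in / nb
      tab <- matrix(c(c_in, nc - c_in, b_in, nb - b_in), nrow = 2)
      p <- tryCatch(
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
        error = function(err) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        var_class = cls, environment = e, observed = c_in,
        expected = expected, p_value = p, test = "chisq",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric enrichment test
#'
#' One-sided upper-tail probability of drawing at least `overlap` marked
#' items when `draw` items are sampled without replacement from a universe
#' of `universe` items of which `marked` are marked.
#'
#' @param overlap Observed overlap count.
#' @param marked Number of marked items in the universe.
#' @param draw Sample size.
#' @param universe Universe size.
#' @return P-value.
#' @export
hypergeom_enrichment <- function(overlap, marked, draw, universe) {
  stopifnot(universe >= marked, universe >= draw, overlap <= min(marked, draw))
  stats::phyper(overlap - 1, marked, universe - marked, draw,
                lower.tail = FALSE)
}

#' Variant environment summary table
#'
#' Counts per class x environment (interface split by subtype), with
#' expected values under the baseline distribution — the layout used for
#' reporting variant mapping results.
#'
#' @param assignments `data.frame` from [map_variants()].
#' @param path Optional TSV output path.
#' @param baseline_class Baseline for expected values.
#' @return The summary `data.frame`, invisibly when `path` is given.
#' @export
variant_environment_table <- function(assignments, path = NULL,
                                      baseline_class = "polymorphism") {
  cols <- c("interface_experimental", "interface_model_predicted",
            "interface_model_suggested", "surface", "interior", "disordered")
  classes <- unique(assignments$var_class)
  cellname <- function(df) ifelse(
    df$environment == "interface",
    paste0("interface_", df$interface_subtype), df$environment)
  tab <- t(vapply(classes, function(cls) {
    cur <- assignments[assignments$var_class == cls, ]
    cn <- cellname(cur)
    vapply(cols, function(cc) sum(cn == cc), numeric(1))
  }, numeric(length(cols))))
  out <- data.frame(var_class = classes, tab, total = rowSums(tab),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
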