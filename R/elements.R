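#' Structure element: a binary complex template for an interaction
#'
#' A `ppi_element` couples one recorded binary interaction with the pair of
#' co-determined chains selected as its modeling template, together with
#' the per-side identities and residue mappings (target position ->
#' template position).
#'
#' @param interaction An [interaction_record()].
#' @param chain_a,chain_b Template [chain_structure()] objects from one
#'   structure entry; `chain_a` templates `interaction$acc_a`.
#' @param ident_a,ident_b Identity fractions of the two sides (each must
#'   exceed 0.25).
#' @param mapping_a,mapping_b [align_pair()] results (target vs template).
#' @return Object of class `ppi_element`.
#' @export
ppi_element <- function(interaction, chain_a, chain_b, ident_a, ident_b,
                        mapping_a = NULL, mapping_b = NULL) {
  if (!identical(chain_a$source_entry, chain_b$source_entry)) {
    stop("template chains must be co-determined (same structure entry)")
  }
  if (ident_a <= 0.25 || ident_b <= 0.25) {
    stop("template identities must exceed 0.25 on both sides")
  }
  structure(list(interaction = interaction,
                 template_entry = chain_a$source_entry,
                 chain_a = chain_a, chain_b = chain_b,
                 ident_a = ident_a, ident_b = ident_b,
                 mapping_a = mapping_a, mapping_b = mapping_b),
            class = "ppi_element")
}

#' @export
print.ppi_element <- function(x, ...) {
  cat(sprintf("<ppi_element> %s-%s on %s chains %s/%s (id %.2f/%.2f)\n",
              x$interaction$acc_a, x$interaction$acc_b, x$template_entry,
              x$chain_a$chain_id, x$chain_b$chain_id, x$ident_a, x$ident_b))
  invisible(x)
}

#' Select the template for one interaction
#'
#' Among candidate co-determined chain pairs, the pair with the highest
#' average identity over the two sides is selected.  Ties are broken
#' lexicographically by (template entry, chain A id, chain B id) and the
#' runner-up list is recorded in the result's `runners_up` attribute so the
#' choice is auditable.
#'
#' @param rec An [interaction_record()].
#' @param candidates List of candidates, each a list with `chain_a`,
#'   `chain_b`, `ident_a`, `ident_b` and optionally `mapping_a`,
#'   `mapping_b`.
#' @return A [ppi_element()], or `NULL` when `candidates` is empty.
#' @export
select_element <- function(rec, candidates) {
  if (length(candidates) == 0) return(NULL)
  avg <- vapply(candidates, function(cd) (cd$ident_a + cd$ident_b) / 2,
                numeric(1))
  ent <- vapply(candidates, function(cd) cd$chain_a$source_entry, character(1))
  ca <- vapply(candidates, function(cd) cd$chain_a$chain_id, character(1))
  cb <- vapply(candidates, function(cd) cd$chain_b$chain_id, character(1))
  ord <- order(-avg, ent, ca, cb)
  best <- candidates[[ord[1]]]
  el <- ppi_element(rec, best$chain_a, best$chain_b, best$ident_a,
                    best$ident_b, best$mapping_a, best$mapping_b)
  attr(el, "runners_up") <- lapply(ord[-1], function(i) {
    cd <- candidates[[i]]
    list(template_entry = cd$chain_a$source_entry,
         chain_a = cd$chain_a$chain_id, chain_b = cd$chain_b$chain_id,
         avg_identity = (cd$ident_a + cd$ident_b) / 2)
  })
  el
}

# all co-determined candidate chain pairs for one interaction; homo-oligomer
# templates contribute every distinct ordered chain pair geometry
.element_candidates <- function(rec, proteins, library, min_identity) {
  ha <- find_homologues(proteins[[rec$acc_a]], library, min_identity)
  hb <- if (rec$acc_a == rec$acc_b) ha
        else find_homologues(proteins[[rec$acc_b]], library, min_identity)
  if (length(ha) == 0 || length(hb) == 0) return(list())
  out <- list()
  for (a in ha) {
    for (b in hb) {
      if (!identical(a$chain$source_entry, b$chain$source_entry)) next
      if (identical(a$chain$chain_id, b$chain$chain_id)) next
      out[[length(out) + 1L]] <- list(
        chain_a = a$chain, chain_b = b$chain,
        ident_a = a$alignment$identity_fraction,
        ident_b = b$alignment$identity_fraction,
        mapping_a = a$alignment, mapping_b = b$alignment)
    }
  }
  out
}

#' Build the structure element dataset
#'
#' Classifies every interaction against the library and, for each
#' complex-category interaction, selects its template by highest average
#' identity.  Output order follows the input interaction order, so runs are
#' deterministic.
#'
#' @param interactions List of [interaction_record()].
#' @param proteins Named list of [protein_entry()].
#' @param library List of [chain_structure()].
#' @param min_identity Exclusive identity threshold (default 0.25).
#' @return List with `elements` (list of [ppi_element()]) and `tally`
#'   (named integer vector over the four categories).
#' @export
build_element_dataset <- function(interactions, proteins, library,
                                  min_identity = 0.25) {
  tally <- c(complex = 0L, independent = 0L, one_sided = 0L, unknown = 0L)
  elements <- list()
  for (rec in interactions) {
    cat_ <- classify_interaction(rec, proteins, library, min_identity)
    tally[cat_] <- tally[cat_] + 1L
    if (cat_ == "complex") {
      cand <- .element_candidates(rec, proteins, library, min_identity)
      el <- select_element(rec, cand)
      if (!is.null(el)) elements[[length(elements) + 1L]] <- el
    }
  }
  list(elements = elements, tally = tally)
}

#' Serialize an element dataset to JSON
#'
#' @param dataset Result of [build_element_dataset()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_element_dataset <- function(dataset, path) {
  recs <- lapply(dataset$elements, function(el) {
    list(acc_a = el$interaction$acc_a, acc_b = el$interaction$acc_b,
         source_id = el$interaction$source_id,
         template_entry = el$template_entry,
         chain_a = el$chain_a$chain_id, chain_b = el$chain_b$chain_id,
         ident_a = el$ident_a, ident_b = el$ident_b,
         mapping_a = if (!is.null(el$mapping_a))
           apply(el$mapping_a$aligned_pairs, 1, as.list) else NULL,
         mapping_b = if (!is.null(el$mapping_b))
           apply(el$mapping_b$aligned_pairs, 1, as.list) else NULL)
  })
  jsonlite::write_json(list(tally = as.list(dataset$tally), elements = recs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
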