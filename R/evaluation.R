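#' CAPRI-style accuracy class from a ligand-subunit rmsd
#'
#' Closed upper bounds: rmsd <= 1 A is `high`, <= 5 A `medium`, <= 10 A
#' `acceptable`, above that `incorrect`.
#'
#' @param rmsd Non-negative rmsd in Angstrom (vectorized).
#' @return Character vector of class labels.
#' @export
capri_class <- function(rmsd) {
  ifelse(rmsd <= 1, "high",
         ifelse(rmsd <= 5, "medium",
                ifelse(rmsd <= 10, "acceptable", "incorrect")))
}

# match each model subunit to a distinct reference chain by best sequence
# identity (greedy, identity-descending); NULL when some subunit has no
# homologous chain left
.match_reference <- function(model, ref_chains, min_identity = 0.25) {
  ns <- length(model$subunits)
  cand <- list()
  for (i in seq_len(ns)) {
    for (j in seq_along(ref_chains)) {
      aln <- align_pair(chain_sequence(model$subunits[[i]]$chain),
                        chain_sequence(ref_chains[[j]]))
      if (aln$identity_fraction > min_identity) {
        cand[[length(cand) + 1L]] <- list(sub = i, ref = j, aln = aln)
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  ord <- order(-vapply(cand, function(cd) cd$aln$identity_fraction,
                       numeric(1)))
  used_s <- integer(); used_r <- integer(); out <- vector("list", ns)
  for (k in ord) {
    cd <- cand[[k]]
    if (cd$sub %in% used_s || cd$ref %in% used_r) next
    out[[cd$sub]] <- cd
    used_s <- c(used_s, cd$sub); used_r <- c(used_r, cd$ref)
  }
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  out
}

#' Find models eligible for the virtual blind test
#'
#' A model enters the blind test when its provenance spans at least two
#' template entries (so part of it was inferred rather than copied) and
#' some experimental reference complex contains homologues of all its
#' subunits.  The predicted subunits are those introduced from a template
#' entry different from their anchor's entry.
#'
#' @param models List of `complex_model`.
#' @param references List of references, each a list with `entry` (label)
#'   and `chains` (list of [chain_structure()]).
#' @param min_identity Homology threshold for subunit-to-reference-chain
#'   matching.
#' @return List of cases: `list(model, reference, matching,
#'   predicted_subunits)`; `matching` gives per-subunit reference chain and
#'   alignment.
#' @export
eligible_blind_cases <- function(models, references, min_identity = 0.25) {
  cases <- list()
  for (model in models) {
    entries <- vapply(model$subunits, function(s) s$template_pair[1],
                      character(1))
    if (length(unique(entries)) < 2) next
    anchor_of <- vapply(model$subunits, function(s) s$anchor, character(1))
    ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
    predicted <- ids[vapply(seq_along(ids), function(i) {
      ai <- match(anchor_of[i], ids)
      entries[i] != entries[ai]
    }, logical(1))]
    if (length(predicted) == 0) next
    for (ref in references) {
      if (length(ref$chains) < length(model$subunits)) next
      matching <- .match_reference(model, ref$chains, min_identity)
      if (is.null(matching)) next
      cases[[length(cases) + 1L]] <- list(model = model, reference = ref,
                                          matching = matching,
                                          predicted_subunits = predicted)
    }
  }
  cases
}

# matched CA coordinate pairs for one subunit against its reference chain
.blind_pairs <- function(sub, ref_chain, aln) {
  cm <- ca_coords(sub$chain); cr <- ca_coords(ref_chain)
  idx_m <- sub$chain$residues$seq_index[aln$aligned_pairs[, 1]]
  idx_r <- ref_chain$residues$seq_index[aln$aligned_pairs[, 2]]
  ok <- as.character(idx_m) %in% rownames(cm) &
        as.character(idx_r) %in% rownames(cr)
  list(P = cm[as.character(idx_m[ok]), , drop = FALSE],
       Q = cr[as.character(idx_r[ok]), , drop = FALSE])
}

#' Blind-test rmsd of a model against its experimental reference
#'
#' The whole model is superposed onto the reference over all matched
#' C-alpha pairs (overall rmsd).  For each predicted subunit, the
#' superposition is re-fit on the *other* (common) subunits only, and the
#' rmsd of the predicted subunit's matched C-alpha atoms is measured
#' without re-fitting — the l-rms convention of docking assessment.
#'
#' @param case One element of [eligible_blind_cases()]'s result.
#' @return List of class `blind_test_result`: `overall_rmsd`,
#'   `subunit_rmsds` (named by predicted subunit ID), `capri`
#'   (named class labels).
#' @export
blind_rmsd <- function(case) {
  model <- case$model
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  pairs <- lapply(seq_along(ids), function(i)
    .blind_pairs(model$subunits[[i]],
                 case$reference$chains[[case$matching[[i]]$ref]],
                 case$matching[[i]]$aln))
  all_P <- do.call(rbind, lapply(pairs, `[[`, "P"))
  all_Q <- do.call(rbind, lapply(pairs, `[[`, "Q"))
  if (nrow(all_P) < 3) stop("fewer than 3 matched residues for fitting")
  overall <- kabsch(all_P, all_Q)$rmsd
  sub_rmsd <- setNames(numeric(0), character(0))
  for (sid in case$predicted_subunits) {
    i <- match(sid, ids)
    others_P <- do.call(rbind, lapply(pairs[-i], `[[`, "P"))
    others_Q <- do.call(rbind, lapply(pairs[-i], `[[`, "Q"))
    if (is.null(others_P) || nrow(others_P) < 3) {
      stop("fewer than 3 matched residues in the fitting set")
    }
    fit <- kabsch(others_P, others_Q)
    moved <- sweep(pairs[[i]]$P %*% t(fit$transform$rotation), 2,
                   -fit$transform$translation)
    sub_rmsd[sid] <- sqrt(mean(rowSums((moved - pairs[[i]]$Q)^2)))
  }
  structure(list(overall_rmsd = overall, subunit_rmsds = sub_rmsd,
                 capri = capri_class(sub_rmsd)),
            class = "blind_test_result")
}

#' Write a blind-test evaluation report
#'
#' One row per evaluated predicted subunit (model, reference, overall and
#' subunit rmsd, CAPRI class), plus an optional rmsd histogram table for
#' plotting.
#'
#' @param results Named list of `blind_test_result` (names are model
#'   labels).
#' @param path Report TSV path.
#' @param bins_path Optional histogram TSV path.
#' @param breaks Histogram bin edges in Angstrom.
#' @return Invisibly, the report `data.frame`.
#' @export
write_blind_report <- function(results, path, bins_path = NULL,
                               breaks = c(0, 1, 2, 3, 4, 5, 7.5, 10, Inf)) {
  rows <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(model = id, subunit = names(r$subunit_rmsds),
               overall_rmsd = round(r$overall_rmsd, 4),
               subunit_rmsd = round(unname(r$subunit_rmsds), 4),
               capri = unname(r$capri), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bins_path)) {
    counts <- as.integer(table(cut(rows$subunit_rmsd, breaks,
                                   include.lowest = TRUE)))
    utils::write.table(
      data.frame(bin_low = utils::head(breaks, -1),
                 bin_high = breaks[-1], count = counts),
      bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(rows)
}

#' @export
print.blind_test_result <- function(x, ...) {
  cat(sprintf("<blind_test_result> overall %.3f A; predicted subunits: %s\n",
              x$overall_rmsd,
              paste(sprintf("%s=%.3f(%s)", names(x$subunit_rmsds),
                            x$subunit_rmsds, x$capri), collapse = ", ")))
  invisible(x)
}
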