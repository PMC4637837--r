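# run a block with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# close C-alpha pair counts between a candidate chain and each existing
# placed subunit
.clash_counts <- function(existing, candidate, dist = 3.0) {
  cc <- ca_coords(candidate)
  vapply(existing, function(s) {
    ce <- ca_coords(s$chain)
    if (nrow(cc) == 0 || nrow(ce) == 0) return(0L)
    d2 <- outer(rowSums(cc^2), rowSums(ce^2), "+") - 2 * cc %*% t(ce)
    sum(d2 < dist^2)
  }, integer(1))
}

#' Steric clash test for a candidate subunit
#'
#' A candidate placement is rejected when its C-alpha atoms come closer
#' than `dist` Angstrom to C-alpha atoms of the existing subunits (all of
#' them, including the anchor) in at least `max_pairs` residue pairs.  The
#' pair-count tolerance lets loop-level brushes through while rejecting
#' core overlap.
#'
#' @param existing List of placed subunits (each with a `$chain`).
#' @param candidate A [chain_structure()] already transformed into the
#'   model frame.
#' @param max_pairs Clash pair-count threshold (default 10).
#' @param dist Distance threshold in Angstrom (default 3.0).
#' @return Logical: `TRUE` when the candidate clashes.
#' @export
clash <- function(existing, candidate, max_pairs = 10, dist = 3.0) {
  sum(.clash_counts(existing, candidate, dist)) >= max_pairs
}

#' Select the next anchoring subunit
#'
#' The placed subunit whose protein has the largest interaction degree in
#' the sub-network, among those not yet exhausted; ties are broken by
#' earliest placement order, then accession.
#'
#' @param model A `complex_model` under construction.
#' @param net The `sub_network` being modeled.
#' @param exhausted Character vector of subunit IDs already exhausted.
#' @return A subunit ID, or `NULL` when every placed subunit is exhausted.
#' @export
select_anchor <- function(model, net, exhausted = character()) {
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  avail <- which(!ids %in% exhausted)
  if (length(avail) == 0) return(NULL)
  prot <- vapply(model$subunits, function(s) s$protein, character(1))
  deg <- unname(net$degree[prot[avail]])
  ord <- order(-deg, avail, prot[avail])
  ids[avail[ord[1]]]
}

# side chains of an element for a given protein accession: returns
# list(shared=, partner=, partner_protein=, mapping_shared=, mapping_partner=)
.element_sides <- function(el, protein) {
  if (el$interaction$acc_a == protein) {
    list(shared = el$chain_a, partner = el$chain_b,
         partner_protein = el$interaction$acc_b,
         mapping_shared = el$mapping_a, mapping_partner = el$mapping_b)
  } else {
    list(shared = el$chain_b, partner = el$chain_a,
         partner_protein = el$interaction$acc_a,
         mapping_shared = el$mapping_b, mapping_partner = el$mapping_a)
  }
}

# target-position -> template seq_index map from an align_pair mapping
.target_map <- function(mapping, chain) {
  if (is.null(mapping) || nrow(mapping$aligned_pairs) == 0) {
    return(setNames(integer(), character()))
  }
  setNames(chain$residues$seq_index[mapping$aligned_pairs[, "subject"]],
           as.character(mapping$aligned_pairs[, "query"]))
}

.placed_subunit <- function(id, protein, chain, mapping, anchor, element_idx,
                            template_pair, transform, scores = NULL) {
  list(subunit_id = id, protein = protein, chain = chain,
       target_map = .target_map(mapping, chain),
       anchor = anchor, introduced_by = element_idx,
       template_pair = template_pair, transform = transform, scores = scores)
}

#' Grow one complex model from a starting protein
#'
#' Implements the iterative template-assembly loop.  The model is seeded
#' with the structure element of the start node's highest-degree edge.
#' Then, repeatedly, an anchoring subunit is chosen (largest sub-network
#' degree by default, or at random with `mode = "random"`) and every unused
#' element incident to the anchor's protein is tried: the element's shared
#' chain is structurally aligned onto the anchor; placements failing the
#' identity/TM-score acceptance gate are skipped and logged; placements
#' sterically hindering existing subunits are discarded and recorded as
#' alternative interfaces; surviving partners are placed.  Iteration stops
#' when no element can introduce a further subunit.
#'
#' Target sequences are mapped onto template chains by alignment; no
#' comparative remodeling of the subunits is performed.
#'
#' @param start Accession of the starting protein (must be in `net`).
#' @param net A `sub_network` from [cluster_subnetworks()].
#' @param elements Optional element list; defaults to the elements carried
#'   on the sub-network's edges.
#' @param mode `"degree"` (default) or `"random"` anchor selection.
#' @param seed Integer seed for `mode = "random"`.
#' @param clash_max_pairs,clash_dist Clash predicate parameters, see
#'   [clash()].
#' @return Object of class `complex_model`: `subunits` (ordered list of
#'   placed subunits), `alternative_records` (list of
#'   `(owner, partner_a, partner_b)` protein triples), `joined_pairs`
#'   (pair keys realized by templates during assembly), `rejections`
#'   (log of gate failures with scores), `start_subunit`, `mode`.
#' @export
grow_model <- function(start, net, elements = NULL,
                       mode = c("degree", "random"), seed = 1L,
                       clash_max_pairs = 10, clash_dist = 3.0) {
  mode <- match.arg(mode)
  if (!start %in% net$nodes) stop("start node ", start, " not in sub-network")
  if (is.null(elements)) elements <- lapply(net$edges, function(e) e$element)
  n_el <- length(elements)
  state <- rep("unused", n_el)
  el_a <- vapply(elements, function(e) e$interaction$acc_a, character(1))
  el_b <- vapply(elements, function(e) e$interaction$acc_b, character(1))

  # seed edge: incident to start, partner of largest degree
  inc <- which(el_a == start | el_b == start)
  if (length(inc) == 0) stop("start node has no incident elements")
  partner <- ifelse(el_a[inc] == start, el_b[inc], el_a[inc])
  pd <- unname(net$degree[partner])
  seed_edge <- inc[order(-pd, partner, inc)][1]
  el <- elements[[seed_edge]]
  sides <- .element_sides(el, start)
  ident <- rigid_transform()
  subunits <- list(
    .placed_subunit("S1", start, sides$shared, sides$mapping_shared,
                    "S1", seed_edge,
                    c(el$template_entry, sides$shared$chain_id), ident),
    .placed_subunit("S2", sides$partner_protein, sides$partner,
                    sides$mapping_partner, "S2", seed_edge,
                    c(el$template_entry, sides$partner$chain_id), ident))
  state[seed_edge] <- "used"
  joined <- pair_key(c(start, sides$partner_protein))
  alternative_records <- list()
  rejections <- list()
  exhausted <- character()

  model <- structure(list(subunits = subunits,
                          alternative_records = alternative_records,
                          joined_pairs = joined, rejections = rejections,
                          start_subunit = start, mode = mode,
                          subnetwork_nodes = net$nodes),
                     class = "complex_model")

  repeat {
    anchor_id <- if (mode == "degree") {
      select_anchor(model, net, exhausted)
    } else {
      ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
      avail <- ids[!ids %in% exhausted]
      if (length(avail) == 0) NULL
      else .with_seed(seed + 7L * length(exhausted),
                      avail[sample.int(length(avail), 1)])
    }
    if (is.null(anchor_id)) break
    anchor <- model$subunits[[match(
      anchor_id, vapply(model$subunits, function(s) s$subunit_id,
                        character(1)))]]
    placed_prot <- vapply(model$subunits, function(s) s$protein, character(1))
    cand_edges <- which(state == "unused" &
                          (el_a == anchor$protein | el_b == anchor$protein))
    if (length(cand_edges) > 0) {
      cp <- ifelse(el_a[cand_edges] == anchor$protein, el_b[cand_edges],
                   el_a[cand_edges])
      cand_edges <- cand_edges[order(cp, cand_edges)]
    }
    for (ei in cand_edges) {
      el <- elements[[ei]]
      sides <- .element_sides(el, anchor$protein)
      if (sides$partner_protein %in% placed_prot) {
        state[ei] <- "consumed"   # both endpoints present; nothing to place
        next
      }
      sup <- tryCatch(structure_align(sides$shared, anchor$chain),
                      error = function(e) NULL)
      if (is.null(sup) ||
          !accept_superposition(sup$identity_struct, sup$tmscore)) {
        state[ei] <- "rejected"
        model$rejections[[length(model$rejections) + 1L]] <- list(
          anchor = anchor_id, element = ei,
          partner = sides$partner_protein,
          identity_struct = if (is.null(sup)) NA_real_ else sup$identity_struct,
          tmscore = if (is.null(sup)) NA_real_ else sup$tmscore)
        next
      }
      cand_chain <- apply_transform(sides$partner, sup$transform)
      counts <- .clash_counts(model$subunits, cand_chain, clash_dist)
      if (sum(counts) >= clash_max_pairs) {
        state[ei] <- "clashed"
        blocker <- model$subunits[[which.max(counts)]]$protein
        model$alternative_records[[
          length(model$alternative_records) + 1L]] <- list(
            owner = anchor$protein, partner_a = blocker,
            partner_b = sides$partner_protein, element = ei)
        next
      }
      sid <- paste0("S", length(model$subunits) + 1L)
      model$subunits[[length(model$subunits) + 1L]] <- .placed_subunit(
        sid, sides$partner_protein, cand_chain, sides$mapping_partner,
        anchor_id, ei, c(el$template_entry, sides$partner$chain_id),
        sup$transform,
        scores = list(identity_struct = sup$identity_struct,
                      tmscore = sup$tmscore, rmsd = sup$rmsd))
      state[ei] <- "used"
      model$joined_pairs <- c(model$joined_pairs,
                              pair_key(c(anchor$protein,
                                         sides$partner_protein)))
      placed_prot <- c(placed_prot, sides$partner_protein)
    }
    exhausted <- c(exhausted, anchor_id)
  }
  model$element_state <- state
  model
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> %d subunits [%s], %d alternative record(s), start=%s\n",
              length(x$subunits),
              paste(vapply(x$subunits, function(s) s$protein, character(1)),
                    collapse = ", "),
              length(x$alternative_records), x$start_subunit))
  invisible(x)
}

# dedup key: protein multiset + geometric contact set (subunit pairs with
# at least 3 CA pairs within 8 A — a cheap stand-in for the interface set
# that is independent of which redundant template edge went unused)
.model_key <- function(model) {
  prot <- vapply(model$subunits, function(s) s$protein, character(1))
  cas <- lapply(model$subunits, function(s) ca_coords(s$chain))
  contacts <- character()
  ns <- length(prot)
  if (ns >= 2) {
    for (i in seq_len(ns - 1)) {
      for (j in seq.int(i + 1, ns)) {
        d2 <- outer(rowSums(cas[[i]]^2), rowSums(cas[[j]]^2), "+") -
          2 * cas[[i]] %*% t(cas[[j]])
        if (sum(d2 < 64) >= 3) {
          contacts <- c(contacts, pair_key(c(prot[i], prot[j])))
        }
      }
    }
  }
  paste(paste(sort(prot), collapse = ","),
        paste(sort(unique(contacts)), collapse = ","), sep = ";")
}

#' Build models from every starting point of a sub-network
#'
#' Runs [grow_model()] from every node, deduplicates models whose protein
#' multisets and assembly interface sets coincide, and returns the
#' survivors sorted by size (descending; ties by start accession).
#'
#' @inheritParams grow_model
#' @return List of `complex_model`.
#' @export
build_all_models <- function(net, elements = NULL,
                             mode = c("degree", "random"), seed = 1L,
                             clash_max_pairs = 10, clash_dist = 3.0) {
  mode <- match.arg(mode)
  models <- lapply(net$nodes, function(v)
    grow_model(v, net, elements, mode = mode, seed = seed,
               clash_max_pairs = clash_max_pairs, clash_dist = clash_dist))
  keys <- vapply(models, .model_key, character(1))
  models <- models[!duplicated(keys)]
  sizes <- vapply(models, function(m) length(m$subunits), integer(1))
  starts <- vapply(models, function(m) m$start_subunit, character(1))
  models[order(-sizes, starts)]
}
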