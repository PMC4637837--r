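# van der Waals radii (Angstrom) used by the accessible-surface
# calculation; unlisted elements fall back to 1.8.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, H = 1.20)

.vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.8
  unname(r)
}

# deterministic quasi-uniform unit sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# heavy-atom table of a chain (coordinates + inflated radii inputs)
.heavy_atoms <- function(chain) {
  a <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  data.frame(seq_index = a$seq_index, element = a$element,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# per-atom accessible areas for atoms `subset` (indices into xyz), with
# every atom in xyz acting as an occluder
.atom_areas <- function(xyz, rad, subset = seq_len(nrow(xyz)),
                        n_points = 960) {
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  out <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[k] <- 4 * pi * rad[i]^2
      next
    }
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    occluded <- rep(FALSE, n_points)
    # nearest neighbours occlude most points; test them first
    for (j in nb[order(d2[nb])]) {
      rem <- which(!occluded)
      if (length(rem) == 0) break
      dj2 <- rowSums(sweep(sp[rem, , drop = FALSE], 2, xyz[j, ])^2)
      occluded[rem[dj2 < rad[j]^2]] <- TRUE
    }
    out[k] <- 4 * pi * rad[i]^2 * sum(!occluded) / n_points
  }
  out
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley SASA: each heavy atom is inflated by the probe radius and
#' sampled with a deterministic quasi-uniform point lattice; points inside
#' any neighbouring inflated atom are occluded.  Areas are summed per
#' residue.
#'
#' @param chains A [chain_structure()] or list of them (computed in each
#'   other's presence).
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @return `data.frame` with columns `chain` (index into the input list),
#'   `chain_id`, `seq_index`, `area` (Angstrom^2).  Residues without atoms
#'   get area 0 with a warning.
#' @export
sasa <- function(chains, probe = 1.4, n_points = 960) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  at <- do.call(rbind, lapply(seq_along(chains), function(i) {
    a <- .heavy_atoms(chains[[i]])
    if (nrow(a) == 0) return(NULL)
    cbind(chain = i, a)
  }))
  res <- do.call(rbind, lapply(seq_along(chains), function(i)
    data.frame(chain = i, chain_id = chains[[i]]$chain_id,
               seq_index = chains[[i]]$residues$seq_index,
               stringsAsFactors = FALSE)))
  res$area <- 0
  if (is.null(at) || nrow(at) == 0) {
    warning("no heavy atoms; all areas are 0")
    return(res)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_radius(at$element) + probe
  area_atom <- .atom_areas(xyz, rad, n_points = n_points)
  sums <- tapply(area_atom, paste(at$chain, at$seq_index, sep = "|"), sum)
  key <- paste(res$chain, res$seq_index, sep = "|")
  hit <- key %in% names(sums)
  res$area[hit] <- as.numeric(sums[key[hit]])
  if (any(!hit)) {
    warning(sum(!hit), " residue(s) without heavy atoms given area 0")
  }
  res
}

# buried area between two chains, reusing cached isolated per-atom areas
# and recomputing only atoms close enough to the partner to be occluded
.buried_pair <- function(ch_a, ch_b, atoms_a, atoms_b, area_a, area_b,
                         probe = 1.4, n_points = 960) {
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  ra <- .vdw_radius(atoms_a$element) + probe
  rb <- .vdw_radius(atoms_b$element) + probe
  cut <- 2 * (max(c(ra, rb)))
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  near_a <- which(apply(d2, 1, min) < cut^2)
  near_b <- which(apply(d2, 2, min) < cut^2)
  zero <- list(area_a = 0, area_b = 0,
               residues_a = integer(), residues_b = integer(),
               loss_a = setNames(numeric(), character()),
               loss_b = setNames(numeric(), character()))
  if (length(near_a) == 0 && length(near_b) == 0) return(zero)
  xyz <- rbind(xa, xb)
  rad <- c(ra, rb)
  new_a <- area_a; new_b <- area_b
  if (length(near_a) > 0) {
    new_a[near_a] <- .atom_areas(xyz, rad, near_a, n_points)
  }
  if (length(near_b) > 0) {
    new_b[near_b] <- .atom_areas(xyz, rad, nrow(xa) + near_b, n_points)
  }
  la <- tapply(area_a - new_a, atoms_a$seq_index, sum)
  lb <- tapply(area_b - new_b, atoms_b$seq_index, sum)
  list(area_a = sum(area_a - new_a), area_b = sum(area_b - new_b),
       residues_a = as.integer(names(la)[la > 0.1]),
       residues_b = as.integer(names(lb)[lb > 0.1]),
       loss_a = la[la > 0.1], loss_b = lb[lb > 0.1])
}

#' Buried surface area between two subunits of a model
#'
#' Per-subunit buried area is the solvent-accessible area of the isolated
#' subunit minus its area in the presence of the partner subunit only.
#' Interface residues are those losing more than 0.1 Angstrom^2.
#'
#' @param model A `complex_model`.
#' @param a,b Subunit IDs or indices.
#' @param probe,n_points Passed to [sasa()].
#' @return List with `area_a`, `area_b` (Angstrom^2), `residues_a`,
#'   `residues_b` (seq_index vectors), and `loss_a`, `loss_b` (named
#'   per-residue area losses).
#' @export
buried_area <- function(model, a, b, probe = 1.4, n_points = 960) {
  ia <- .subunit_index(model, a); ib <- .subunit_index(model, b)
  ch_a <- model$subunits[[ia]]$chain; ch_b <- model$subunits[[ib]]$chain
  atoms_a <- .heavy_atoms(ch_a); atoms_b <- .heavy_atoms(ch_b)
  area_a <- .atom_areas(as.matrix(atoms_a[, c("x", "y", "z")]),
                        .vdw_radius(atoms_a$element) + probe,
                        n_points = n_points)
  area_b <- .atom_areas(as.matrix(atoms_b[, c("x", "y", "z")]),
                        .vdw_radius(atoms_b$element) + probe,
                        n_points = n_points)
  .buried_pair(ch_a, ch_b, atoms_a, atoms_b, area_a, area_b, probe,
               n_points)
}

.subunit_index <- function(model, x) {
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  if (is.character(x)) {
    i <- match(x, ids)
    if (is.na(i)) stop("no subunit ", x, " in model")
    i
  } else as.integer(x)
}

#' Detect interfaces in an assembled model
#'
#' Every subunit pair burying more than `area_threshold` Angstrom^2 (on the
#' larger of the two per-subunit buried areas) is reported as an interface.
#' On each subunit, interfaces to different partners that share at least
#' `overlap_frac` of their buried residue area (relative to the smaller of
#' the two interfaces) are treated as one alternative-capable site; the
#' partners involved are cross-listed in `alternative_partners`.
#'
#' @param model A `complex_model`.
#' @param area_threshold Interface area threshold, Angstrom^2 (default 250).
#' @param overlap_frac Area-sharing fraction distinguishing overlapping
#'   from independent sites (default 0.1).
#' @param probe,n_points Passed to [sasa()].
#' @return List of `ppi_interface` objects with fields `subunit_a`,
#'   `subunit_b`, `protein_a`, `protein_b`, `residues_a`, `residues_b`,
#'   `area_a`, `area_b`, `type` (`NA` until [type_interfaces()]), `direct`,
#'   `alternative_partners`.
#' @export
detect_interfaces <- function(model, area_threshold = 250,
                              overlap_frac = 0.1, probe = 1.4,
                              n_points = 960) {
  ns <- length(model$subunits)
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  prots <- vapply(model$subunits, function(s) s$protein, character(1))
  atoms <- lapply(model$subunits, function(s) .heavy_atoms(s$chain))
  isolated <- lapply(atoms, function(a)
    .atom_areas(as.matrix(a[, c("x", "y", "z")]),
                .vdw_radius(a$element) + probe, n_points = n_points))
  ifaces <- list()
  if (ns >= 2) {
    for (i in seq_len(ns - 1)) {
      for (j in seq.int(i + 1, ns)) {
        ba <- .buried_pair(model$subunits[[i]]$chain,
                           model$subunits[[j]]$chain,
                           atoms[[i]], atoms[[j]],
                           isolated[[i]], isolated[[j]], probe, n_points)
        if (max(ba$area_a, ba$area_b) > area_threshold) {
          ifaces[[length(ifaces) + 1L]] <- structure(
            list(subunit_a = ids[i], subunit_b = ids[j],
                 protein_a = prots[i], protein_b = prots[j],
                 residues_a = ba$residues_a, residues_b = ba$residues_b,
                 area_a = ba$area_a, area_b = ba$area_b,
                 loss_a = ba$loss_a, loss_b = ba$loss_b,
                 type = NA_character_, direct = NA,
                 alternative_partners = character()),
            class = "ppi_interface")
        }
      }
    }
  }
  # overlap analysis per subunit: shared buried-residue area between the
  # sites used for different partners
  for (sid in ids) {
    on_s <- which(vapply(ifaces, function(f)
      sid %in% c(f$subunit_a, f$subunit_b), logical(1)))
    if (length(on_s) < 2) next
    side <- lapply(ifaces[on_s], function(f)
      if (f$subunit_a == sid) list(loss = f$loss_a, partner = f$subunit_b,
                                   area = f$area_a)
      else list(loss = f$loss_b, partner = f$subunit_a, area = f$area_b))
    for (u in seq_along(on_s)) {
      for (v in seq_along(on_s)) {
        if (u == v) next
        common <- intersect(names(side[[u]]$loss), names(side[[v]]$loss))
        shared <- sum(pmin(side[[u]]$loss[common], side[[v]]$loss[common]))
        denom <- min(side[[u]]$area, side[[v]]$area)
        if (denom > 0 && shared / denom >= overlap_frac) {
          f <- ifaces[[on_s[u]]]
          f$alternative_partners <- sort(unique(c(f$alternative_partners,
                                                  side[[v]]$partner)))
          ifaces[[on_s[u]]] <- f
        }
      }
    }
  }
  ifaces
}

#' @export
print.ppi_interface <- function(x, ...) {
  cat(sprintf("<interface> %s(%s)-%s(%s) areas %.0f/%.0f A^2 type=%s%s\n",
              x$subunit_a, x$protein_a, x$subunit_b, x$protein_b,
              x$area_a, x$area_b, x$type,
              if (length(x$alternative_partners))
                paste0(" alt:", paste(x$alternative_partners, collapse = ","))
              else ""))
  invisible(x)
}

#' Annotate interface types
#'
#' An interface is *experimentally determined* when the subunit pair was
#' joined by a structure element during assembly; *model-predicted* when it
#' was not template-joined but the protein pair is recorded in the
#' interaction table (structure unknown, interaction known); and
#' *model-suggested* otherwise (neither recorded nor templated).
#'
#' @param model The `complex_model` the interfaces came from.
#' @param interfaces Result of [detect_interfaces()].
#' @param interactions List of [interaction_record()] (the full table).
#' @return The interfaces with `type` filled in.
#' @export
type_interfaces <- function(model, interfaces, interactions) {
  known <- unique(vapply(interactions, pair_key, character(1)))
  joined <- unique(model$joined_pairs)
  lapply(interfaces, function(f) {
    pk <- pair_key(c(f$protein_a, f$protein_b))
    f$type <- if (pk %in% joined) "experimental"
              else if (pk %in% known) "model_predicted"
              else "model_suggested"
    f
  })
}

#' Direct/indirect annotation of recorded interactions
#'
#' A recorded interaction between two placed subunits is *direct* when the
#' subunits share a detected interface, *indirect* otherwise (the proteins
#' co-occur in the complex without touching).  The detection method is
#' carried through so per-method indirect rates can be tabulated.
#'
#' @param model A `complex_model`.
#' @param interfaces Result of [detect_interfaces()].
#' @param interactions List of [interaction_record()].
#' @return `data.frame` with columns `acc_a`, `acc_b`, `detection_method`,
#'   `direct` (logical); one row per record whose both proteins are placed.
#' @export
flag_indirect <- function(model, interfaces, interactions) {
  placed <- vapply(model$subunits, function(s) s$protein, character(1))
  contact <- unique(vapply(interfaces, function(f)
    pair_key(c(f$protein_a, f$protein_b)), character(1)))
  rows <- lapply(interactions, function(rec) {
    if (!(rec$acc_a %in% placed && rec$acc_b %in% placed)) return(NULL)
    data.frame(acc_a = rec$acc_a, acc_b = rec$acc_b,
               detection_method = rec$detection_method,
               direct = pair_key(rec) %in% contact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(acc_a = character(), acc_b = character(),
                      detection_method = character(), direct = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Indirect-interaction rate per detection method
#'
#' @param flags Result of [flag_indirect()] (rows may be pooled over
#'   models).
#' @return `data.frame` with `detection_method`, `n`, `n_indirect`,
#'   `indirect_rate`.
#' @export
indirect_rate_by_method <- function(flags) {
  if (nrow(flags) == 0) {
    return(data.frame(detection_method = character(), n = integer(),
                      n_indirect = integer(), indirect_rate = numeric()))
  }
  agg <- split(flags, flags$detection_method)
  out <- do.call(rbind, lapply(names(agg), function(m)
    data.frame(detection_method = m, n = nrow(agg[[m]]),
               n_indirect = sum(!agg[[m]]$direct),
               indirect_rate = mean(!agg[[m]]$direct),
               stringsAsFactors = FALSE)))
  out[order(out$detection_method), , drop = FALSE]
}

#' Collapse redundant homologous interfaces
#'
#' Interfaces whose protein pairs are mutually homologous (identity above
#' `min_identity` on both sides, in either pairing orientation) are grouped
#' by single linkage and one representative (the first in input order) is
#' kept per group.
#'
#' @param interfaces List of `ppi_interface` (possibly pooled over models).
#' @param proteins Named list of [protein_entry()].
#' @param min_identity Exclusive homology threshold (default 0.25).
#' @return List with `representatives` (interface list) and `groups`
#'   (list of integer index vectors into the input).
#' @export
collapse_homologous <- function(interfaces, proteins, min_identity = 0.25) {
  n <- length(interfaces)
  if (n == 0) return(list(representatives = list(), groups = list()))
  idcache <- new.env(parent = emptyenv())
  hom <- function(p, q) {
    if (p == q) return(TRUE)
    key <- paste(sort(c(p, q)), collapse = "|")
    if (!is.null(idcache[[key]])) return(idcache[[key]])
    v <- align_pair(proteins[[p]], proteins[[q]])$identity_fraction >
      min_identity
    idcache[[key]] <- v
    v
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      fi <- interfaces[[i]]; fj <- interfaces[[j]]
      same <- (hom(fi$protein_a, fj$protein_a) &&
                 hom(fi$protein_b, fj$protein_b)) ||
              (hom(fi$protein_a, fj$protein_b) &&
                 hom(fi$protein_b, fj$protein_a))
      if (same) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  list(representatives = interfaces[vapply(groups, min, integer(1))],
       groups = unname(groups))
}

#' Classify alternative-interface partners
#'
#' For each alternative-interface record (two partners competing for one
#' site on an owner subunit), the partners are classified as `homologous`
#' (sequence identity above 0.25), `same_fold` (not homologous but
#' structurally alignable with TM-score above 0.5), or `different_fold`.
#'
#' @param model The `complex_model` carrying the records.
#' @param elements The element list used during assembly (source of the
#'   discarded partner's template chain).
#' @param proteins Named list of [protein_entry()].
#' @return `data.frame` with `owner`, `partner_a`, `partner_b`, `class`.
#' @export
alternative_partner_classes <- function(model, elements, proteins) {
  rows <- lapply(model$alternative_records, function(rec) {
    cls <- "different_fold"
    idf <- align_pair(proteins[[rec$partner_a]],
                      proteins[[rec$partner_b]])$identity_fraction
    if (idf > 0.25) {
      cls <- "homologous"
    } else {
      ch_a <- .find_subunit_chain(model, rec$partner_a)
      el <- elements[[rec$element]]
      sides <- .element_sides(el, rec$owner)
      ch_b <- sides$partner
      tm <- tryCatch(structure_align(ch_b, ch_a)$tmscore,
                     error = function(e) NA_real_)
      if (is.na(tm)) {
        # sequence-dissimilar partners: fall back to rank-order residue
        # correspondence (fold comparison must not depend on sequence)
        ia <- ch_a$residues$seq_index[ch_a$residues$has_coords]
        ib <- ch_b$residues$seq_index[ch_b$residues$has_coords]
        n <- min(length(ia), length(ib))
        if (n >= 3) {
          tm <- tryCatch(
            tm_score(ch_b, ch_a, cbind(ib[seq_len(n)], ia[seq_len(n)]),
                     norm_length = length(ia)),
            error = function(e) NA_real_)
        }
      }
      if (!is.na(tm) && tm > 0.5) cls <- "same_fold"
    }
    data.frame(owner = rec$owner, partner_a = rec$partner_a,
               partner_b = rec$partner_b, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(owner = character(), partner_a = character(),
                      partner_b = character(), class = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

.find_subunit_chain <- function(model, protein) {
  for (s in model$subunits) if (s$protein == protein) return(s$chain)
  stop("protein ", protein, " not placed in model")
}

#' Write an interface table TSV
#'
#' @param interfaces List of typed `ppi_interface` objects.
#' @param flags Optional result of [flag_indirect()] used to fill the
#'   direct column.
#' @param path Output TSV path.
#' @param model_id Label written in the first column.
#' @return Invisibly, the written `data.frame`.
#' @export
write_interface_table <- function(interfaces, path, flags = NULL,
                                  model_id = "model") {
  rows <- lapply(interfaces, function(f) {
    direct <- NA
    if (!is.null(flags) && nrow(flags) > 0) {
      m <- which(vapply(seq_len(nrow(flags)), function(i)
        pair_key(c(flags$acc_a[i], flags$acc_b[i])) ==
          pair_key(c(f$protein_a, f$protein_b)), logical(1)))
      if (length(m) > 0) direct <- flags$direct[m[1]]
    }
    data.frame(model = model_id, subunit_a = f$subunit_a,
               subunit_b = f$subunit_b, protein_a = f$protein_a,
               protein_b = f$protein_b,
               area_a = round(f$area_a, 2), area_b = round(f$area_b, 2),
               residues_a = paste(f$residues_a, collapse = ","),
               residues_b = paste(f$residues_b, collapse = ","),
               type = f$type, direct = direct,
               alternative_partners = paste(f$alternative_partners,
                                            collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
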