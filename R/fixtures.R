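# ---- synthetic fixture generator ------------------------------------------
#
# Toy "crystal" structures with known ground truth: every chain is an
# idealized four-helix bundle (up-down-up-down around a square), which
# gives each subunit a buried core (for interior residues), four flat
# faces (for planted contact patches) and coordinate-less loops/tails
# (for disordered residues).  Complexes are laid out on a lattice; each
# ground-truth contact pair is emitted as a separate two-chain entry in
# its own random rigid frame, so assembly has to re-derive the whole
# complex by superposition.

.FIX <- list(
  helix_len = 12,     # residues per helix
  loop_len = 3,       # coordinate-less residues between helices
  tail_len = 4,       # coordinate-less C-terminal tail
  rise = 1.5,         # Angstrom per residue along the helix axis
  twist = 100,        # degrees per residue
  sq_side = 8.5,      # helix-axis separation inside a bundle (square side)
  contact = 8.5,      # helix-axis separation across a planted contact
  center_dist = 16.0  # bundle center distance for edge-to-edge contact
                      # (buries ~400 A^2 per side without steric clash)
)

# atom placement relative to the CA helical track (radius, dphi deg, dz)
.HELIX_ATOMS <- data.frame(
  name = c("N", "CA", "C", "O", "CB"),
  element = c("N", "C", "C", "O", "C"),
  r = c(1.60, 2.28, 1.65, 2.00, 3.30),
  dphi = c(-26, 0, 21, 40, -15),
  dz = c(-0.75, 0, 0.75, 1.25, -0.60),
  stringsAsFactors = FALSE)

# amino-acid alphabet used for random sequences (proline excluded: its
# conservative-substitution partner would score negative) and the
# conservative partner map (all BLOSUM62 scores >= 0) used to mutate
# sequences to planted identities.
.FIX_ALPHABET <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]
.CONS_PARTNER <- c(A = "S", C = "A", D = "E", E = "D", F = "Y", G = "A",
                   H = "Y", I = "V", K = "R", L = "M", M = "L", N = "D",
                   Q = "E", R = "K", S = "T", T = "S", V = "I", W = "Y",
                   Y = "F", X = "A")

#' Fixture specification
#'
#' @param seed Integer; fully determines all generator output.
#' @param n_proteins Number of subunits in the planted complex (2-8;
#'   `star` supports up to 5 = hub + 4 leaves; `ring` needs at least 3;
#'   `two_blocks` at least 4).
#' @param topology Complex layout: `star`, `path`, `ring`, `complete`
#'   (path geometry with a complete interaction table) or `two_blocks`
#'   (two branches competing for the same site on a shared hub).
#' @param chain_length Approximate residues per chain (default 61; four
#'   helices are sized to fit).
#' @param clash_pairs Number of extra proteins planted onto an
#'   already-occupied site (each yields one alternative-interface record).
#' @param identity_ladder Numeric vector of planted homologue identities;
#'   each adds a single-chain decoy entry homologous to the first protein.
#' @param variant_plan Named integer vector with planted variant counts per
#'   environment, e.g. `c(interface = 2, surface = 1, interior = 2,
#'   disordered = 1)`.
#' @param n_indirect Extra non-contact pairs added to the interaction
#'   table (detection method "coimmunoprecipitation").
#' @param drop_edge Drop one redundant contact (the cycle-closing edge)
#'   from both the interaction table and the structure entries (only
#'   honored for `ring` and `complete`, where the network stays
#'   connected), creating a model-suggested interface.
#' @param drop_entry Like `drop_edge` but keeps the interaction record and
#'   drops only the crystal entry, creating a model-predicted interface.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_proteins = 4,
                         topology = c("star", "path", "ring", "complete",
                                      "two_blocks"),
                         chain_length = 61, clash_pairs = 0,
                         identity_ladder = NULL, variant_plan = NULL,
                         n_indirect = 0, drop_edge = FALSE,
                         drop_entry = FALSE) {
  topology <- match.arg(topology)
  if (topology == "star" && (n_proteins < 3 || n_proteins > 5)) {
    stop("star topology supports 3-5 proteins (hub + up to 4 leaves)")
  }
  if (topology %in% c("ring") && n_proteins < 3) {
    stop("ring needs at least 3 proteins")
  }
  if (topology == "two_blocks" && n_proteins < 4) {
    stop("two_blocks needs at least 4 proteins")
  }
  if (n_proteins < 2 || n_proteins > 8) stop("n_proteins must be in 2..8")
  hl <- max(8L, as.integer(floor((chain_length - 3 * 3 - 4) / 4)))
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 topology = topology, chain_length = chain_length,
                 helix_len = hl, clash_pairs = as.integer(clash_pairs),
                 identity_ladder = identity_ladder,
                 variant_plan = variant_plan,
                 n_indirect = as.integer(n_indirect),
                 drop_edge = isTRUE(drop_edge),
                 drop_entry = isTRUE(drop_entry)),
            class = "fixture_spec")
}

#' Mutate a sequence to a planted identity
#'
#' Substitutes evenly spaced interior positions with conservative partners
#' (BLOSUM62 score >= 0), so a local alignment retains full coverage and
#' its identity equals the planted fraction.
#'
#' @param sequence Amino-acid string.
#' @param identity Target identity fraction in (0, 1].
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, identity) {
  s <- strsplit(sequence, "")[[1]]
  L <- length(s)
  k <- round((1 - identity) * L)
  if (k == 0) return(sequence)
  pos <- unique(round(seq(2, L - 1, length.out = k)))
  s[pos] <- .CONS_PARTNER[s[pos]]
  paste0(s, collapse = "")
}

# random uniform rotation matrix (quaternion method)
.rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# residue layout of a bundle chain: helix membership and phases
.bundle_layout <- function(hl = .FIX$helix_len) {
  loop <- .FIX$loop_len
  starts <- cumsum(c(1, rep(hl + loop, 3)))
  list(hl = hl, starts = starts,
       tail_start = starts[4] + hl,
       n_res = starts[4] + hl - 1 + .FIX$tail_len,
       vertex = c(45, 135, 225, 315),
       dir = c(1, -1, 1, -1))
}

# build one four-helix-bundle chain at the origin; seq is the full-length
# protein sequence (loops and tail get no atoms)
.bundle_chain <- function(chain_id, sequence, hl = .FIX$helix_len,
                          source_protein = NA_character_) {
  lay <- .bundle_layout(hl)
  s <- strsplit(sequence, "")[[1]]
  stopifnot(length(s) >= lay$n_res)
  rsq <- .FIX$sq_side / sqrt(2)
  mid <- floor(hl / 2)
  atoms <- list()
  for (h in 1:4) {
    vx <- rsq * cos(lay$vertex[h] * pi / 180)
    vy <- rsq * sin(lay$vertex[h] * pi / 180)
    phase <- lay$vertex[h] + 180 - .FIX$twist * mid   # mid residue faces in
    for (r in 0:(hl - 1)) {
      resno <- lay$starts[h] + r
      ang <- (phase + .FIX$twist * r) * pi / 180
      z0 <- lay$dir[h] * (r - (hl - 1) / 2) * .FIX$rise
      a <- .HELIX_ATOMS
      atoms[[length(atoms) + 1L]] <- data.frame(
        seq_index = resno, name = a$name, element = a$element,
        x = vx + a$r * cos(ang + a$dphi * pi / 180),
        y = vy + a$r * sin(ang + a$dphi * pi / 180),
        z = z0 + lay$dir[h] * a$dz, stringsAsFactors = FALSE)
    }
  }
  residues <- data.frame(seq_index = seq_len(lay$n_res),
                         aa = s[seq_len(lay$n_res)],
                         stringsAsFactors = FALSE)
  chain_structure(chain_id, residues, do.call(rbind, atoms),
                  source_protein = source_protein)
}

# residue of a bundle whose side chain faces global direction `dir_deg`
# (choosing the helix whose vertex is nearest that direction), `rank`-th
# best by angular fit around mid-height
.facing_residue <- function(lay, theta, dir_deg, rank = 1) {
  rel <- (dir_deg - theta) %% 360
  h <- which.min(pmin(abs(lay$vertex - rel), 360 - abs(lay$vertex - rel)))
  mid <- floor(lay$hl / 2)
  phase <- lay$vertex[h] + 180 - .FIX$twist * mid
  r <- 0:(lay$hl - 1)
  ang <- (phase + .FIX$twist * r) %% 360
  off <- pmin(abs(ang - rel), 360 - abs(ang - rel))
  # prefer mid-height residues among well-facing ones
  score <- off + 10 * abs(r - mid) / lay$hl
  ord <- order(score)
  lay$starts[h] + r[ord[rank]]
}

# residue facing the bundle core (interior), on helix `h`
.core_residue <- function(lay, h = 1) {
  floor(lay$hl / 2) + lay$starts[h]
}

# node placements (center, orientation, free outward direction) per
# topology; returns data.frame plus the contact edge list (by node index)
.layout_nodes <- function(topology, n) {
  D <- .FIX$center_dist
  if (topology %in% c("path", "complete")) {
    nodes <- data.frame(cx = (seq_len(n) - 1) * D, cy = 0, theta = 0,
                        free_dir = NA_real_)
    nodes$free_dir[1] <- 180; nodes$free_dir[n] <- 0
    edges <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  } else if (topology == "star") {
    beta <- c(0, 90, 180, 270)[seq_len(n - 1)]
    nodes <- data.frame(
      cx = c(0, D * cos(beta * pi / 180)),
      cy = c(0, D * sin(beta * pi / 180)),
      theta = c(0, beta), free_dir = c(NA_real_, beta))
    edges <- cbind(1L, 1L + seq_len(n - 1))
  } else if (topology == "ring") {
    # closed cycle walked around the perimeter of a 2-row lattice, so
    # every lattice-adjacent contact is the robust edge-to-edge packing;
    # for odd n the closure pair is co-framed in its entry but does not
    # touch (a perfectly usable template nonetheless)
    ncol_ <- ceiling(n / 2)
    top <- seq_len(ncol_)                     # (0..ncol-1, 0)
    bottom <- rev(seq_len(n - ncol_))         # (ncol-1.., 1) walking back
    xs <- c((top - 1) * D, (bottom - 1) * D)
    ys <- c(rep(0, length(top)), rep(D, length(bottom)))
    nodes <- data.frame(cx = xs, cy = ys, theta = 0, free_dir = NA_real_)
    edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  } else { # two_blocks: hub + two branches sharing the hub site
    k2 <- (n - 1) %/% 2; k1 <- n - 1 - k2
    nodes <- data.frame(cx = 0, cy = 0, theta = 0, free_dir = NA_real_)
    for (i in seq_len(k1)) {
      nodes <- rbind(nodes, data.frame(cx = i * D, cy = 0, theta = 0,
                                       free_dir = if (i == k1) 0 else NA))
    }
    for (i in seq_len(k2)) {
      nodes <- rbind(nodes, data.frame(cx = i * D, cy = 0, theta = 0,
                                       free_dir = if (i == k2) 0 else NA))
    }
    e1 <- if (k1 > 0) cbind(c(1L, 1L + seq_len(k1 - 1)), 1L + seq_len(k1))
          else NULL
    e2 <- if (k2 > 0) cbind(c(1L, 1L + k1 + seq_len(k2 - 1)),
                            1L + k1 + seq_len(k2)) else NULL
    edges <- rbind(e1, e2)
  }
  list(nodes = nodes, edges = edges)
}

#' Generate a toy complex with ground truth and pipeline input files
#'
#' Builds the planted complex, splits every contact pair into its own
#' randomly-reframed two-chain "crystal" entry, and (optionally) writes
#' the four input file types the pipeline consumes: per-entry PDB files,
#' a FASTA of protein sequences, a MITAB-style interaction TSV and a
#' variant TSV.  The interaction table is a superset (optional indirect
#' edges) and subset (optional dropped edge) of the true contacts.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory; created if missing.
#' @return Object of class `toy_complex` with the ground truth: `proteins`,
#'   `true_chains` (global frame), `edges`, `entries` (per-entry chains in
#'   entry frames + transforms), `interactions`, `variants` (with planted
#'   environments), `planted_clashes`, `expected_models` (protein sets),
#'   `dropped_pairs`, and `paths` when files were written.
#' @export
make_toy_complex <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, .make_toy_complex_impl(spec, out_dir))
}

.make_toy_complex_impl <- function(spec, out_dir) {
  n <- spec$n_proteins
  hl <- spec$helix_len
  lay <- .bundle_layout(hl)
  lt <- .layout_nodes(spec$topology, n)
  nodes <- lt$nodes
  accs <- sprintf("P%02d", seq_len(n))

  # clash extras: duplicate the site of the first non-hub node, bound to
  # the hub (node 1)
  n_extra <- if (spec$topology == "two_blocks") 0L else spec$clash_pairs
  planted_clashes <- list()
  if (n_extra > 0) {
    dup_site <- 2L   # the first partner of node 1
    for (j in seq_len(n_extra)) {
      accs <- c(accs, sprintf("P%02d", n + j))
      nodes <- rbind(nodes, nodes[dup_site, ])
      lt$edges <- rbind(lt$edges, c(1L, n + j))
      planted_clashes[[j]] <- list(owner = accs[1],
                                   partner_a = accs[dup_site],
                                   partner_b = accs[n + j])
    }
  }
  if (spec$topology == "two_blocks") {
    k2 <- (n - 1) %/% 2; k1 <- n - 1 - k2
    planted_clashes[[1]] <- list(owner = accs[1], partner_a = accs[2],
                                 partner_b = accs[2 + k1])
  }
  n_all <- length(accs)

  # pairwise-dissimilar random sequences (re-drawn until no spurious
  # homology), so planted identity relations are the only ones present;
  # both the full sequences and the coordinate-bearing chain subsequences
  # are compared, since local alignments of either can find different
  # optima
  chain_sub <- function(s) {
    keep <- setdiff(seq_len(lay$n_res),
                    c(unlist(lapply(lay$starts[1:3] + lay$hl, function(st)
                      st + 0:(.FIX$loop_len - 1))),
                      lay$tail_start + 0:(.FIX$tail_len - 1)))
    paste0(strsplit(s, "")[[1]][keep], collapse = "")
  }
  dissimilar <- function(a, b) {
    all(vapply(list(c(a, b), c(a, chain_sub(b)), c(chain_sub(a), b),
                    c(chain_sub(a), chain_sub(b))),
               function(p) align_pair(p[1], p[2])$identity_fraction <= 0.25,
               logical(1)))
  }
  seqs <- character(n_all)
  for (i in seq_len(n_all)) {
    repeat {
      cand <- paste0(sample(.FIX_ALPHABET, lay$n_res, replace = TRUE),
                     collapse = "")
      if (all(vapply(seq_len(i - 1), function(j) dissimilar(cand, seqs[j]),
                     logical(1)))) { seqs[i] <- cand; break }
    }
  }
  proteins <- setNames(lapply(seq_len(n_all), function(i)
    protein_entry(accs[i], seqs[i])), accs)

  # ground-truth chains in the global frame
  true_chains <- setNames(lapply(seq_len(n_all), function(i) {
    ch <- .bundle_chain("A", seqs[i], hl, source_protein = accs[i])
    th <- nodes$theta[i] * pi / 180
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  nrow = 3, byrow = TRUE)
    apply_transform(ch, rigid_transform(rot, c(nodes$cx[i], nodes$cy[i], 0)))
  }), accs)

  # crystal entries: one per contact edge, in a random rigid frame
  edges <- data.frame(acc_a = accs[lt$edges[, 1]], acc_b = accs[lt$edges[, 2]],
                      entry = sprintf("E%03d", seq_len(nrow(lt$edges))),
                      stringsAsFactors = FALSE)
  record_edges <- edges   # rows that enter the interaction table
  dropped_pairs <- character(); dropped_entry_pairs <- character()
  if ((spec$drop_edge || spec$drop_entry) &&
      spec$topology %in% c("ring", "complete")) {
    di <- nrow(edges)     # the cycle-closing, network-redundant edge
    key <- pair_key(c(edges$acc_a[di], edges$acc_b[di]))
    if (spec$drop_edge) {
      dropped_pairs <- key
      record_edges <- record_edges[-di, , drop = FALSE]
    } else {
      dropped_entry_pairs <- key
    }
    edges <- edges[-di, , drop = FALSE]
  }
  entries <- list()
  for (k in seq_len(nrow(edges))) {
    tr <- rigid_transform(.rand_rotation(), stats::runif(3, -30, 30))
    ca <- apply_transform(true_chains[[edges$acc_a[k]]], tr)
    cb <- apply_transform(true_chains[[edges$acc_b[k]]], tr)
    ca$chain_id <- "A"; cb$chain_id <- "B"
    ca$source_entry <- edges$entry[k]; cb$source_entry <- edges$entry[k]
    entries[[edges$entry[k]]] <- list(chains = list(ca, cb), transform = tr)
  }

  # homologue-ladder decoys: single-chain entries homologous to protein 1
  ladder <- list()
  if (!is.null(spec$identity_ladder)) {
    for (j in seq_along(spec$identity_ladder)) {
      ent <- sprintf("L%03d", j)
      mseq <- mutate_sequence(seqs[1], spec$identity_ladder[j])
      ch <- .bundle_chain("A", mseq, hl)
      ch$source_entry <- ent
      ladder[[ent]] <- list(chains = list(ch),
                            identity = spec$identity_ladder[j])
    }
  }

  # interaction table: contact edges (+ clash-extra edges already in
  # `record_edges`), plus optional extra non-contact pairs; a fully
  # dropped edge is absent by construction
  inter <- data.frame(acc_a = record_edges$acc_a, acc_b = record_edges$acc_b,
                      detection_method = "two hybrid",
                      source_id = sprintf("INT-%03d",
                                          seq_len(nrow(record_edges))),
                      stringsAsFactors = FALSE)
  if (spec$topology == "complete") {
    all_pairs <- t(utils::combn(accs[seq_len(n)], 2))
    have <- c(vapply(seq_len(nrow(inter)), function(i)
      pair_key(c(inter$acc_a[i], inter$acc_b[i])), character(1)),
      dropped_pairs)
    extra <- all_pairs[!apply(all_pairs, 1, pair_key) %in% have, ,
                       drop = FALSE]
    if (nrow(extra) > 0) {
      inter <- rbind(inter, data.frame(
        acc_a = extra[, 1], acc_b = extra[, 2],
        detection_method = "coimmunoprecipitation",
        source_id = sprintf("INT-%03d", nrow(inter) + seq_len(nrow(extra))),
        stringsAsFactors = FALSE))
    }
  } else if (spec$n_indirect > 0) {
    all_pairs <- t(utils::combn(accs[seq_len(n)], 2))
    have <- c(vapply(seq_len(nrow(inter)), function(i)
      pair_key(c(inter$acc_a[i], inter$acc_b[i])), character(1)),
      dropped_pairs)
    extra <- all_pairs[!apply(all_pairs, 1, pair_key) %in% have, ,
                       drop = FALSE]
    extra <- utils::head(extra, spec$n_indirect)
    if (nrow(extra) > 0) {
      inter <- rbind(inter, data.frame(
        acc_a = extra[, 1], acc_b = extra[, 2],
        detection_method = "coimmunoprecipitation",
        source_id = sprintf("INT-%03d", nrow(inter) + seq_len(nrow(extra))),
        stringsAsFactors = FALSE))
    }
  }

  # expected distinct models after deduplication
  expected_models <- if (spec$topology == "two_blocks") {
    k2 <- (n - 1) %/% 2; k1 <- n - 1 - k2
    list(c(accs[1], accs[1 + seq_len(k1)]),
         c(accs[1], accs[1 + k1 + seq_len(k2)]))
  } else {
    list(accs[seq_len(n)])
  }

  # planted variants
  variants <- NULL
  if (!is.null(spec$variant_plan)) {
    variants <- .plant_variants(spec, lay, nodes, accs, seqs, lt$edges, n)
  }

  out <- structure(list(spec = spec, proteins = proteins,
                        true_chains = true_chains, edges = edges,
                        entries = entries, ladder = ladder,
                        interactions = inter, variants = variants,
                        planted_clashes = planted_clashes,
                        expected_models = expected_models,
                        dropped_pairs = dropped_pairs,
                        dropped_entry_pairs = dropped_entry_pairs,
                        layout = list(nodes = nodes, lay = lay)),
                   class = "toy_complex")
  if (!is.null(out_dir)) out$paths <- write_toy_complex(out, out_dir)
  out
}

# pick planted variant positions with construction-time known environments
.plant_variants <- function(spec, lay, nodes, accs, seqs, edge_idx, n) {
  plan <- spec$variant_plan
  classes <- c("disease", "polymorphism", "unclassified")
  rows <- list()
  used <- character()
  add <- function(acc, pos, env) {
    key <- paste(acc, pos)
    if (key %in% used || pos > lay$n_res) return(FALSE)
    used <<- c(used, key)
    s <- strsplit(seqs[match(acc, accs)], "")[[1]]
    rows[[length(rows) + 1L]] <<- data.frame(
      accession = acc, position = pos, ref_aa = s[pos],
      alt_aa = unname(.CONS_PARTNER[s[pos]]),
      var_class = classes[(length(rows) %% 3) + 1],
      planted_env = env, stringsAsFactors = FALSE)
    TRUE
  }
  # interface: residues facing the partner across planted contacts
  k <- 0; want <- if (is.na(plan["interface"])) 0 else plan["interface"]
  for (rank in 1:3) {
    for (e in seq_len(nrow(edge_idx))) {
      if (k >= want) break
      i <- edge_idx[e, 1]; j <- edge_idx[e, 2]
      if (i > n || j > n) next
      dir <- atan2(nodes$cy[j] - nodes$cy[i],
                   nodes$cx[j] - nodes$cx[i]) * 180 / pi
      pos <- .facing_residue(lay, nodes$theta[i], dir, rank)
      if (add(accs[i], pos, "interface")) k <- k + 1
    }
  }
  # surface: outward face of nodes with a free direction
  k <- 0; want <- if (is.na(plan["surface"])) 0 else plan["surface"]
  for (rank in 1:3) {
    for (i in seq_len(n)) {
      if (k >= want) break
      if (is.na(nodes$free_dir[i])) next
      pos <- .facing_residue(lay, nodes$theta[i], nodes$free_dir[i], rank)
      if (add(accs[i], pos, "surface")) k <- k + 1
    }
  }
  # interior: core-facing residues
  k <- 0; want <- if (is.na(plan["interior"])) 0 else plan["interior"]
  for (h in 1:4) {
    for (i in seq_len(n)) {
      if (k >= want) break
      if (add(accs[i], .core_residue(lay, h), "interior")) k <- k + 1
    }
  }
  # disordered: tail and loop positions
  k <- 0; want <- if (is.na(plan["disordered"])) 0 else plan["disordered"]
  cand_pos <- c(lay$tail_start + seq_len(.FIX$tail_len) - 1,
                lay$starts[1] + lay$hl + 0:(.FIX$loop_len - 1))
  for (pos in cand_pos) {
    for (i in seq_len(n)) {
      if (k >= want) break
      if (add(accs[i], pos, "disordered")) k <- k + 1
    }
  }
  do.call(rbind, rows)
}

#' Write a toy complex's pipeline input files
#'
#' @param toy A `toy_complex`.
#' @param out_dir Output directory (created if missing).
#' @return Named list of written paths (`entries` dir, `fasta`,
#'   `interactions`, `variants`).
#' @export
write_toy_complex <- function(toy, out_dir) {
  dir.create(file.path(out_dir, "entries"), recursive = TRUE,
             showWarnings = FALSE)
  for (ent in names(toy$entries)) {
    write_complex(toy$entries[[ent]]$chains,
                  file.path(out_dir, "entries", paste0(ent, ".pdb")))
  }
  for (ent in names(toy$ladder)) {
    write_complex(toy$ladder[[ent]]$chains,
                  file.path(out_dir, "entries", paste0(ent, ".pdb")))
  }
  fasta <- file.path(out_dir, "proteins.fasta")
  seqs <- Biostrings::AAStringSet(vapply(toy$proteins, function(p) p$sequence,
                                         character(1)))
  names(seqs) <- names(toy$proteins)
  Biostrings::writeXStringSet(seqs, fasta)
  itsv <- file.path(out_dir, "interactions.tsv")
  utils::write.table(toy$interactions, itsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vtsv <- NULL
  if (!is.null(toy$variants)) {
    vtsv <- file.path(out_dir, "variants.tsv")
    utils::write.table(
      toy$variants[, c("accession", "position", "ref_aa", "alt_aa",
                       "var_class")],
      vtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(entries = file.path(out_dir, "entries"), fasta = fasta,
       interactions = itsv, variants = vtsv)
}

#' All-subunit rmsd of a model against fixture ground truth
#'
#' Subunits are matched to ground-truth chains by protein accession; all
#' matched C-alpha coordinates are pooled, superposed once (whole-complex
#' Kabsch) and the rmsd reported.
#'
#' @param model A `complex_model`.
#' @param toy The `toy_complex` it was built from.
#' @return Rmsd in Angstrom.
#' @export
ground_truth_rmsd <- function(model, toy) {
  P <- NULL; Q <- NULL
  for (s in model$subunits) {
    truth <- toy$true_chains[[s$protein]]
    if (is.null(truth)) stop("no ground-truth chain for ", s$protein)
    cm <- ca_coords(s$chain); ct <- ca_coords(truth)
    common <- intersect(rownames(cm), rownames(ct))
    P <- rbind(P, cm[common, , drop = FALSE])
    Q <- rbind(Q, ct[common, , drop = FALSE])
  }
  kabsch(P, Q)$rmsd
}
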