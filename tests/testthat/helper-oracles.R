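# Independent oracles and small constructors used across the suite.
# Every oracle re-derives its quantity by a different route than the
# package implementation (textbook DP, quaternion eigenproblem, dense
# random sampling, flood fill, exact enumeration).

.b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- Smith-Waterman (Gotoh affine) local alignment oracle -----------------
# gap of length L costs open + L * ext
oracle_sw <- function(a, b, open = 11, ext = 1, min_score = 25) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)   # best ending in match
  E <- matrix(-Inf, n + 1, m + 1) # gap in B (deletion from A)
  F <- matrix(-Inf, n + 1, m + 1) # gap in A
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
      s <- .b62[A[i - 1], B[j - 1]]
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best < min_score) {
    return(list(score = best, identity_fraction = 0,
                aligned_pairs = matrix(integer(), ncol = 2)))
  }
  # traceback from (bi, bj)
  i <- bi; j <- bj
  pairs <- NULL; nid <- 0
  while (i > 1 && j > 1 && H[i, j] > 0) {
    s <- .b62[A[i - 1], B[j - 1]]
    if (H[i, j] == H[i - 1, j - 1] + s) {
      pairs <- rbind(c(i - 1, j - 1), pairs)
      if (A[i - 1] == B[j - 1]) nid <- nid + 1
      i <- i - 1; j <- j - 1
    } else if (H[i, j] == E[i, j]) {
      while (i > 1 && E[i, j] != H[i - 1, j] - open - ext) i <- i - 1
      i <- i - 1
    } else {
      while (j > 1 && F[i, j] != H[i, j - 1] - open - ext) j <- j - 1
      j <- j - 1
    }
  }
  list(score = best, identity_fraction = nid / nrow(pairs),
       aligned_pairs = pairs)
}

# re-score an alignment path (matched-column pairs) under the same
# substitution/affine-gap model; unmatched residues between consecutive
# columns sit opposite gaps
rescore_alignment <- function(a, b, pairs, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  sc <- 0; nid <- 0
  for (r in seq_len(nrow(pairs))) {
    sc <- sc + .b62[A[pairs[r, 1]], B[pairs[r, 2]]]
    if (A[pairs[r, 1]] == B[pairs[r, 2]]) nid <- nid + 1
    if (r > 1) {
      dq <- pairs[r, 1] - pairs[r - 1, 1] - 1
      ds <- pairs[r, 2] - pairs[r - 1, 2] - 1
      if (dq > 0) sc <- sc - open - ext * dq
      if (ds > 0) sc <- sc - open - ext * ds
    }
  }
  list(score = sc, identity = nid / nrow(pairs))
}

# --- Horn quaternion superposition oracle ---------------------------------
oracle_horn <- function(moving, fixed) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    nrow = 3, byrow = TRUE)
  moved <- P %*% t(R)
  list(R = R,
       t = as.numeric(colMeans(fixed) - R %*% colMeans(moving)),
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# --- dense-sampling SASA oracle -------------------------------------------
# random sphere points (seeded), default 10,000 per atom
oracle_sasa_dense <- function(chains, probe = 1.4, n_points = 10000,
                              seed = 991) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  radii <- function(el) {
    r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)[
      toupper(el)]
    r[is.na(r)] <- 1.8
    unname(r)
  }
  at <- do.call(rbind, lapply(seq_along(chains), function(i) {
    a <- chains[[i]]$atoms
    a <- a[a$is_heavy, , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    data.frame(chain = i, seq_index = a$seq_index, element = a$element,
               x = a$x, y = a$y, z = a$z)
  }))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- radii(at$element) + probe
  set.seed(seed)
  # quasi-uniform lattice under an independent random rotation per atom:
  # dense and accurate, with none of the iid-sampling noise
  i_pt <- seq_len(n_points) - 0.5
  zz <- 1 - 2 * i_pt / n_points
  rr <- sqrt(pmax(0, 1 - zz^2))
  phi <- i_pt * (pi * (sqrt(5) - 1))   # a different spiral increment
  base_pts <- cbind(rr * cos(phi), rr * sin(phi), zz)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- base_pts %*% t(rand_rot())
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) { area[i] <- 4 * pi * rad[i]^2; next }
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc[acc][rowSums(sweep(sp[acc, , drop = FALSE], 2,
                             xyz[j, ])^2) < rad[j]^2] <- FALSE
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  out <- aggregate(area, by = list(chain = at$chain,
                                   seq_index = at$seq_index), FUN = sum)
  names(out)[3] <- "area"
  out
}

# --- connected-components flood-fill oracle -------------------------------
oracle_components <- function(acc_a, acc_b) {
  nodes <- sort(unique(c(acc_a, acc_b)))
  seen <- character()
  comps <- list()
  adj <- function(v) unique(c(acc_b[acc_a == v], acc_a[acc_b == v]))
  for (v in nodes) {
    if (v %in% seen) next
    comp <- character(); queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj(u), comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# --- exact hypergeometric tail by enumeration -----------------------------
oracle_hyper_tail <- function(overlap, marked, unmarked, draw) {
  ks <- overlap:min(marked, draw)
  ks <- ks[draw - ks <= unmarked]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(marked, ks) + lchoose(unmarked, draw - ks) -
            lchoose(marked + unmarked, draw)))
}

# --- exhaustive-seed TM-score oracle --------------------------------------
# all contiguous windows of every length >= 5 as seeds, refined with the
# same keep-close/re-superpose rule but using the Horn oracle for fits
oracle_tm <- function(P, Q, norm_length) {
  d0 <- if (norm_length > 15) {
    max(0.5, 1.24 * (norm_length - 15)^(1 / 3) - 1.8)
  } else 0.5
  n <- nrow(P)
  best <- -Inf
  refine <- function(sel) {
    res <- -Inf
    repeat {
      if (length(sel) < 3) break
      fit <- oracle_horn(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      moved <- sweep(P %*% t(fit$R), 2, -fit$t)
      d <- sqrt(rowSums((moved - Q)^2))
      sc <- sum(1 / (1 + (d / d0)^2)) / norm_length
      if (sc > res) res <- sc
      cut <- max(d0, 3.5)
      repeat {
        ns <- which(d < cut)
        if (length(ns) >= 3) break
        cut <- cut + 0.5
      }
      if (identical(ns, sel)) break
      sel <- ns
    }
    res
  }
  for (L in 5:n) {
    for (s in 1:(n - L + 1)) {
      sc <- refine(seq.int(s, s + L - 1))
      if (sc > best) best <- sc
    }
  }
  best
}

# --- constructors ----------------------------------------------------------

# CA-only chain from a coordinate matrix
make_ca_chain <- function(xyz, seq = strrep("A", nrow(xyz)),
                          chain_id = "A", entry = NA_character_,
                          protein = NA_character_) {
  n <- nrow(xyz)
  chain_structure(chain_id,
                  data.frame(seq_index = 1:n,
                             aa = strsplit(seq, "")[[1]][1:n]),
                  data.frame(seq_index = 1:n, name = "CA", element = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                  source_entry = entry, source_protein = protein)
}

# ideal CA helix along z
helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.28, phase = 0) {
  ang <- (phase + twist * (0:(n - 1))) * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * (0:(n - 1)))
}

# full-backbone straight helix (N, CA, C, O, CB), axis along z at (x0, y0);
# geometry mirrors the fixture generator's ideal-helix parameters
helix_chain <- function(n, chain_id = "A", seq = strrep("A", n),
                        x0 = 0, y0 = 0, z0 = 0, phase = 0,
                        entry = NA_character_, protein = NA_character_) {
  tpl <- data.frame(name = c("N", "CA", "C", "O", "CB"),
                    element = c("N", "C", "C", "O", "C"),
                    r = c(1.60, 2.28, 1.65, 2.00, 3.30),
                    dphi = c(-26, 0, 21, 40, -15),
                    dz = c(-0.75, 0, 0.75, 1.25, -0.60))
  atoms <- do.call(rbind, lapply(0:(n - 1), function(i) {
    ang <- (phase + 100 * i) * pi / 180
    data.frame(seq_index = i + 1, name = tpl$name, element = tpl$element,
               x = x0 + tpl$r * cos(ang + tpl$dphi * pi / 180),
               y = y0 + tpl$r * sin(ang + tpl$dphi * pi / 180),
               z = z0 + 1.5 * i + tpl$dz)
  }))
  chain_structure(chain_id,
                  data.frame(seq_index = 1:n,
                             aa = strsplit(seq, "")[[1]][1:n]),
                  atoms, source_entry = entry, source_protein = protein)
}

# minimal complex_model wrapper around placed chains
fake_model <- function(chains, proteins = NULL, joined = character()) {
  if (is.null(proteins)) proteins <- paste0("P", seq_along(chains))
  subunits <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    list(subunit_id = paste0("S", i), protein = proteins[i], chain = ch,
         target_map = setNames(ch$residues$seq_index,
                               as.character(seq_len(nrow(ch$residues)))),
         anchor = if (i <= 2) paste0("S", i) else "S1",
         introduced_by = NA, template_pair = c(ch$source_entry, ch$chain_id),
         transform = rigid_transform())
  })
  structure(list(subunits = subunits, alternative_records = list(),
                 joined_pairs = joined, rejections = list(),
                 start_subunit = proteins[1], mode = "degree"),
            class = "complex_model")
}

# random proper rotation for property tests
rand_rot <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# --- shared fixtures (generated once per test session) --------------------
.toy_cache <- new.env(parent = emptyenv())

shared_toy <- function(key, spec) {
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- make_toy_complex(spec, out_dir = tempfile(key))
  }
  .toy_cache[[key]]
}

toy_star4c <- function() shared_toy("star4c", fixture_spec(
  seed = 101, n_proteins = 4, topology = "star", clash_pairs = 1,
  variant_plan = c(interface = 2, surface = 1, interior = 2,
                   disordered = 1)))

toy_path3 <- function() shared_toy("path3", fixture_spec(
  seed = 102, n_proteins = 3, topology = "path"))

toy_complete4 <- function() shared_toy("complete4", fixture_spec(
  seed = 103, n_proteins = 4, topology = "complete"))

# assemble a toy's models from its in-memory entries (full coordinate
# precision, no PDB round trip)
assemble_in_memory <- function(toy, start = "P01") {
  library_chains <- unname(unlist(lapply(toy$entries, `[[`, "chains"),
                                  recursive = FALSE))
  recs <- lapply(seq_len(nrow(toy$interactions)), function(i)
    interaction_record(toy$interactions$acc_a[i], toy$interactions$acc_b[i],
                       toy$interactions$detection_method[i],
                       toy$interactions$source_id[i]))
  ds <- build_element_dataset(recs, toy$proteins, library_chains)
  net <- cluster_subnetworks(ds$elements)[[1]]
  grow_model(start, net)
}

shared_pipeline <- function(key, toy, detect = TRUE) {
  pkey <- paste0("pipe_", key, "_", detect)
  if (is.null(.toy_cache[[pkey]])) {
    inp <- load_inputs(toy$paths$entries, toy$paths$fasta,
                       toy$paths$interactions, toy$paths$variants)
    .toy_cache[[pkey]] <- list(
      inputs = inp,
      result = suppressWarnings(run_pipeline(inp, detect = detect)))
  }
  .toy_cache[[pkey]]
}
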