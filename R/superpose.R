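#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `moving`
#' onto `fixed`.  A reflection-only optimum is corrected to a proper
#' rotation by flipping the smallest singular direction.
#'
#' @param moving,fixed Numeric n x 3 matrices (n >= 3) of corresponding
#'   points.
#' @return List with `transform` (a [rigid_transform()]) and `rmsd`, the
#'   minimized root-mean-square deviation in Angstrom.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed))) {
    stop("point sets must have equal dimensions")
  }
  if (nrow(moving) < 3) stop("need at least 3 points")
  mp <- colMeans(moving); mf <- colMeans(fixed)
  P <- sweep(moving, 2, mp); Q <- sweep(fixed, 2, mf)
  H <- crossprod(P, Q)                       # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(mf - R %*% mp)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

#' TM-score normalization distance d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom (the floor is
#' what makes the score usable for short chains, L < ~19).
#'
#' @param norm_length Normalization length L.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(norm_length) {
  if (norm_length > 15) max(0.5, 1.24 * (norm_length - 15)^(1 / 3) - 1.8)
  else 0.5
}

# refine a superposition from a seed subset: iteratively keep pairs within
# d_cut, re-superpose, recompute the TM-score on ALL pairs; returns best
# encountered (score, transform).
.tm_refine <- function(P, Q, seed_idx, d0, norm_length, max_iter = 20) {
  best <- list(score = -Inf, transform = NULL)
  sel <- seed_idx
  for (it in seq_len(max_iter)) {
    if (length(sel) < 3) break
    fit <- kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
    moved <- sweep(P %*% t(fit$transform$rotation), 2,
                   -fit$transform$translation)
    d <- sqrt(rowSums((moved - Q)^2))
    sc <- sum(1 / (1 + (d / d0)^2)) / norm_length
    if (sc > best$score) best <- list(score = sc, transform = fit$transform)
    d_cut <- max(d0, 3.5)
    repeat {
      new_sel <- which(d < d_cut)
      if (length(new_sel) >= 3) break
      d_cut <- d_cut + 0.5
    }
    if (identical(new_sel, sel)) break
    sel <- new_sel
  }
  best
}

.tm_opt <- function(P, Q, norm_length) {
  n <- nrow(P)
  d0 <- tm_d0(norm_length)
  lens <- if (n <= 5) n else seq.int(n, 5L)
  best <- list(score = -Inf, transform = NULL)
  max_score <- n / norm_length   # attained only when every pair sits at 0
  for (L in lens) {
    for (s in seq_len(n - L + 1L)) {
      cand <- .tm_refine(P, Q, seq.int(s, s + L - 1L), d0, norm_length)
      if (cand$score > best$score) best <- cand
      if (best$score >= max_score - 1e-9) return(best)
    }
  }
  best
}

#' TM-score of a matched residue pairing
#'
#' `TM = max over superpositions of (1/L_norm) * sum_i 1/(1 + (d_i/d0)^2)`
#' where the sum runs over the matched C-alpha pairs and the maximization
#' uses an exhaustive iterative fragment-seed search (every contiguous
#' seed window of length 5 up to the full alignment, each refined by
#' keep-close-pairs/re-superpose iteration).
#'
#' @param moving,fixed [chain_structure()] objects.
#' @param pairs Two-column matrix of residue `seq_index` values
#'   (moving, fixed) for the matched pairs.
#' @param norm_length Normalization length (by convention the length of the
#'   anchor, i.e. `fixed`, subunit).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(moving, fixed, pairs,
                     norm_length = sum(fixed$residues$has_coords)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) stop("no matched pairs")
  cm <- ca_coords(moving); cf <- ca_coords(fixed)
  keep <- as.character(pairs[, 1]) %in% rownames(cm) &
          as.character(pairs[, 2]) %in% rownames(cf)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3) stop("fewer than 3 matched pairs with CA coordinates")
  P <- cm[as.character(pairs[, 1]), , drop = FALSE]
  Q <- cf[as.character(pairs[, 2]), , drop = FALSE]
  .tm_opt(P, Q, norm_length)$score
}

#' Sequence-guided structural alignment of two chains
#'
#' Residue correspondence is taken from a local sequence alignment of the
#' two chains ([align_pair()]), then refined by iterative superposition
#' with outlier rejection: pairs farther than `2 d0` are dropped and the
#' remainder re-superposed, up to 10 rounds.  This deliberately simplified
#' structural aligner provides the score semantics needed by the assembly
#' acceptance gate; exact numerical agreement with full
#' dynamic-programming structure aligners is not promised.
#'
#' @param a Moving chain ([chain_structure()]).
#' @param b Fixed (anchor) chain.
#' @param min_score Score floor passed to [align_pair()].
#' @return List of class `superposition_result`: `transform` (maps `a` into
#'   the frame of `b`), `rmsd` (over retained pairs), `tmscore` (normalized
#'   by the fixed chain length), `n_matched` (retained pairs),
#'   `identity_struct` (identity over retained pairs), `pairs` (the full
#'   sequence-aligned pairing).
#' @export
structure_align <- function(a, b, min_score = 25) {
  na <- sum(a$residues$has_coords); nb <- sum(b$residues$has_coords)
  if (na < 15 || nb < 15) stop("chains must have >= 15 residues with coordinates")
  aln <- align_pair(chain_sequence(a), chain_sequence(b),
                    min_score = min_score)
  if (nrow(aln$aligned_pairs) == 0) stop("sequence alignment is empty")
  # map alignment positions (residue-table order) to seq_index
  idx_a <- a$residues$seq_index[aln$aligned_pairs[, 1]]
  idx_b <- b$residues$seq_index[aln$aligned_pairs[, 2]]
  cm <- ca_coords(a); cf <- ca_coords(b)
  ok <- as.character(idx_a) %in% rownames(cm) &
        as.character(idx_b) %in% rownames(cf)
  idx_a <- idx_a[ok]; idx_b <- idx_b[ok]
  if (length(idx_a) < 3) stop("fewer than 3 aligned residues with coordinates")
  P <- cm[as.character(idx_a), , drop = FALSE]
  Q <- cf[as.character(idx_b), , drop = FALSE]
  d0 <- tm_d0(nb)
  sel <- seq_along(idx_a)
  fit <- kabsch(P, Q)
  for (round in seq_len(10)) {
    moved <- sweep(P %*% t(fit$transform$rotation), 2,
                   -fit$transform$translation)
    d <- sqrt(rowSums((moved - Q)^2))
    keep <- intersect(sel, which(d <= 2 * d0))
    if (length(keep) < 3 || identical(keep, sel)) break
    sel <- keep
    fit <- kabsch(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
  }
  moved_sel <- sweep(P[sel, , drop = FALSE] %*% t(fit$transform$rotation), 2,
                     -fit$transform$translation)
  rmsd <- sqrt(mean(rowSums((moved_sel - Q[sel, , drop = FALSE])^2)))
  aa_a <- setNames(a$residues$aa, as.character(a$residues$seq_index))
  aa_b <- setNames(b$residues$aa, as.character(b$residues$seq_index))
  ident <- mean(aa_a[as.character(idx_a[sel])] ==
                aa_b[as.character(idx_b[sel])])
  tm <- .tm_opt(P, Q, nb)$score
  structure(list(transform = fit$transform, rmsd = rmsd, tmscore = tm,
                 n_matched = length(sel), identity_struct = ident,
                 pairs = cbind(moving = idx_a, fixed = idx_b)),
            class = "superposition_result")
}

#' Superposition acceptance gate
#'
#' A superposition of an anchor subunit onto a template's shared chain is
#' accepted when the sequence identity (from structure alignment) exceeds
#' 30% and the TM-score exceeds 0.5, or when the identity lies in the
#' 25-30% band and the TM-score exceeds 0.6.  Below 25% identity nothing is
#' accepted.  Identity exactly 0.30 falls in the stricter band; identity
#' exactly 0.25 is admitted to it.
#'
#' @param identity_struct Identity fraction in `[0,1]`.
#' @param tmscore TM-score in `[0,1]`.
#' @return Logical.
#' @export
accept_superposition <- function(identity_struct, tmscore) {
  stopifnot(identity_struct >= 0, identity_struct <= 1,
            tmscore >= 0, tmscore <= 1)
  (identity_struct > 0.30 & tmscore > 0.5) |
    (identity_struct >= 0.25 & identity_struct <= 0.30 & tmscore > 0.6)
}
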