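# conservative substitution used to plant single point mutations
.CONS_PARTNER_TEST <- function(aa) {
  m <- c(A = "S", C = "A", D = "E", E = "D", F = "Y", G = "A", H = "Y",
         I = "V", K = "R", L = "M", M = "L", N = "D", Q = "E", R = "K",
         S = "T", T = "S", V = "I", W = "Y", Y = "F")
  m[[aa]]
}

test_that("Kabsch recovers rigid motions and matches the quaternion oracle", {
  set.seed(5)
  pts <- helix_ca(12)
  self <- kabsch(pts, pts)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)
  # recover a planted motion and invert it
  R <- rand_rot(); tr <- c(4, -2, 7)
  moved <- sweep(pts %*% t(R), 2, -tr)
  fit <- kabsch(pts, moved)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$transform$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - tr)), 1e-9)
  # perturbed point sets: rmsd equals the Horn oracle
  for (k in 1:50) {
    n <- sample(4:20, 1)
    P <- matrix(stats::rnorm(3 * n, sd = 5), ncol = 3)
    Q <- sweep(P %*% t(rand_rot()), 2, stats::rnorm(3)) +
      matrix(stats::rnorm(3 * n, sd = 0.5), ncol = 3)
    expect_lt(abs(kabsch(P, Q)$rmsd - oracle_horn(P, Q)$rmsd), 1e-9)
    expect_equal(det(kabsch(P, Q)$transform$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "3 points")
  expect_error(kabsch(pts[1:4, ], pts[1:5, ]), "equal")
})

test_that("degenerate near-planar point sets still yield proper rotations", {
  # a mirrored planar set invites a reflection optimum; it must be
  # corrected to a proper rotation
  P <- cbind(c(0, 1, 2, 3, 1), c(0, 2, 0, 2, 1), 0)
  Q <- P; Q[, 1] <- -Q[, 1]
  fit <- kabsch(P, Q)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_gte(fit$rmsd, 0)
})

test_that("TM-score is 1 for self and rigid copies and matches its oracle", {
  ch <- make_ca_chain(helix_ca(30))
  pairs <- cbind(1:30, 1:30)
  expect_equal(tm_score(ch, ch, pairs), 1.0, tolerance = 1e-9)
  moved <- apply_transform(ch, rigid_transform(rand_rot(), c(3, 2, -9)))
  expect_equal(tm_score(moved, ch, pairs), 1.0, tolerance = 1e-9)
  # planted smooth ~2 A distortion: agree with the exhaustive-seed oracle
  set.seed(42)
  xyz <- helix_ca(30)
  dist_xyz <- xyz
  dist_xyz[, 1] <- xyz[, 1] + 2 * sin(seq(0, pi, length.out = 30))
  cha <- make_ca_chain(dist_xyz)
  tm <- tm_score(cha, ch, pairs, norm_length = 30)
  expect_equal(tm, oracle_tm(dist_xyz, xyz, 30), tolerance = 1e-6)
  expect_lt(tm, 1)
  expect_error(tm_score(ch, ch, matrix(integer(), ncol = 2)), "pairs")
})

test_that("TM-score is invariant under rigid motion of either input", {
  ch <- make_ca_chain(helix_ca(25) +
                        matrix(stats::rnorm(75, sd = 0.8), ncol = 3))
  ref <- make_ca_chain(helix_ca(25))
  pairs <- cbind(1:25, 1:25)
  base <- tm_score(ch, ref, pairs, norm_length = 25)
  set.seed(8)
  for (k in 1:5) {
    t1 <- rigid_transform(rand_rot(), stats::rnorm(3, sd = 20))
    expect_equal(tm_score(apply_transform(ch, t1), ref, pairs,
                          norm_length = 25), base, tolerance = 1e-6)
  }
})

test_that("d0 follows the standard formula with a 0.5 A floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(tm_d0(19), 0.5)   # formula gives 0.17, floored
  expect_equal(tm_d0(10), 0.5)
})

test_that("structure alignment reports identity over matched pairs", {
  toy <- toy_path3()
  ch <- toy$true_chains[["P01"]]
  res <- structure_align(ch, ch)
  expect_equal(res$tmscore, 1.0, tolerance = 1e-9)
  expect_equal(res$identity_struct, 1.0)
  expect_lt(res$rmsd, 1e-9)
  # point-mutated rigid copy: 1 of 30+ residues changed
  mut <- ch
  i <- which(mut$residues$has_coords)[10]
  mut$residues$aa[i] <- .CONS_PARTNER_TEST(mut$residues$aa[i])
  moved <- apply_transform(mut, rigid_transform(rand_rot(), c(5, 5, 5)))
  res2 <- structure_align(moved, ch)
  ncoord <- res2$n_matched
  expect_equal(res2$identity_struct, (ncoord - 1) / ncoord)
  expect_gte(res2$tmscore, 0.99)
  # unrelated folds: helix vs extended strand, same sequence
  seqx <- strrep("A", 30)
  hel <- make_ca_chain(helix_ca(30), seq = seqx)
  strand <- make_ca_chain(cbind(3.8 * (0:29), 0, 0), seq = seqx)
  expect_lt(structure_align(strand, hel)$tmscore, 0.5)
  expect_error(structure_align(make_ca_chain(helix_ca(10)),
                               make_ca_chain(helix_ca(10))),
               ">= 15")
})

test_that("the acceptance gate reproduces all printed regimes", {
  # high-identity regime still requires TM > 0.5
  expect_false(accept_superposition(0.35, 0.45))
  expect_true(accept_superposition(0.35, 0.55))
  # 25-30% band requires TM > 0.6
  expect_true(accept_superposition(0.27, 0.65))
  expect_false(accept_superposition(0.27, 0.55))
  # below 25% identity nothing passes
  expect_false(accept_superposition(0.20, 0.95))
  # boundary conventions: 0.30 belongs to the strict band, 0.25 enters it
  expect_false(accept_superposition(0.30, 0.55))
  expect_true(accept_superposition(0.30, 0.65))
  expect_true(accept_superposition(0.25, 0.65))
  expect_false(accept_superposition(0.25, 0.55))
  # monotone non-decreasing in TM-score at fixed identity
  for (id in c(0.2, 0.27, 0.5)) {
    tms <- seq(0, 1, by = 0.05)
    acc <- vapply(tms, function(tm) accept_superposition(id, tm), logical(1))
    expect_true(all(diff(acc) >= 0))
  }
})
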