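test_that("clash predicate counts close CA pairs against a brute-force count", {
  base <- make_ca_chain(cbind(0, 0, 4 * (0:19)))
  far <- make_ca_chain(cbind(50, 0, 4 * (0:19)))
  expect_false(clash(list(list(chain = base)), far))
  expect_true(clash(list(list(chain = base)), base))  # exact superposition
  # construct exactly k pairs at 2.5 A
  mk_overlap <- function(k) {
    xyz <- cbind(50, 0, 4 * (0:19))
    xyz[seq_len(k), ] <- cbind(2.5, 0, 4 * (0:(k - 1)))
    make_ca_chain(xyz)
  }
  brute <- function(cand) {
    ca <- ca_coords(base); cb <- ca_coords(cand)
    sum(sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") -
               2 * ca %*% t(cb)) < 3.0)
  }
  c8 <- mk_overlap(8); c12 <- mk_overlap(12)
  expect_equal(brute(c8), 8)
  expect_equal(brute(c12), 12)
  expect_false(clash(list(list(chain = base)), c8))
  expect_true(clash(list(list(chain = base)), c12))
  # configurable thresholds
  expect_true(clash(list(list(chain = base)), c8, max_pairs = 5))
})

test_that("anchor selection follows degree with placement-order ties", {
  net <- cluster_subnetworks(list(
    structure(list(interaction = interaction_record("A", "B")),
              class = "ppi_element"),
    structure(list(interaction = interaction_record("A", "C")),
              class = "ppi_element"),
    structure(list(interaction = interaction_record("A", "D")),
              class = "ppi_element")))[[1]]
  model <- fake_model(list(make_ca_chain(helix_ca(16)),
                           make_ca_chain(helix_ca(16)),
                           make_ca_chain(helix_ca(16))),
                      proteins = c("A", "B", "C"))
  expect_equal(select_anchor(model, net), "S1")          # degree 3 hub
  expect_equal(select_anchor(model, net, "S1"), "S2")    # tie B/C: placed first
  expect_null(select_anchor(model, net, c("S1", "S2", "S3")))
})

test_that("assembly recovers a star and records planted clashes", {
  toy <- toy_star4c()
  inp <- shared_pipeline("star4c", toy, detect = TRUE)
  model <- grow_model("P01", cluster_subnetworks(
    inp$result$dataset$elements)[[1]])
  prots <- vapply(model$subunits, function(s) s$protein, character(1))
  expect_setequal(prots, toy$expected_models[[1]])
  expect_lt(ground_truth_rmsd(model, toy), 0.1)
  # the planted same-site extra yields exactly one alternative record
  expect_length(model$alternative_records, 1)
  rec <- model$alternative_records[[1]]
  planted <- toy$planted_clashes[[1]]
  expect_equal(rec$owner, planted$owner)
  expect_setequal(c(rec$partner_a, rec$partner_b),
                  c(planted$partner_a, planted$partner_b))
  # non-seed subunits anchor onto already-placed subunits
  ids <- vapply(model$subunits, function(s) s$subunit_id, character(1))
  for (i in seq_along(ids)) {
    expect_true(model$subunits[[i]]$anchor %in% ids[seq_len(max(i, 2))])
  }
})

test_that("a single-edge sub-network yields its seed dimer", {
  toy <- shared_toy("path2", fixture_spec(seed = 107, n_proteins = 2,
                                          topology = "path"))
  pip <- shared_pipeline("path2", toy, detect = FALSE)
  net <- cluster_subnetworks(pip$result$dataset$elements)[[1]]
  model <- grow_model("P01", net)
  expect_length(model$subunits, 2)
  expect_setequal(vapply(model$subunits, function(s) s$protein,
                         character(1)), c("P01", "P02"))
})

test_that("deduplication keeps one model per distinct assembly", {
  toy <- toy_path3()
  pip <- shared_pipeline("path3", toy, detect = FALSE)
  expect_length(pip$result$models, 1)
  expect_length(pip$result$models[[1]]$subunits, 3)
  # two incompatible halves survive as distinct models
  toy2 <- shared_toy("blocks5", fixture_spec(seed = 108, n_proteins = 5,
                                             topology = "two_blocks"))
  pip2 <- shared_pipeline("blocks5", toy2, detect = FALSE)
  sets <- lapply(pip2$result$models, function(m)
    sort(vapply(m$subunits, function(s) s$protein, character(1))))
  expect_length(pip2$result$models, 2)
  expect_setequal(lapply(toy2$expected_models, sort), sets)
})

test_that("random anchor selection matches degree mode in mean size", {
  toy <- toy_path3()
  pip <- shared_pipeline("path3", toy, detect = FALSE)
  net <- cluster_subnetworks(pip$result$dataset$elements)[[1]]
  deg_size <- length(grow_model("P01", net, mode = "degree")$subunits)
  sizes <- vapply(1:20, function(s)
    length(grow_model("P01", net, mode = "random", seed = s)$subunits),
    integer(1))
  expect_equal(mean(sizes), deg_size)
  # per-seed reproducibility
  m1 <- grow_model("P01", net, mode = "random", seed = 7)
  m2 <- grow_model("P01", net, mode = "random", seed = 7)
  expect_identical(vapply(m1$subunits, function(s) s$protein, character(1)),
                   vapply(m2$subunits, function(s) s$protein, character(1)))
})

test_that("models terminate, never clash internally, and are deterministic", {
  toy <- toy_star4c()
  pip <- shared_pipeline("star4c", toy)
  for (model in pip$result$models) {
    # termination bound: at most one subunit per sub-network node
    expect_lte(length(model$subunits), length(model$subnetwork_nodes))
    # post-hoc pairwise clash audit
    for (i in seq_along(model$subunits)) {
      others <- model$subunits[-i]
      if (length(others) > 0) {
        expect_false(clash(others, model$subunits[[i]]$chain))
      }
    }
  }
  # byte-level determinism of repeated assembly
  net <- cluster_subnetworks(pip$result$dataset$elements)[[1]]
  m1 <- grow_model("P01", net); m2 <- grow_model("P01", net)
  expect_identical(m1$subunits, m2$subunits)
  expect_identical(m1$alternative_records, m2$alternative_records)
})
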