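# 60-point sphere used to build the atom cage
.sphere_pts_60 <- function() {
  i <- seq_len(60) - 0.5
  z <- 1 - 2 * i / 60
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

test_that("SASA matches a dense-sampling oracle and basic limits", {
  # a single free amino acid: every sphere point of every atom is checked
  # against the 10,000-point random-sampling oracle
  gly <- chain_structure("A",
    data.frame(seq_index = 1, aa = "G"),
    data.frame(seq_index = 1, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(-1.2, 0, 1.3, 2.1), y = c(0.5, 0, 0.4, -0.5),
               z = c(0, 0, 0, 0.3)))
  got <- sasa(gly)$area
  want <- oracle_sasa_dense(gly)$area
  expect_lt(abs(got - want) / want, 0.02)
  # a residue fully enclosed by an atom cage has zero accessible area
  cage_pts <- 4.0 * .sphere_pts_60()
  caged <- chain_structure("A",
    data.frame(seq_index = 1:2, aa = c("A", "X")),
    rbind(data.frame(seq_index = 1, name = "CA", element = "C",
                     x = 0, y = 0, z = 0),
          data.frame(seq_index = 2, name = "X", element = "C",
                     x = cage_pts[, 1], y = cage_pts[, 2],
                     z = cage_pts[, 3])))
  expect_equal(sasa(caged)$area[1], 0)
  # additivity: far-apart chains keep their isolated areas
  a <- helix_chain(12, "A"); b <- helix_chain(12, "B", x0 = 60)
  joint <- sasa(list(a, b))
  expect_equal(joint$area[joint$chain == 1], sasa(a)$area,
               tolerance = 1e-9)
  # SASA is non-negative and weakly decreases with added neighbours
  close_b <- helix_chain(12, "B", x0 = 9)
  joint2 <- sasa(list(a, close_b))
  expect_true(all(joint2$area >= 0))
  expect_true(all(joint2$area[joint2$chain == 1] <= sasa(a)$area + 1e-9))
})

test_that("buried areas match the dense oracle and are roughly symmetric", {
  toy <- toy_path3()
  model <- fake_model(unname(toy$true_chains),
                      proteins = names(toy$true_chains))
  ba <- buried_area(model, 1, 2)
  expect_gt(ba$area_a, 250)
  # dense-oracle cross-check of the planted contact
  ch1 <- toy$true_chains[[1]]; ch2 <- toy$true_chains[[2]]
  alone <- oracle_sasa_dense(ch1, n_points = 4000)
  pairD <- oracle_sasa_dense(list(ch1, ch2), n_points = 4000)
  want <- sum(alone$area) - sum(pairD$area[pairD$chain == 1])
  expect_lt(abs(ba$area_a - want) / want, 0.02)
  # per-subunit areas agree within 25% for compact fixtures
  expect_lt(abs(ba$area_a - ba$area_b) / max(ba$area_a, ba$area_b), 0.25)
  # disjoint subunits bury nothing
  ba13 <- buried_area(model, 1, 3)
  expect_equal(ba13$area_a, 0)
  expect_length(ba13$residues_a, 0)
})

test_that("the 250 A^2 threshold separates a constructed dimer family", {
  # family construction: bundles at growing separation plus single-helix
  # pairs; oracle-measured areas span ~85-450 A^2 and avoid the threshold
  # neighbourhood so sampling noise cannot flip a label
  fam <- list()
  for (D in c(15.5, 16.5, 18.0)) {
    toy <- toy_path3()
    a <- toy$true_chains[[1]]
    b <- apply_transform(a, rigid_transform(diag(3), c(D, 0, 0)))
    fam[[length(fam) + 1L]] <- list(a = a, b = b)
  }
  for (d in c(9.2, 10.0, 10.5)) {
    fam[[length(fam) + 1L]] <- list(a = helix_chain(24, "A"),
                                    b = helix_chain(24, "B", x0 = d))
  }
  for (case in fam) {
    model <- fake_model(list(case$a, case$b))
    alone_a <- oracle_sasa_dense(case$a, n_points = 4000)
    alone_b <- oracle_sasa_dense(case$b, n_points = 4000)
    both <- oracle_sasa_dense(list(case$a, case$b), n_points = 4000)
    area_a <- sum(alone_a$area) - sum(both$area[both$chain == 1])
    area_b <- sum(alone_b$area) - sum(both$area[both$chain == 2])
    want_iface <- max(area_a, area_b) > 250
    ifs <- suppressWarnings(detect_interfaces(model))
    expect_equal(length(ifs) == 1, want_iface,
                 info = sprintf("oracle area %.0f", max(area_a, area_b)))
  }
})

test_that("the 10% sharing rule separates overlapping from distinct sites", {
  hub_family <- function(delta) {
    hub <- helix_chain(30, "H")
    p1 <- helix_chain(24, "P", x0 = 8.6, z0 = 4)
    p2 <- helix_chain(24, "Q", x0 = 8.6 * cos(delta * pi / 180),
                      y0 = 8.6 * sin(delta * pi / 180), z0 = 4)
    fake_model(list(hub, p1, p2))
  }
  oracle_frac <- function(model) {
    hub <- model$subunits[[1]]$chain
    loss <- lapply(2:3, function(i) {
      p <- model$subunits[[i]]$chain
      alone <- oracle_sasa_dense(hub, n_points = 4000)
      pairD <- oracle_sasa_dense(list(hub, p), n_points = 4000)
      l <- alone$area - pairD$area[pairD$chain == 1]
      names(l) <- alone$seq_index
      l[l > 0.1]
    })
    common <- intersect(names(loss[[1]]), names(loss[[2]]))
    sum(pmin(loss[[1]][common], loss[[2]][common])) /
      min(sum(loss[[1]]), sum(loss[[2]]))
  }
  for (delta in c(60, 90, 120, 180)) {
    model <- hub_family(delta)
    ifs <- suppressWarnings(detect_interfaces(model))
    hub_ifs <- Filter(function(f) f$subunit_a == "S1", ifs)
    expect_length(hub_ifs, 2)
    merged <- any(vapply(hub_ifs, function(f)
      length(f$alternative_partners) > 0, logical(1)))
    expect_equal(merged, oracle_frac(model) >= 0.1,
                 info = sprintf("delta %d oracle frac %.3f", delta,
                                oracle_frac(model)))
  }
})

test_that("interface types follow template and record provenance", {
  # template-joined pairs are experimentally determined interfaces
  toy <- toy_star4c()
  pip <- shared_pipeline("star4c", toy)
  ifs <- pip$result$interfaces[[1]]
  expect_gt(length(ifs), 0)
  expect_true(all(vapply(ifs, function(f) f$type, character(1)) ==
                    "experimental"))
  # recorded but template-less contact: model-predicted
  toy_mp <- shared_toy("ring4de", fixture_spec(seed = 109, n_proteins = 4,
                                               topology = "ring",
                                               drop_entry = TRUE))
  pip_mp <- shared_pipeline("ring4de", toy_mp)
  types_mp <- vapply(pip_mp$result$interfaces[[1]], function(f)
    c(pair_key(c(f$protein_a, f$protein_b)), f$type), character(2))
  expect_true("model_predicted" %in% types_mp[2, ])
  expect_equal(types_mp[1, types_mp[2, ] == "model_predicted"],
               toy_mp$dropped_entry_pairs)
  # contact recorded nowhere: model-suggested
  toy_ms <- shared_toy("ring4ds", fixture_spec(
    seed = 110, n_proteins = 4, topology = "ring", drop_edge = TRUE))
  pip_ms <- shared_pipeline("ring4ds", toy_ms)
  types_ms <- vapply(pip_ms$result$interfaces[[1]], function(f)
    c(pair_key(c(f$protein_a, f$protein_b)), f$type), character(2))
  expect_true("model_suggested" %in% types_ms[2, ])
  expect_true(toy_ms$dropped_pairs %in%
                types_ms[1, types_ms[2, ] == "model_suggested"])
  # type labels partition all detected interfaces
  expect_true(all(types_ms[2, ] %in% c("experimental", "model_predicted",
                                       "model_suggested")))
})

test_that("recorded interactions split into direct and indirect by contact", {
  toy <- toy_complete4()
  pip <- shared_pipeline("complete4", toy)
  model <- pip$result$models[[1]]
  flags <- pip$result$indirect[[1]]
  # brute-force contact oracle: any CA pair within 8 A
  prots <- vapply(model$subunits, function(s) s$protein, character(1))
  touch <- function(pa, pb) {
    ca <- ca_coords(model$subunits[[match(pa, prots)]]$chain)
    cb <- ca_coords(model$subunits[[match(pb, prots)]]$chain)
    min(sqrt(outer(rowSums(ca^2), rowSums(cb^2), "+") -
               2 * ca %*% t(cb))) < 8
  }
  for (i in seq_len(nrow(flags))) {
    expect_equal(flags$direct[i], touch(flags$acc_a[i], flags$acc_b[i]),
                 info = paste(flags$acc_a[i], flags$acc_b[i]))
  }
  # path geometry with a complete record table: non-adjacent = indirect
  expect_true(all(flags$direct[flags$detection_method == "two hybrid"]))
  expect_false(any(flags$direct[flags$detection_method ==
                                  "coimmunoprecipitation"]))
  rates <- indirect_rate_by_method(flags)
  expect_equal(rates$indirect_rate[rates$detection_method == "two hybrid"], 0)
  expect_equal(rates$indirect_rate[
    rates$detection_method == "coimmunoprecipitation"], 1)
})

test_that("homologous interface redundancy collapses to representatives", {
  toy <- toy_path3()
  mk_iface <- function(pa, pb) {
    structure(list(subunit_a = "S1", subunit_b = "S2",
                   protein_a = pa, protein_b = pb,
                   residues_a = 1:3, residues_b = 1:3,
                   area_a = 300, area_b = 300, type = "experimental",
                   direct = TRUE, alternative_partners = character()),
              class = "ppi_interface")
  }
  proteins <- toy$proteins
  # paralogues of P01/P02 at ~0.4 identity
  proteins[["H1"]] <- protein_entry("H1", mutate_sequence(
    proteins[["P01"]]$sequence, 0.4))
  proteins[["H2"]] <- protein_entry("H2", mutate_sequence(
    proteins[["P02"]]$sequence, 0.4))
  ifs <- list(mk_iface("P01", "P02"), mk_iface("P01", "P02"),
              mk_iface("H1", "H2"), mk_iface("P01", "P03"))
  res <- collapse_homologous(ifs, proteins)
  expect_length(res$representatives, 2)
  expect_equal(res$groups[[1]], 1:3)   # copies + paralogous pair
  expect_equal(res$groups[[2]], 4L)    # unrelated pair unchanged
})

test_that("alternative-interface partners are classified by similarity", {
  toy <- toy_star4c()
  pip <- shared_pipeline("star4c", toy)
  model <- pip$result$models[[1]]
  elements <- pip$result$dataset$elements
  cls <- alternative_partner_classes(model, elements, pip$inputs$proteins)
  expect_equal(nrow(cls), 1)
  # the planted duplicate is sequence-dissimilar but the identical bundle
  # fold: same fold, not homologous
  expect_equal(cls$class, "same_fold")
  # a homologous partner pair classifies as homologous
  proteins2 <- pip$inputs$proteins
  hom_acc <- model$alternative_records[[1]]$partner_a
  proteins2[[model$alternative_records[[1]]$partner_b]] <-
    protein_entry(model$alternative_records[[1]]$partner_b,
                  mutate_sequence(proteins2[[hom_acc]]$sequence, 0.5))
  cls2 <- alternative_partner_classes(model, elements, proteins2)
  expect_equal(cls2$class, "homologous")
})
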