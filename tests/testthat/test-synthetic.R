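# Synthetic experiment generator: ground truth, calibration, layout.

test_that("the study-like preset has the expected structure", {
  spec <- paperlike_preset(n_cultures = 1, seed = 2)
  expect_identical(length(enumerate_mixtures(spec$panel)), 255L)
  plate <- simulate_plate(spec)
  # (255 mixtures + 45 control microcosms) x 4 replicates = 1200 wells
  expect_identical(length(unique(plate$well)), 1200L)
  expect_identical(nrow(plate), 1200L * 73L)
  # control wells carry the empty mixture
  ctrl <- plate[plate$mixture == 0L, ]
  expect_identical(length(unique(ctrl$well)), 180L)
})

test_that("simulation is reproducible and substreams are independent", {
  spec <- paperlike_preset(n_cultures = 1, seed = 5)
  p1 <- simulate_plate(spec)
  p2 <- simulate_plate(spec)
  expect_identical(p1, p2)
  # a different master seed changes the noise
  spec2 <- paperlike_preset(n_cultures = 1, seed = 6)
  p3 <- simulate_plate(spec2)
  expect_false(identical(p1$od, p3$od))
})

test_that("true lattice realises the planted log-linear model", {
  panel <- tiny_panel(3)
  cultures <- data.frame(culture = "c1", K = 1, r = 0.3, N0 = 0.01)

  # no planted interactions: every net interaction of the truth is 1
  spec0 <- generator_spec(panel, cultures,
                          single_effects = c(a = 0.5, b = 0.8, c = 1.2))
  tl0 <- true_lattice(spec0)
  lat0 <- exact_lattice(tl0)
  for (m in c(3L, 5L, 6L, 7L))
    expect_equal(net_interaction(lat0, m), 1, tolerance = 1e-12)

  # planted pair {a,b} = 2: emergent pair is 2, any superset emergent 1
  spec1 <- generator_spec(panel, cultures,
                          single_effects = c(a = 0.5, b = 0.8, c = 1.2),
                          interaction_terms = list("a;b" = 2))
  lat1 <- exact_lattice(true_lattice(spec1))
  expect_equal(emergent_interaction(lat1, 3L), 2, tolerance = 1e-12)
  expect_equal(exp(mobius_log_interaction(lat1, 7L)), 1, tolerance = 1e-12)

  # interaction planted on the full set only: partial residuals of the
  # full mixture stay at the planted value for every order below n
  panel4 <- tiny_panel(4)
  spec2 <- generator_spec(panel4,
                          cultures,
                          single_effects = c(a = 0.9, b = 0.9, c = 0.9, d = 0.9),
                          interaction_terms = list("a;b;c;d" = 0.5))
  lat2 <- exact_lattice(true_lattice(spec2))
  for (m0 in 1:3)
    expect_equal(partial_null_residual(lat2, 15L, m0), 0.5, tolerance = 1e-10)
  expect_equal(emergent_interaction(lat2, 15L), 0.5, tolerance = 1e-10)
  for (m in c(7L, 11L, 13L, 14L))
    expect_equal(emergent_interaction(lat2, m), 1, tolerance = 1e-10)
})

test_that("noiseless curves reproduce planted G within calibration tolerance", {
  panel <- tiny_panel(2)
  spec <- generator_spec(panel,
                         data.frame(culture = "c1", K = 1.2, r = 0.35, N0 = 0.02),
                         single_effects = c(a = 0.4, b = 1.3),
                         interaction_terms = list("a;b" = 1.7),
                         n_replicates = 2L, n_controls = 2L,
                         noise_sd = 0, seed = 1L)
  aucs <- plate_auc(simulate_plate(spec))
  lat <- response_lattice(aucs, "c1")
  truth <- true_lattice(spec)
  expect_lt(max(abs(lat$g[names(truth)] / truth - 1)), 1e-3)
})

test_that("unreachable planted growth targets are refused", {
  panel <- tiny_panel(1)
  spec <- generator_spec(panel,
                         data.frame(culture = "c1", K = 0.5, r = 0.3, N0 = 0.05),
                         single_effects = c(a = 1e-6),
                         n_replicates = 2L, n_controls = 2L, noise_sd = 0)
  expect_error(simulate_plate(spec), class = "stressmix_unreachable")
})

test_that("generator specs are validated", {
  panel <- tiny_panel(2)
  cultures <- data.frame(culture = "c1", K = 1, r = 0.3, N0 = 0.01)
  expect_error(generator_spec(panel, cultures, c(a = 0.5, b = -1)),
               class = "stressmix_domain")
  expect_error(generator_spec(panel, cultures, c(a = 0.5, b = 1),
                              interaction_terms = list("a" = 2)),
               class = "stressmix_argument")
  expect_error(generator_spec(panel,
                              data.frame(culture = "c1", K = 0.005, r = 0.3,
                                         N0 = 0.01),
                              c(a = 0.5, b = 1)),
               class = "stressmix_argument")
})

test_that("Brownian trait simulation respects seed and lambda", {
  set.seed(3)
  tree <- ape::rcoal(16)
  x1 <- simulate_bm_traits(tree, 1, 1, seed = 9)
  x2 <- simulate_bm_traits(tree, 1, 1, seed = 9)
  expect_identical(x1, x2)
  expect_identical(names(x1), rownames(ape::vcv(tree)))
  x3 <- simulate_bm_traits(tree, 1, 0, seed = 9)
  expect_false(identical(x1, x3))
  expect_error(simulate_bm_traits(tree, -1, 1), class = "stressmix_domain")
  expect_error(simulate_bm_traits(tree, 1, 2), class = "stressmix_argument")
})

test_that("the preset drives an antibiotic-split bimodal response", {
  spec <- paperlike_preset(n_cultures = 1, seed = 31)
  aucs <- plate_auc(simulate_plate(spec))
  lat <- response_lattice(aucs, "strain_01")
  masks <- as.integer(names(lat$g))
  with_ab <- bitwAnd(masks, 1L) == 1L  # the antibiotic is chemical 1
  gap <- mean(lat$g[!with_ab]) - mean(lat$g[with_ab])
  expect_gt(gap, 0.3)
  # and the complexity regression picks up the antibiotic indicator
  resp <- data.frame(culture = "strain_01", mixture = masks,
                     complexity = mixture_size(masks), g = unname(lat$g))
  reg <- complexity_regression(resp, "oxytetracycline", spec$panel)
  expect_lt(reg$focal_coefficient, -0.3)
})
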