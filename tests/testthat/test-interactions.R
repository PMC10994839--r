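# Interaction coefficients on the subset lattice.

test_that("the multiplicative null is the product of single effects", {
  # two chemicals each leaving 30% of control growth predict 9% growth,
  # i.e. a 91% reduction
  expect_equal(combine_null(c(0.3, 0.3)), 0.09, tolerance = 1e-12)
  expect_equal(combine_null(c(1, 1, 1)), 1)
  expect_equal(combine_null(c(0.5, 2.0)), 1)
  expect_error(combine_null(c(0.5, 0)), class = "stressmix_domain")
  expect_error(combine_null(c(0.5, -1)), class = "stressmix_domain")
})

test_that("net interaction is G over the singleton product", {
  # exactly multiplicative lattice: all net interactions are 1
  lat <- planted_lattice(c(a = 0.6, b = 0.8, c = 1.2))
  for (m in c(3L, 5L, 6L, 7L))
    expect_equal(net_interaction(lat, m), 1, tolerance = 1e-12)

  # direct substitution: G_ab = 0.5 over 0.5 * 0.5 = 2
  g <- stats::setNames(c(0.5, 0.5, 0.5), c("1", "2", "3"))
  lat2 <- exact_lattice(g)
  expect_equal(net_interaction(lat2, 3L), 2, tolerance = 1e-12)
  expect_equal(exp(mobius_log_interaction(lat2, 3L)), 2, tolerance = 1e-12)

  expect_error(net_interaction(lat, 1L), class = "stressmix_argument")
  # missing singleton is reported by its encoding
  lat3 <- exact_lattice(stats::setNames(c(0.5, 0.25), c("1", "3")))
  expect_error(net_interaction(lat3, 3L), "2",
               class = "stressmix_incomplete_lattice")
})

test_that("emergent equals net on pairs and strips planted lower orders", {
  lat <- planted_lattice(c(a = 0.5, b = 0.7, c = 0.9, d = 1.1),
                         iota = c("3" = 2.0))  # pair {a,b}
  # pairs: net and emergent identical by construction
  for (m in c(3L, 5L, 9L, 6L))
    expect_identical(emergent_interaction(lat, m), net_interaction(lat, m))
  expect_equal(emergent_interaction(lat, 3L), 2.0, tolerance = 1e-10)
  # any superset of the planted pair has emergent exactly 1 (noiseless)
  for (m in c(7L, 11L, 15L))
    expect_equal(log(emergent_interaction(lat, m)), 0, tolerance = 1e-10)
})

test_that("iterative emergent interaction matches the Moebius oracle", {
  for (s in 1:30) {
    n <- sample(2:6, 1)
    lat <- random_lattice(n, seed = s)
    full <- 2L^n - 1L
    masks <- enumerate_mixtures(tiny_panel(n))
    for (m in masks[mixture_size(masks) >= 2]) {
      expect_equal(log(emergent_interaction(lat, m)),
                   mobius_log_interaction(lat, m), tolerance = 1e-10)
    }
  }
})

test_that("interaction coefficients telescope back to observed growth", {
  lat <- random_lattice(5, seed = 99)
  masks <- enumerate_mixtures(tiny_panel(5))
  for (m in masks[mixture_size(masks) >= 2]) {
    singles <- masks[mixture_size(masks) == 1 & bitwAnd(masks, m) == masks]
    subs <- masks[bitwAnd(masks, m) == masks & mixture_size(masks) >= 2]
    recon <- sum(log(lat$g[as.character(singles)])) +
      sum(vapply(subs, function(s) log(emergent_interaction(lat, s)),
                 numeric(1)))
    expect_equal(recon, log(lat$g[[as.character(m)]]), tolerance = 1e-10)
  }
})

test_that("interaction values are invariant to chemical relabelling", {
  # permute panel indices: mixture {1,2} becomes {2,3} etc.; values of
  # corresponding subsets must be identical
  lat <- random_lattice(4, seed = 12)
  perm <- c(3L, 1L, 4L, 2L)  # old index -> new index
  remap <- function(mask) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:3)) != 0)
    sum(bitwShiftL(1L, perm[members] - 1L))
  }
  g2 <- lat$g
  names(g2) <- as.character(vapply(as.integer(names(lat$g)), remap, integer(1)))
  lat2 <- exact_lattice(g2)
  for (m in as.integer(names(lat$g))[mixture_size(as.integer(names(lat$g))) >= 2]) {
    expect_equal(emergent_interaction(lat, m),
                 emergent_interaction(lat2, remap(m)), tolerance = 1e-12)
    expect_equal(net_interaction(lat, m),
                 net_interaction(lat2, remap(m)), tolerance = 1e-12)
  }
})

test_that("partial-order residuals interpolate between net and emergent", {
  lat <- random_lattice(5, seed = 5)
  full <- 31L
  expect_equal(partial_null_residual(lat, full, 1),
               net_interaction(lat, full), tolerance = 1e-12)
  expect_equal(partial_null_residual(lat, full, 4),
               emergent_interaction(lat, full), tolerance = 1e-10)
  expect_error(partial_null_residual(lat, full, 5),
               class = "stressmix_argument")
  expect_error(partial_null_residual(lat, full, 0),
               class = "stressmix_argument")

  # pairwise-only planted lattice: a 4-chemical mixture is fully
  # explained once pairwise terms are in the null
  lat2 <- planted_lattice(c(a = 0.6, b = 0.8, c = 0.9, d = 1.1),
                          iota = c("3" = 1.8, "12" = 0.7))
  expect_false(isTRUE(all.equal(partial_null_residual(lat2, 15L, 1), 1)))
  expect_equal(partial_null_residual(lat2, 15L, 2), 1, tolerance = 1e-10)
  expect_equal(partial_null_residual(lat2, 15L, 3), 1, tolerance = 1e-10)
})

test_that("bootstrap weights reproduce the direct computations", {
  lat <- random_lattice(5, seed = 31)
  logg <- log(lat$g)
  for (m in c(7L, 21L, 31L)) {
    for (kind in c("net", "emergent")) {
      w <- stressmix:::.interaction_weights(m, kind)
      direct <- switch(kind, net = net_interaction(lat, m),
                       emergent = emergent_interaction(lat, m))
      expect_equal(sum(w * logg[names(w)]), log(direct), tolerance = 1e-10)
    }
    for (m0 in seq_len(mixture_size(m) - 1)) {
      w <- stressmix:::.interaction_weights(m, "partial", m0)
      expect_equal(sum(w * logg[names(w)]),
                   log(partial_null_residual(lat, m, m0)), tolerance = 1e-10)
    }
  }
})

test_that("classification is direction-aware and gated", {
  # harmful null, ratio above 1: dampened effect -> antagonistic
  expect_identical(classify_interaction(1.2, 1.5, 0.5, TRUE), "antagonistic")
  # harmful null, ratio below 1: amplified effect -> synergistic
  expect_identical(classify_interaction(0.5, 0.8, 0.5, TRUE), "synergistic")
  # beneficial null flips the mapping
  expect_identical(classify_interaction(1.2, 1.5, 1.4, TRUE), "synergistic")
  expect_identical(classify_interaction(0.5, 0.8, 1.4, TRUE), "antagonistic")
  # CI containing 1: multiplicative
  expect_identical(classify_interaction(0.9, 1.1, 0.5, TRUE), "multiplicative")
  # failed gate dominates everything
  expect_identical(classify_interaction(1.2, 1.5, 0.5, FALSE), "no_response")
  expect_error(classify_interaction(1.5, 1.2, 0.5, TRUE),
               class = "stressmix_argument")
  expect_error(classify_interaction(1.2, 1.5, 0, TRUE),
               class = "stressmix_domain")
  # null exactly 1 edge case is logged and classified by amplification
  expect_message(out <- classify_interaction(1.2, 1.5, 1, TRUE))
  expect_identical(out, "synergistic")
})
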