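# Result-level aggregations.

test_that("sign table proportions behave at the extremes", {
  panel <- tiny_panel(3)
  masks <- enumerate_mixtures(panel)

  all_neg <- make_responses(masks, g = rep(0.5, 7), significant = rep(TRUE, 7))
  st <- response_sign_table(all_neg)
  expect_true(all(st$table$negative == 1))
  expect_true(all(abs(st$table$negative + st$table$positive +
                        st$table$none - 1) < 1e-12))

  none_sig <- make_responses(masks, g = rep(0.5, 7), significant = rep(FALSE, 7))
  st0 <- response_sign_table(none_sig)
  expect_equal(st0$trend$slope, 0)
  expect_error(response_sign_table(all_neg[0, ]), class = "stressmix_argument")
})

test_that("one harmful chemical gives negative proportion k/8 at complexity k", {
  panel <- tiny_panel(8)
  masks <- enumerate_mixtures(panel)
  has1 <- bitwAnd(masks, 1L) == 1L  # contains chemical 1
  resp <- make_responses(masks, g = ifelse(has1, 0.4, 1),
                         significant = has1)
  st <- response_sign_table(resp)
  # fraction of size-k subsets of 8 containing a fixed element is k/8
  expect_equal(st$table$negative, st$table$complexity / 8, tolerance = 1e-12)
})

test_that("complexity regression is exact on noiseless linear data", {
  panel <- tiny_panel(8)
  masks <- enumerate_mixtures(panel)
  k <- mixture_size(masks)
  focal <- as.integer(bitwAnd(masks, 1L) == 1L)
  g <- 1.0 - 0.03 * k - 0.42 * focal
  resp <- make_responses(masks, g = g, significant = rep(TRUE, 255))
  reg <- complexity_regression(resp, 1L)
  expect_equal(reg$intercept, 1.0, tolerance = 1e-10)
  expect_equal(reg$slope, -0.03, tolerance = 1e-10)
  expect_equal(reg$focal_coefficient, -0.42, tolerance = 1e-10)
  expect_gt(reg$r2, 0.999999)

  # constant G degenerates gracefully
  flat <- make_responses(masks, g = rep(1, 255), significant = rep(FALSE, 255))
  reg0 <- complexity_regression(flat, 1L)
  expect_equal(reg0$slope, 0, tolerance = 1e-12)
  expect_equal(reg0$focal_coefficient, 0, tolerance = 1e-12)
  expect_identical(reg0$r2, 0)
  expect_true(reg0$degenerate)

  expect_error(complexity_regression(resp, 99L), class = "stressmix_argument")
})

test_that("persistence lattice edges follow the one-level subset rule", {
  panel <- tiny_panel(4)
  masks <- enumerate_mixtures(panel)
  base <- data.frame(culture = "cx", mixture = masks,
                     complexity = mixture_size(masks), kind = "net",
                     estimate = 1, ci_low = 1, ci_high = 1,
                     null_prediction = 0.5,
                     category = "multiplicative", stringsAsFactors = FALSE)

  # no significant interactions: no edges
  lat0 <- build_interaction_lattice(base)
  expect_identical(nrow(lat0$edges), 0L)

  # planted persistent antagonism: pair {1,2} and all its supersets
  persist <- base
  keep <- bitwAnd(masks, 3L) == 3L & mixture_size(masks) >= 2
  persist$category[keep] <- "antagonistic"
  lat1 <- build_interaction_lattice(persist)
  # brute-force count of one-level subset pairs among significant nodes
  sig <- masks[keep]
  expected <- sum(outer(sig, sig, function(a, b)
    mixture_size(b) == mixture_size(a) + 1L & bitwAnd(a, b) == a))
  expect_identical(nrow(lat1$edges), as.integer(expected))
  # every edge is a Hasse edge of the Boolean lattice
  expect_true(all(mixture_size(lat1$edges$super) ==
                    mixture_size(lat1$edges$sub) + 1L))
  expect_true(all(bitwAnd(lat1$edges$sub, lat1$edges$super) == lat1$edges$sub))

  # significant nodes two levels apart with nothing between: no edges
  gap <- base
  gap$category[gap$mixture %in% c(3L, 15L)] <- "synergistic"
  expect_identical(nrow(build_interaction_lattice(gap)$edges), 0L)

  expect_error(build_interaction_lattice(rbind(base, base)),
               class = "stressmix_argument")
})

test_that("emergent consistency counts shared interaction types", {
  panel <- tiny_panel(3)
  m3 <- 7L  # the only size-3 mixture
  rows <- function(culture, category)
    data.frame(culture = culture, mixture = m3, complexity = 3L,
               kind = "emergent", estimate = 2, ci_low = 1.5, ci_high = 2.5,
               null_prediction = 0.4, category = category,
               stringsAsFactors = FALSE)
  # all cultures agree
  agree <- rbind(rows("a", "antagonistic"), rows("b", "antagonistic"))
  expect_equal(emergent_consistency(agree)$proportion, 1)
  # disagreement: the single qualifying mixture is inconsistent
  clash <- rbind(rows("a", "antagonistic"), rows("b", "synergistic"))
  expect_equal(emergent_consistency(clash)$proportion, 0)
  # a lone culture does not qualify
  lone <- rows("a", "antagonistic")
  out <- emergent_consistency(lone)
  expect_identical(out$n_qualifying, 0L)
  expect_true(is.na(out$proportion))
})

test_that("terms-required counts drop to zero once planted order is reached", {
  # pairwise-only planted lattice, noiseless replicate pools: the
  # bootstrap CIs are degenerate so significance is exact
  lat <- planted_lattice(c(a = 0.6, b = 0.7, c = 0.8, d = 0.9),
                         iota = c("3" = 1.6, "12" = 0.6))
  aucs <- aucs_from_lattice(lat)
  fit <- stressmix(aucs, panel = tiny_panel(4), kind = "net",
                   boot = bootstrap_settings(n_reps = 200, seed = 3))
  tab <- terms_required_table(fit, max_orders = 2:3)
  # three- and four-chemical mixtures containing a planted pair show a
  # net interaction, but adding pairwise terms explains everything
  expect_true(all(tab$net > 0))
  expect_true(all(tab$order_2 == 0, na.rm = TRUE))
  expect_true(all(tab$order_3 == 0, na.rm = TRUE))
  # counts non-increasing in order
  expect_true(all(tab$order_2 <= tab$net))
})

test_that("shared planted emergent interactions are consistent across cultures", {
  panel <- tiny_panel(6)
  cultures <- data.frame(culture = c("s1", "s2"), K = c(1.0, 1.2),
                         r = c(0.3, 0.35), N0 = 0.01)
  eff <- matrix(rep(seq(0.8, 0.9, length.out = 6), each = 2), 2,
                dimnames = list(cultures$culture, letters[1:6]))
  spec <- generator_spec(panel, cultures, eff,
                         interaction_terms = list("a;b;c" = 2.0,
                                                  "b;d;e" = 0.5,
                                                  "a;c;e;f" = 2.0),
                         n_replicates = 4L, n_controls = 12L,
                         times = 0:72, noise_sd = 0.01, seed = 5L)
  fit <- stressmix(plate_auc(simulate_plate(spec)), panel, kind = "emergent",
                   boot = bootstrap_settings(n_reps = 300, seed = 5L))
  cons <- emergent_consistency(fit$interactions)
  expect_gte(cons$n_qualifying, 3L)
  expect_gte(cons$proportion, 0.8)
})
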