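# Synthetic plate-experiment generator with planted ground truth.
#
# True relative growth is defined on the AUC-ratio scale, the same
# scale the analysis estimates: for mixture A,
#   log G_A = sum_{a in A} log g_a + sum_{planted k subset A} log iota_k.
# Each well's logistic growth curve is calibrated so that its
# noiseless AUC ratio to control equals the planted G: carrying
# capacity and rate are both multiplied by G^theta, with theta solved
# by a one-dimensional root find (planting effects on K or r alone
# would make true G depend on the integration window).

#' Construct a synthetic experiment specification
#'
#' @param panel a [chemical_panel()].
#' @param cultures data.frame with columns `culture, K, r, N0`:
#'   logistic carrying capacity (OD), growth rate (per hour) and
#'   inoculum (OD) for each synthetic culture under control conditions.
#' @param single_effects true per-chemical relative growths: either a
#'   named vector over panel chemicals (shared by all cultures) or a
#'   matrix with one row per culture (rownames = culture ids) and one
#'   column per panel chemical.
#' @param interaction_terms named list of planted interaction
#'   coefficients shared by all cultures; names are semicolon-joined
#'   chemical sets (size >= 2), values positive ratios.
#' @param n_replicates treatment replicates per mixture (default 4).
#' @param n_controls number of no-chemical control microcosms, each
#'   also replicated `n_replicates` times (default 45, giving
#'   (2^8 - 1) * 4 + 45 * 4 = 1200 wells per culture on an 8-panel).
#' @param times hourly sampling grid (default 0..72 h).
#' @param noise_sd additive Gaussian OD noise, truncated at 0.
#' @param noise_type `"additive"` (default) or `"multiplicative"`
#'   (lognormal factor with that log-sd).
#' @param seed master seed; per-well substreams are derived from it.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(panel, cultures, single_effects,
                           interaction_terms = list(),
                           n_replicates = 4L, n_controls = 45L,
                           times = 0:72, noise_sd = 0.01,
                           noise_type = c("additive", "multiplicative"),
                           seed = 1L) {
  stopifnot(inherits(panel, "chemical_panel"))
  noise_type <- match.arg(noise_type)
  if (!all(c("culture", "K", "r", "N0") %in% names(cultures)))
    .stop_class("stressmix_argument", "cultures needs columns culture, K, r, N0")
  if (any(cultures$K <= cultures$N0) || any(cultures$N0 <= 0) ||
      any(cultures$r <= 0))
    .stop_class("stressmix_argument",
                "growth parameters must satisfy K > N0 > 0, r > 0")
  chem <- unclass(panel)
  if (is.matrix(single_effects) || is.data.frame(single_effects)) {
    single_effects <- as.matrix(single_effects)
  } else {
    single_effects <- matrix(rep(single_effects[chem], each = nrow(cultures)),
                             nrow = nrow(cultures),
                             dimnames = list(cultures$culture, chem))
  }
  if (!all(chem %in% colnames(single_effects)) ||
      !all(cultures$culture %in% rownames(single_effects)))
    .stop_class("stressmix_argument",
                "single_effects must cover every culture and panel chemical")
  if (any(single_effects <= 0))
    .stop_class("stressmix_domain", "single effects must be positive")
  iota <- numeric(0)
  if (length(interaction_terms) > 0L) {
    masks <- vapply(strsplit(names(interaction_terms), ";", fixed = TRUE),
                    function(ch) mixture(trimws(ch), panel), integer(1))
    if (any(mixture_size(masks) < 2L))
      .stop_class("stressmix_argument", "interaction terms need >= 2 chemicals")
    iota <- stats::setNames(as.numeric(interaction_terms), as.character(masks))
    if (any(iota <= 0))
      .stop_class("stressmix_domain", "interaction coefficients must be positive")
  }
  structure(list(panel = panel, cultures = cultures,
                 single_effects = single_effects[cultures$culture, chem,
                                                 drop = FALSE],
                 interaction_terms = iota,
                 n_replicates = as.integer(n_replicates),
                 n_controls = as.integer(n_controls),
                 times = as.numeric(times),
                 noise_sd = noise_sd, noise_type = noise_type,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  n <- attr(x$panel, "size")
  cat(sprintf("Synthetic experiment: %d chemicals, %d culture(s), %d mixtures\n",
              n, nrow(x$cultures), 2^n - 1))
  cat(sprintf("  %d replicates, %d control microcosms, %d time points, noise sd %g\n",
              x$n_replicates, x$n_controls, length(x$times), x$noise_sd))
  if (length(x$interaction_terms))
    cat(sprintf("  %d planted interaction term(s)\n", length(x$interaction_terms)))
  invisible(x)
}

#' True relative-growth lattice of a synthetic specification
#'
#' Evaluates the planted log-linear model over all non-empty mixtures:
#' the noiseless ground truth against which estimates are validated.
#' By construction, emergent interactions computed on this lattice
#' recover exactly the planted coefficients (and 1 where none were
#' planted).
#'
#' @param spec a [generator_spec()].
#' @param culture culture id (default: first culture).
#' @return named numeric vector of true G, names = mixture encodings.
#' @export
true_lattice <- function(spec, culture = spec$cultures$culture[1]) {
  stopifnot(inherits(spec, "generator_spec"))
  masks <- enumerate_mixtures(spec$panel)
  log_single <- log(spec$single_effects[culture, ])
  iota_masks <- as.integer(names(spec$interaction_terms))
  log_g <- vapply(masks, function(m) {
    lg <- sum(log_single[.mask_members(m)])
    if (length(iota_masks)) {
      inside <- bitwAnd(iota_masks, m) == iota_masks
      lg <- lg + sum(log(spec$interaction_terms[inside]))
    }
    lg
  }, numeric(1))
  stats::setNames(exp(log_g), as.character(masks))
}

# ---- logistic AUC and calibration -----------------------------------------

# Closed-form AUC of the logistic curve K / (1 + C exp(-r t)) on [0, T],
# C = (K - N0)/N0, written to avoid exp overflow.
.logistic_auc <- function(K, r, N0, T) {
  C <- (K - N0) / N0
  (K / r) * (r * T + log1p(C * exp(-r * T)) - log1p(C))
}

.logistic_od <- function(K, r, N0, t) {
  C <- (K - N0) / N0
  K / (1 + C * exp(-r * t))
}

# Solve theta such that AUC(K G^theta, r G^theta) = G * AUC(K, r):
# both carrying capacity and rate are scaled by the same factor.
.calibrate_theta <- function(K, r, N0, T, G) {
  if (abs(G - 1) < 1e-12) return(0)
  auc0 <- .logistic_auc(K, r, N0, T)
  f <- function(th) .logistic_auc(K * G^th, r * G^th, N0, T) - G * auc0
  if (G < 1) {
    # K G^theta must stay above the inoculum for a growing culture
    th_max <- log(1.05 * N0 / K) / log(G)
    if (f(th_max) > 0)
      .stop_class("stressmix_unreachable",
                  "target relative growth %g unreachable for K=%g, N0=%g",
                  G, K, N0)
    stats::uniroot(f, c(0, th_max), tol = 1e-12)$root
  } else {
    hi <- 1
    while (f(hi) < 0 && hi < 64) hi <- hi * 2
    if (f(hi) < 0)
      .stop_class("stressmix_unreachable",
                  "target relative growth %g unreachable", G)
    stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  }
}

#' Simulate a complete synthetic plate experiment
#'
#' Every culture x mixture x replicate gets a logistic growth curve
#' calibrated so the noiseless AUC ratio to control equals the planted
#' true G (within the calibration tolerance of the root find), plus
#' per-well noise drawn from an independent, reproducible substream of
#' the master seed.
#'
#' @param spec a [generator_spec()].
#' @param cultures optional subset of cultures to simulate.
#' @return a `plate_table` (see [read_plate_table()]) with the panel
#'   attached.
#' @export
simulate_plate <- function(spec, cultures = spec$cultures$culture) {
  stopifnot(inherits(spec, "generator_spec"))
  times <- spec$times
  nt <- length(times)
  out <- vector("list", 0L)
  for (ci in seq_len(nrow(spec$cultures))) {
    cc <- spec$cultures$culture[ci]
    if (!(cc %in% cultures)) next
    K <- spec$cultures$K[ci]; r <- spec$cultures$r[ci]
    N0 <- spec$cultures$N0[ci]
    truth <- true_lattice(spec, cc)
    masks <- as.integer(names(truth))
    # distinct targets share one calibration solve
    theta_cache <- new.env(parent = emptyenv())
    theta_of <- function(G) {
      key <- sprintf("%.12g", G)
      if (is.null(theta_cache[[key]]))
        theta_cache[[key]] <- .calibrate_theta(K, r, N0, max(times), G)
      theta_cache[[key]]
    }
    rows <- vector("list", length(masks) * spec$n_replicates +
                     spec$n_controls * spec$n_replicates)
    k <- 0L
    emit <- function(mask, rep_id, G) {
      th <- theta_of(G)
      y <- .logistic_od(K * G^th, r * G^th, N0, times)
      od <- with_seed(substream_seed(spec$seed, cc, mask, rep_id), {
        if (spec$noise_sd <= 0) y
        else if (spec$noise_type == "additive")
          pmax(y + stats::rnorm(nt, 0, spec$noise_sd), 0)
        else y * exp(stats::rnorm(nt, 0, spec$noise_sd))
      })
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        culture = cc, well = sprintf("%s.m%d.r%d", cc, mask, rep_id),
        mixture = mask, replicate = rep_id, time_h = times, od = od,
        stringsAsFactors = FALSE)
    }
    for (m in masks)
      for (rp in seq_len(spec$n_replicates)) emit(m, rp, truth[[as.character(m)]])
    for (rp in seq_len(spec$n_controls * spec$n_replicates)) emit(0L, rp, 1)
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  plate <- do.call(rbind, out)
  rownames(plate) <- NULL
  structure(plate, panel = spec$panel, excluded = character(0),
            class = c("plate_table", "data.frame"))
}

#' Study-like synthetic preset
#'
#' Eight chemicals named after common freshwater pollutant classes,
#' one strongly growth-inhibiting antibiotic (relative growth around
#' 0.3, which drives a bimodal response distribution split on its
#' presence), mild effects for the rest, a planted pairwise antagonism
#' between the antibiotic and a fungicide, and cultures with varied
#' susceptibility.  Defaults match the emulated design: 255 mixtures,
#' 4 replicates, 45 control microcosms, hourly readings over 72 h.
#'
#' @param n_cultures number of synthetic cultures (default 12).
#' @param noise_sd additive OD noise (default 0.01, a realistic
#'   plate-reader scale).
#' @param seed master seed.
#' @return a [generator_spec()].
#' @export
paperlike_preset <- function(n_cultures = 12L, noise_sd = 0.01, seed = 1L) {
  panel <- chemical_panel(c("oxytetracycline", "amoxicillin",
                            "chlorothalonil", "tebuconazole",
                            "glyphosate", "diflufenican",
                            "metaldehyde", "imidacloprid"))
  i <- seq_len(n_cultures)
  cultures <- data.frame(
    culture = sprintf("strain_%02d", i),
    K = 0.9 + 0.05 * ((i - 1) %% 7),
    r = 0.22 + 0.03 * ((i - 1) %% 5),
    N0 = 0.01)
  # per-culture susceptibility: the antibiotic is always severe
  # (g near 0.3); the others are mild and vary deterministically
  base <- c(oxytetracycline = 0.30, amoxicillin = 0.92,
            chlorothalonil = 0.95, tebuconazole = 0.85,
            glyphosate = 0.98, diflufenican = 1.02,
            metaldehyde = 0.97, imidacloprid = 0.94)
  wiggle <- outer(sin(i), seq_len(8)) # deterministic, culture-specific
  eff <- matrix(rep(base, each = n_cultures), n_cultures, 8,
                dimnames = list(cultures$culture, names(base)))
  eff <- eff * (1 + 0.05 * sin(wiggle))
  eff[, "oxytetracycline"] <- 0.24 + 0.12 * (i - 1) / max(1, n_cultures - 1)
  generator_spec(panel, cultures, eff,
                 interaction_terms = list("oxytetracycline;tebuconazole" = 2.0),
                 n_replicates = 4L, n_controls = 45L, times = 0:72,
                 noise_sd = noise_sd, seed = seed)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws tip values from a multivariate normal whose covariance is the
#' lambda-scaled Brownian tree covariance: ground truth for the
#' phylogenetic-signal recovery tests.
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda_true signal strength in [0, 1]; 0 = independent tips,
#'   1 = plain Brownian motion.
#' @param seed integer seed.
#' @return named numeric vector of tip traits.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda_true = 1, seed = 1L) {
  if (sigma2 <= 0)
    .stop_class("stressmix_domain", "sigma2 must be positive")
  if (lambda_true < 0 || lambda_true > 1)
    .stop_class("stressmix_argument", "lambda_true must be in [0, 1]")
  C <- sigma2 * .lambda_vcv(ape::vcv(tree), lambda_true)
  ch <- chol(C)
  x <- with_seed(seed, drop(crossprod(ch, stats::rnorm(nrow(C)))))
  stats::setNames(x, rownames(C))
}
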