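# Shared fixtures: all synthetic, built in code at test time.

tiny_panel <- function(n) chemical_panel(letters[seq_len(n)])

# A response lattice with exact (noiseless) replicate pools: every
# mixture's G is given directly and each replicate AUC equals
# G * control mean, so bootstrap CIs are degenerate at the point value.
exact_lattice <- function(g_by_mask, culture = "cx", n_reps = 4,
                          control_auc = 50, n_controls = 6) {
  controls <- rep(control_auc, n_controls)
  reps <- lapply(g_by_mask, function(g) rep(g * control_auc, n_reps))
  names(reps) <- names(g_by_mask)
  structure(list(culture = culture, g = g_by_mask, reps = reps,
                 controls = controls, g_floor = 1e-4,
                 floored = character(0)),
            class = "response_lattice")
}

# Random log-G lattice over all non-empty subsets of an n-chemical panel.
random_lattice <- function(n, seed, sd = 0.5) {
  panel <- tiny_panel(n)
  masks <- enumerate_mixtures(panel)
  set.seed(seed)
  g <- stats::setNames(exp(stats::rnorm(length(masks), 0, sd)),
                       as.character(masks))
  exact_lattice(g)
}

# Lattice generated from a planted log-linear model: singleton effects
# plus interaction coefficients on chosen subsets.
planted_lattice <- function(singles, iota = numeric(0)) {
  n <- length(singles)
  panel <- tiny_panel(n)
  masks <- enumerate_mixtures(panel)
  log_g <- vapply(masks, function(m) {
    lg <- sum(log(singles[which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0)]))
    if (length(iota)) {
      im <- as.integer(names(iota))
      lg <- lg + sum(log(iota[bitwAnd(im, m) == im]))
    }
    lg
  }, numeric(1))
  exact_lattice(stats::setNames(exp(log_g), as.character(masks)))
}

# Small AUC table (one culture) built directly from a lattice, with
# optional multiplicative replicate noise.
aucs_from_lattice <- function(lat, noise_cv = 0, seed = 1) {
  set.seed(seed)
  rows <- list(data.frame(culture = lat$culture, mixture = 0L,
                          replicate = seq_along(lat$controls),
                          auc = lat$controls))
  for (key in names(lat$reps)) {
    v <- lat$reps[[key]]
    if (noise_cv > 0) v <- v * exp(stats::rnorm(length(v), 0, noise_cv))
    rows[[length(rows) + 1L]] <- data.frame(culture = lat$culture,
                                            mixture = as.integer(key),
                                            replicate = seq_along(v),
                                            auc = v)
  }
  do.call(rbind, rows)
}

# Gated-response data.frame builder for summaries tests.
make_responses <- function(masks, g, significant, culture = "cx") {
  data.frame(culture = culture, mixture = as.integer(masks),
             complexity = mixture_size(masks), g = g,
             ci_low = ifelse(significant, g * 0.99, pmin(g, 1) * 0.99),
             ci_high = ifelse(significant, g * 1.01, pmax(g, 1) * 1.01),
             significant = significant,
             direction = ifelse(!significant, "none",
                                ifelse(g < 1, "negative", "positive")),
             stringsAsFactors = FALSE)
}
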