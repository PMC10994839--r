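# Two-stage bootstrap significance machinery.
#
# Stage 1 (the gate): does the mixture change growth at all?  Treatment
# and control AUC replicate pools are resampled with replacement, G is
# recomputed each time, and a percentile CI is formed; a CI containing
# 1 means "no response" and the mixture is not tested further.
#
# Stage 2: for gated mixtures, every replicate pool entering the
# interaction formula is resampled per bootstrap replicate, all
# lower-order coefficients are recomputed from the resampled data, and
# the target coefficient's percentile CI decides significance.  The
# shared control pool is resampled once per replicate and reused in
# every G term of that replicate, because all G values divide by the
# same control mean.

#' Bootstrap settings
#'
#' @param n_reps number of bootstrap replicates (default 10,000; at
#'   least 100 for any CI claim).
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @param seed master integer seed; per-(culture, mixture) substreams
#'   are derived from it by hashing, so adding one mixture never
#'   perturbs another's CI.
#' @return object of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(n_reps = 10000L, ci_level = 0.95, seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 100L)
    .stop_class("stressmix_argument", "n_reps must be >= 100 (got %d)", n_reps)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    .stop_class("stressmix_argument", "ci_level must be in (0, 1)")
  structure(list(n_reps = n_reps, ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "bootstrap_settings")
}

# Resampled means of a replicate pool: B columns of means of n draws.
.resample_means <- function(values, B) {
  n <- length(values)
  .colMeans(values[sample.int(n, n * B, replace = TRUE)], n, B)
}

# Does a ratio CI exclude 1?  A relative tolerance absorbs floating-
# point dust: on noiseless (degenerate) replicate pools a coefficient
# that is mathematically 1 can compute to 1 +/- a few ulps, which must
# not count as a significant interaction.
.excludes_one <- function(lo, hi, tol = 1e-9) lo > 1 + tol || hi < 1 - tol

# Control-pool resampled means with redraw-on-zero (a resample whose
# mean AUC is zero would make every G of that replicate undefined).
.control_means <- function(controls, B) {
  m <- .resample_means(controls, B)
  redraws <- 0L
  while (any(m <= 0)) {
    bad <- which(m <= 0)
    redraws <- redraws + length(bad)
    m[bad] <- .resample_means(controls, length(bad))
  }
  if (redraws > 0.01 * B)
    warning(sprintf("%d/%d control resamples redrawn for zero mean AUC",
                    redraws, B))
  m
}

#' Bootstrap test of a mixture's growth response (the gate)
#'
#' @param treatment_aucs,control_aucs replicate AUC pools (>= 2 each).
#' @param settings a [bootstrap_settings()].
#' @param seed optional substream seed; defaults to `settings$seed`.
#' @return list of class `g_test`: `g_point`, `ci_low`, `ci_high`,
#'   `significant` (CI excludes 1) and `n_reps`.
#' @export
bootstrap_g <- function(treatment_aucs, control_aucs, settings,
                        seed = settings$seed) {
  stopifnot(inherits(settings, "bootstrap_settings"))
  if (length(treatment_aucs) < 2L || length(control_aucs) < 2L)
    .stop_class("stressmix_insufficient_data",
                "need >= 2 replicates in each pool for the bootstrap")
  B <- settings$n_reps
  alpha <- 1 - settings$ci_level
  g <- with_seed(seed, {
    tm <- .resample_means(treatment_aucs, B)
    cm <- .control_means(control_aucs, B)
    tm / cm
  })
  ci <- unname(stats::quantile(g, c(alpha / 2, 1 - alpha / 2)))
  structure(list(g_point = mean(treatment_aucs) / mean(control_aucs),
                 ci_low = ci[1], ci_high = ci[2],
                 significant = .excludes_one(ci[1], ci[2]),
                 n_reps = B),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G = %.4f, %s CI [%.4f, %.4f] -> %s\n", x$g_point,
              "bootstrap", x$ci_low, x$ci_high,
              if (x$significant) "significant response" else "no response"))
  invisible(x)
}

#' Bootstrap an interaction coefficient and classify it
#'
#' Each bootstrap replicate independently resamples the replicate AUC
#' pool of every mixture subset entering the coefficient's formula
#' (singletons and lower-order terms included), resamples the shared
#' control pool once, recomputes all lower-order interaction terms from
#' the resampled data and finally the target coefficient.  The
#' percentile CI then feeds the direction-aware antagonism/synergism
#' rule of [classify_interaction()].
#'
#' @param lattice a [response_lattice()].
#' @param mask mixture encoding (>= 2 chemicals).
#' @param kind `"net"`, `"emergent"` or `"partial"`.
#' @param settings a [bootstrap_settings()].
#' @param gate_significant result of the stage-1 gate for this mixture
#'   (see [bootstrap_g()]); if `FALSE` the category is `no_response`.
#' @param max_order highest interaction order in the null (for
#'   `kind = "partial"`).
#' @param seed optional substream seed; defaults to a hash of
#'   (settings seed, culture, mixture, kind).
#' @return object of class `interaction_estimate` with `mixture`,
#'   `kind`, `estimate`, `ci_low`, `ci_high`, `null_prediction`,
#'   `category` and `significant`.
#' @export
bootstrap_interaction <- function(lattice, mask, kind = c("emergent", "net", "partial"),
                                  settings, gate_significant,
                                  max_order = NULL, seed = NULL) {
  stopifnot(inherits(lattice, "response_lattice"),
            inherits(settings, "bootstrap_settings"))
  kind <- match.arg(kind)
  mask <- as.integer(mask)
  if (is.null(seed))
    seed <- substream_seed(settings$seed, lattice$culture, mask, kind,
                           if (is.null(max_order)) "" else max_order)
  est <- switch(kind,
                net = net_interaction(lattice, mask),
                emergent = emergent_interaction(lattice, mask),
                partial = partial_null_residual(lattice, mask, max_order))
  g_mix <- unname(lattice$g[as.character(mask)])
  null_pred <- g_mix / est
  w <- .interaction_weights(mask, kind, max_order)
  w <- w[w != 0]
  terms <- as.integer(names(w))
  # fail loudly before resampling if any subset pool is absent
  missing <- setdiff(as.character(terms), names(lattice$reps))
  if (length(missing) > 0L)
    .stop_class("stressmix_incomplete_lattice",
                "lattice for '%s' is missing replicate pool(s) for subset(s): %s",
                lattice$culture, paste(missing, collapse = ", "))
  B <- settings$n_reps
  alpha <- 1 - settings$ci_level
  lfloor <- log(lattice$g_floor)
  boot <- with_seed(seed, {
    cm <- .control_means(lattice$controls, B)
    log_ctrl <- log(cm)
    acc <- numeric(B)
    for (j in seq_along(terms)) {
      tm <- .resample_means(lattice$reps[[as.character(terms[j])]], B)
      lg <- pmax(log(tm) - log_ctrl, lfloor)
      acc <- acc + w[j] * lg
    }
    exp(acc)
  })
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  category <- classify_interaction(ci[1], ci[2], null_pred, gate_significant)
  structure(list(mixture = mask, kind = kind, max_order = max_order,
                 estimate = est, ci_low = ci[1], ci_high = ci[2],
                 null_prediction = null_pred, category = category,
                 significant = category %in% c("antagonistic", "synergistic"),
                 n_reps = B),
            class = "interaction_estimate")
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("%s interaction = %.4f, CI [%.4f, %.4f], null G = %.4f -> %s\n",
              x$kind, x$estimate, x$ci_low, x$ci_high, x$null_prediction,
              x$category))
  invisible(x)
}
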