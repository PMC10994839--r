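# Net and emergent interaction coefficients on the mixture subset
# lattice under the multiplicative null model.
#
# All interaction arithmetic is carried in log space (products of up to
# 255 ratios underflow otherwise) and exponentiated at the end.  The
# emergent coefficient follows the iterative power-set construction:
# interaction terms are computed for subsets of size 2, then 3, ...,
# each dividing observed mixture growth by all singleton responses and
# all previously computed lower-order interaction terms.  An
# inclusion-exclusion (Moebius) closed form is provided as an
# independent oracle.

#' Build a response lattice for one culture
#'
#' Collects the relative-growth ratio and replicate AUC lists of every
#' measured mixture of one culture, keyed by mixture encoding.
#'
#' @param aucs an AUC table (see [plate_auc()]) or data.frame with
#'   columns `culture, mixture, replicate, auc`.
#' @param culture culture id to extract.
#' @param g_floor relative-growth values below this floor are raised to
#'   it before log-transform (log of zero growth is undefined); floored
#'   mixtures are recorded in `$floored`.
#' @return object of class `response_lattice`: list with `culture`,
#'   `g` (named vector of point G, names = mixture encodings),
#'   `reps` (named list of treatment replicate AUCs), `controls`
#'   (control AUC pool) and `floored`.
#' @export
response_lattice <- function(aucs, culture, g_floor = 1e-4) {
  rows <- aucs[aucs$culture == culture, , drop = FALSE]
  if (nrow(rows) == 0L)
    .stop_class("stressmix_validation", "no AUC rows for culture '%s'", culture)
  controls <- rows$auc[rows$mixture == 0L]
  if (length(controls) < 2L)
    .stop_class("stressmix_insufficient_data",
                "culture '%s' has %d control wells; need >= 2",
                culture, length(controls))
  if (mean(controls) <= 0)
    .stop_class("stressmix_undefined_ratio",
                "culture '%s' has zero mean control AUC", culture)
  trt <- rows[rows$mixture != 0L, , drop = FALSE]
  reps <- split(trt$auc, trt$mixture)
  g <- vapply(reps, mean, numeric(1)) / mean(controls)
  floored <- names(g)[g < g_floor]
  g <- pmax(g, g_floor)
  structure(list(culture = culture, g = g, reps = reps,
                 controls = controls, g_floor = g_floor, floored = floored),
            class = "response_lattice")
}

#' @export
print.response_lattice <- function(x, ...) {
  cat(sprintf("Response lattice for '%s': %d mixtures, %d control wells\n",
              x$culture, length(x$g), length(x$controls)))
  if (length(x$floored))
    cat(sprintf("  %d mixture(s) floored at G = %g\n",
                length(x$floored), x$g_floor))
  invisible(x)
}

# named log-G lookup with loud failure on missing subsets
.log_g <- function(lattice, masks) {
  key <- as.character(masks)
  hit <- match(key, names(lattice$g))
  if (anyNA(hit))
    .stop_class("stressmix_incomplete_lattice",
                "lattice for '%s' is missing mixture subset(s): %s",
                lattice$culture, paste(key[is.na(hit)], collapse = ", "))
  log(unname(lattice$g[hit]))
}

#' Multiplicative null prediction for combined stressors
#'
#' The null expectation for growth in a mixture is the product of the
#' relative growths under each constituent alone: relative fitness is a
#' percentage change, so independent effects compound multiplicatively
#' (two stressors that each leave 30% of control growth predict
#' 0.3 * 0.3 = 0.09, a 91% reduction — an additive model would predict
#' an impossible 140% reduction).
#'
#' @param singles positive relative growths of the individual chemicals.
#' @return the product of `singles`.
#' @export
combine_null <- function(singles) {
  singles <- as.numeric(singles)
  if (length(singles) == 0L || any(!is.finite(singles)) || any(singles <= 0))
    .stop_class("stressmix_domain", "single-chemical G values must be positive")
  exp(sum(log(singles)))
}

#' Net interaction coefficient of a mixture
#'
#' `N_A = G_A / prod(G_a, a in A)`: the overall deviation of mixture
#' growth from the multiplicative null built from single-chemical
#' responses only.
#'
#' @param lattice a [response_lattice()].
#' @param mask mixture encoding with at least 2 chemicals.
#' @return positive ratio; 1 means the null holds.
#' @export
net_interaction <- function(lattice, mask) {
  mask <- as.integer(mask)
  if (.mask_size(mask) < 2L)
    .stop_class("stressmix_argument", "net interaction needs >= 2 chemicals")
  singles <- bitwShiftL(1L, .mask_members(mask) - 1L)
  exp(.log_g(lattice, mask) - sum(.log_g(lattice, singles)))
}

#' Emergent (higher-order) interaction coefficient
#'
#' The residual interaction attributable specifically to the full set,
#' after dividing out all singleton responses and all lower-order
#' interaction terms among its proper subsets.  Computed by the
#' iterative power-set procedure: pairwise terms first, then
#' three-way, and so on.  For a two-chemical mixture this equals the
#' net interaction exactly.
#'
#' @inheritParams net_interaction
#' @return positive ratio; 1 means no interaction unique to the full set.
#' @seealso [mobius_log_interaction()] for the closed-form oracle.
#' @export
emergent_interaction <- function(lattice, mask) {
  mask <- as.integer(mask)
  if (.mask_size(mask) < 2L)
    .stop_class("stressmix_argument", "emergent interaction needs >= 2 chemicals")
  exp(.emergent_log_table(lattice, mask)[[as.character(mask)]])
}

# Iteratively compute log I_S for every subset S of `mask` with |S| >= 2,
# in increasing size order.  Returns a named list keyed by encoding.
.emergent_log_table <- function(lattice, mask) {
  subs <- c(.proper_submasks(mask), mask)
  subs <- subs[.mask_size(subs) >= 2L]
  subs <- subs[order(.mask_size(subs), subs)]
  log_i <- list()
  for (s in subs) {
    singles <- bitwShiftL(1L, .mask_members(s) - 1L)
    lower <- .proper_submasks(s)
    lower <- lower[.mask_size(lower) >= 2L]
    li <- .log_g(lattice, s) - sum(.log_g(lattice, singles))
    for (k in lower) li <- li - log_i[[as.character(k)]]
    log_i[[as.character(s)]] <- li
  }
  log_i
}

#' Inclusion-exclusion closed form for the emergent interaction
#'
#' Independent oracle for [emergent_interaction()]: the iterative
#' power-set recursion telescopes to the Moebius sum
#' `log I_A = sum over non-empty S subset A of (-1)^(|A|-|S|) log G_S`.
#'
#' @inheritParams net_interaction
#' @return log of the emergent interaction coefficient.
#' @export
mobius_log_interaction <- function(lattice, mask) {
  mask <- as.integer(mask)
  if (.mask_size(mask) < 2L)
    .stop_class("stressmix_argument", "needs >= 2 chemicals")
  subs <- c(.proper_submasks(mask), mask)
  signs <- (-1)^(.mask_size(mask) - .mask_size(subs))
  sum(signs * vapply(subs, function(s) .log_g(lattice, s), numeric(1)))
}

#' Residual interaction under a partial-order null model
#'
#' Divides mixture growth by the null model that includes all singleton
#' responses and all emergent interaction terms of order up to
#' `max_order`.  `max_order = 1` is the net interaction; `max_order =
#' |A| - 1` recovers the emergent interaction.  A residual of 1 means
#' interactions up to `max_order` fully explain the mixture's response.
#'
#' @inheritParams net_interaction
#' @param max_order highest interaction order included in the null;
#'   must satisfy `1 <= max_order < mixture size`.
#' @return positive residual ratio.
#' @export
partial_null_residual <- function(lattice, mask, max_order) {
  mask <- as.integer(mask)
  n <- .mask_size(mask)
  if (n < 2L)
    .stop_class("stressmix_argument", "needs >= 2 chemicals")
  if (max_order < 1L || max_order >= n)
    .stop_class("stressmix_argument",
                "max_order must be in [1, %d] for a %d-chemical mixture (use emergent_interaction for the full order)",
                n - 1L, n)
  singles <- bitwShiftL(1L, .mask_members(mask) - 1L)
  res <- .log_g(lattice, mask) - sum(.log_g(lattice, singles))
  if (max_order >= 2L) {
    log_i <- .emergent_log_table(lattice, mask)
    keep <- .proper_submasks(mask)
    keep <- keep[.mask_size(keep) >= 2L & .mask_size(keep) <= max_order]
    for (k in keep) res <- res - log_i[[as.character(k)]]
  }
  exp(res)
}

# Linear weights w such that the log interaction statistic equals
# sum(w_S * log G_S) over the non-empty subsets S of `mask`.  Used to
# vectorise the bootstrap.  kind: "net", "emergent" or "partial".
.interaction_weights <- function(mask, kind, max_order = NULL) {
  mask <- as.integer(mask)
  n <- .mask_size(mask)
  subs <- c(.proper_submasks(mask), mask)
  sizes <- .mask_size(subs)
  w <- numeric(length(subs))
  names(w) <- as.character(subs)
  w[as.character(mask)] <- 1
  if (kind == "net") {
    w[sizes == 1L] <- -1
  } else if (kind == "emergent") {
    # Moebius expansion: coefficient of log G_S is (-1)^(n-|S|)
    w[] <- (-1)^(n - sizes)
  } else if (kind == "partial") {
    m0 <- max_order
    # log R = log G_A - sum_{k subset A, 1 <= |k| <= m0} log I_k, and
    # log I_k = sum_{S subset k} (-1)^(|k|-|S|) log G_S, so the
    # coefficient of log G_S collapses to a binomial sum over |k|.
    for (j in seq_along(subs)) {
      s <- sizes[j]
      if (subs[j] == mask) next
      if (s > m0) { w[j] <- 0; next }
      jj <- s:m0
      w[j] <- -sum((-1)^(jj - s) * choose(n - s, jj - s))
    }
  } else .stop_class("stressmix_argument", "unknown interaction kind '%s'", kind)
  w
}

#' Classify a significant interaction as antagonistic or synergistic
#'
#' Direction-aware rule: when the null prediction is itself a growth
#' reduction, an interaction ratio above 1 dampens the predicted effect
#' (antagonism) and below 1 amplifies it (synergism); when the null
#' predicts a growth increase the mapping flips.
#'
#' @param ci_low,ci_high bootstrap CI of the interaction ratio.
#' @param null_prediction the multiplicative null prediction of G for
#'   the mixture (the denominator of the ratio).
#' @param gate_significant did the mixture's growth response itself
#'   differ from control (G CI excluding 1)?  If not, the mixture is
#'   classified `no_response` regardless of the interaction CI.
#' @return one of `"no_response"`, `"multiplicative"`, `"antagonistic"`,
#'   `"synergistic"`.
#' @export
classify_interaction <- function(ci_low, ci_high, null_prediction,
                                 gate_significant) {
  if (ci_low > ci_high)
    .stop_class("stressmix_argument", "ci_low > ci_high")
  if (null_prediction <= 0)
    .stop_class("stressmix_domain", "null prediction must be positive")
  if (!isTRUE(gate_significant)) return("no_response")
  if (!.excludes_one(ci_low, ci_high)) return("multiplicative")
  ratio_up <- ci_low > 1
  if (null_prediction > 1) {
    return(if (ratio_up) "synergistic" else "antagonistic")
  }
  if (null_prediction < 1) {
    return(if (ratio_up) "antagonistic" else "synergistic")
  }
  # null exactly 1 with a significant interaction: classify by whether
  # the deviation amplifies |G - 1| (amplification = synergism)
  message("classify_interaction: null prediction exactly 1; classifying by amplification")
  "synergistic"
}
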