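# Result-level aggregations over a fitted analysis: response-sign
# proportions by complexity, complexity regressions with a focal
# chemical indicator, the interaction persistence lattice, the
# interaction-order sufficiency table and cross-culture consistency of
# emergent interactions.

#' Response-sign proportions by mixture complexity
#'
#' Classifies every (culture, mixture) response as negative (G CI
#' entirely below 1), positive (entirely above 1) or none, aggregates
#' by complexity, and fits an OLS regression of the negative proportion
#' on complexity.
#'
#' @param responses the `responses` data.frame of a [stressmix()] fit
#'   (columns `complexity`, `direction`).
#' @return list with `table` (complexity, counts and proportions per
#'   category) and `trend` (intercept, slope, r2 of negative-proportion
#'   on complexity).
#' @export
response_sign_table <- function(responses) {
  if (is.null(responses) || nrow(responses) == 0L)
    .stop_class("stressmix_argument", "empty response table")
  tab <- do.call(rbind, lapply(split(responses, responses$complexity),
    function(d) data.frame(
      complexity = d$complexity[1], n = nrow(d),
      n_negative = sum(d$direction == "negative"),
      n_positive = sum(d$direction == "positive"),
      n_none = sum(d$direction == "none"),
      negative = mean(d$direction == "negative"),
      positive = mean(d$direction == "positive"),
      none = mean(d$direction == "none"))))
  rownames(tab) <- NULL
  trend <- if (nrow(tab) >= 2L && stats::var(tab$negative) > 0) {
    fit <- stats::lm(negative ~ complexity, data = tab)
    # noiseless inputs fit perfectly; the summary warning is expected
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r2 = suppressWarnings(summary(fit)$r.squared))
  } else {
    list(intercept = if (nrow(tab)) tab$negative[1] else NA_real_,
         slope = 0, r2 = 0)
  }
  list(table = tab, trend = trend)
}

#' Regression of mean relative growth on mixture complexity
#'
#' OLS of per-mixture mean G on the number of chemicals and an
#' indicator for the presence of a focal chemical — the standard probe
#' for bimodal response distributions driven by one dominant stressor
#' (e.g. an antibiotic).
#'
#' @param responses `responses` data.frame of a [stressmix()] fit
#'   (columns `culture, mixture, complexity, g`).
#' @param focal_chemical panel index (1-based) or chemical name of the
#'   focal chemical.
#' @param panel the [chemical_panel()] (needed when a name is given).
#' @param culture optional single culture; default pools mixture means
#'   across cultures.
#' @return list with `intercept`, `slope`, `focal_coefficient`, `r2`
#'   and the fitted `lm` object.
#' @export
complexity_regression <- function(responses, focal_chemical, panel = NULL,
                                  culture = NULL) {
  if (is.character(focal_chemical)) {
    stopifnot(inherits(panel, "chemical_panel"))
    focal_chemical <- match(focal_chemical, unclass(panel))
  }
  focal_chemical <- as.integer(focal_chemical)
  if (is.na(focal_chemical) || focal_chemical < 1L ||
      (!is.null(panel) && focal_chemical > attr(panel, "size")))
    .stop_class("stressmix_argument", "focal chemical index out of range")
  d <- responses
  if (!is.null(culture)) d <- d[d$culture == culture, , drop = FALSE]
  if (focal_chemical > 30L || !any(bitwAnd(d$mixture,
                                           bitwShiftL(1L, focal_chemical - 1L)) > 0))
    .stop_class("stressmix_argument",
                "focal chemical index %d not present in any measured mixture",
                focal_chemical)
  dat <- data.frame(
    g = d$g,
    complexity = d$complexity,
    focal = as.integer(bitwAnd(d$mixture, bitwShiftL(1L, focal_chemical - 1L)) > 0))
  fit <- stats::lm(g ~ complexity + focal, data = dat)
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  degenerate <- stats::var(dat$g) == 0
  list(intercept = unname(cf[1]),
       slope = if (is.na(cf[2])) 0 else unname(cf[2]),
       focal_coefficient = if (is.na(cf[3])) 0 else unname(cf[3]),
       r2 = if (degenerate || is.nan(r2)) 0 else r2,
       degenerate = degenerate,
       model = fit)
}

#' Build the interaction persistence lattice
#'
#' Nodes are mixtures with their interaction category; edges join
#' significantly interacting mixtures exactly one complexity level
#' apart where the smaller mixture is a subset of the larger — the
#' Hasse-diagram view of interaction persistence.
#'
#' @param interactions the `interactions` data.frame of a [stressmix()]
#'   fit, restricted to one culture.
#' @return list with `nodes` (mixture, complexity, category) and
#'   `edges` (sub, super).
#' @export
build_interaction_lattice <- function(interactions) {
  if (anyDuplicated(interactions$mixture))
    .stop_class("stressmix_argument",
                "duplicate mixtures; pass one culture's interactions")
  nodes <- interactions[c("mixture", "complexity", "category")]
  sig <- nodes$mixture[nodes$category %in% c("antagonistic", "synergistic")]
  edges <- NULL
  if (length(sig) >= 2L) {
    sz <- mixture_size(sig)
    pairs <- expand.grid(sub = sig, super = sig)
    keep <- mixture_size(pairs$super) == mixture_size(pairs$sub) + 1L &
      bitwAnd(pairs$sub, pairs$super) == pairs$sub
    edges <- pairs[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(sub = integer(0), super = integer(0))
  list(nodes = nodes, edges = edges)
}

#' Interaction-order sufficiency table
#'
#' For every mixture with a significant net interaction, asks how many
#' interaction orders the null model must absorb before the residual
#' stops being significant: residuals are re-bootstrapped under partial
#' nulls of order 2, 3, ... and counted.  Counts are non-increasing in
#' the order for fixed data and seed (nested nulls).
#'
#' @param fit a [stressmix()] fit with `kind = "net"`.
#' @param max_orders orders to test (default 2 up to panel size - 1).
#' @return data.frame with one row per complexity level: number of
#'   mixtures with a significant net interaction, and the counts still
#'   significant at each tested order.
#' @export
terms_required_table <- function(fit, max_orders = NULL) {
  stopifnot(inherits(fit, "stressmix"))
  int <- fit$interactions
  if (is.null(int) || fit$kind != "net")
    .stop_class("stressmix_argument", "fit must carry net interactions")
  sig <- int[int$category %in% c("antagonistic", "synergistic"), , drop = FALSE]
  if (is.null(max_orders))
    max_orders <- seq(2L, max(2L, max(int$complexity) - 1L))
  lv <- sort(unique(int$complexity[int$complexity >= 3L]))
  out <- data.frame(complexity = lv,
                    net = vapply(lv, function(k)
                      sum(sig$complexity == k), integer(1)))
  for (m0 in max_orders) {
    col <- integer(length(lv))
    for (i in seq_along(lv)) {
      k <- lv[i]
      if (m0 >= k) { col[i] <- NA_integer_; next }
      rows <- sig[sig$complexity == k, , drop = FALSE]
      n_sig <- 0L
      for (j in seq_len(nrow(rows))) {
        lat <- fit$lattices[[rows$culture[j]]]
        est <- bootstrap_interaction(lat, rows$mixture[j], kind = "partial",
                                     settings = fit$settings,
                                     gate_significant = TRUE,
                                     max_order = m0)
        if (est$significant) n_sig <- n_sig + 1L
      }
      col[i] <- n_sig
    }
    out[[paste0("order_", m0)]] <- col
  }
  out
}

#' Cross-culture consistency of emergent interactions
#'
#' Among mixtures of three or more chemicals where at least two
#' cultures show a significant emergent interaction, the fraction for
#' which all such cultures agree on the interaction type.
#'
#' @param interactions `interactions` data.frame of an emergent-kind
#'   [stressmix()] fit across cultures.
#' @return list with `proportion` (NA when no mixture qualifies),
#'   `n_qualifying` and the per-mixture detail table.
#' @export
emergent_consistency <- function(interactions) {
  sig <- interactions[interactions$complexity >= 3L &
                        interactions$category %in% c("antagonistic", "synergistic"),
                      , drop = FALSE]
  detail <- do.call(rbind, lapply(split(sig, sig$mixture), function(d) {
    data.frame(mixture = d$mixture[1], n_cultures = nrow(d),
               consistent = length(unique(d$category)) == 1L)
  }))
  if (is.null(detail)) detail <- data.frame(mixture = integer(0),
                                            n_cultures = integer(0),
                                            consistent = logical(0))
  qual <- detail[detail$n_cultures >= 2L, , drop = FALSE]
  list(proportion = if (nrow(qual)) mean(qual$consistent) else NA_real_,
       n_qualifying = nrow(qual),
       detail = detail)
}
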