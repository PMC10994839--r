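# The central estimator: fit interaction coefficients for every
# measured mixture of every culture in an AUC table, gate each mixture
# on its growth response, and classify significant interactions.

#' Fit multi-stressor interaction coefficients to an AUC table
#'
#' For each culture, builds the response lattice, runs the stage-1
#' bootstrap gate on every mixture (does the mixture change growth at
#' all?) and then, for mixtures of two or more chemicals, bootstraps
#' the requested interaction coefficient against the multiplicative
#' null and classifies it as antagonistic, synergistic, multiplicative
#' or no-response.
#'
#' @param aucs an AUC table from [plate_auc()] or a data.frame with
#'   columns `culture, mixture, replicate, auc` (control wells have
#'   `mixture == 0`).
#' @param panel a [chemical_panel()]; defaults to `attr(aucs, "panel")`.
#' @param kind interaction coefficient to estimate: `"net"` (default,
#'   deviation from the singleton product) or `"emergent"` (residual
#'   after all lower-order interaction terms).
#' @param boot a [bootstrap_settings()].
#' @param g_floor floor applied to relative growth before
#'   log-transform; see [response_lattice()].
#' @param cultures optional subset of cultures to fit.
#' @param mixtures optional integer vector of mixture encodings to test
#'   (all measured mixtures by default).
#' @param fdr `"off"` (default, matching the two-stage CI procedure
#'   with no multiplicity adjustment) or `"bh"` to additionally report
#'   Benjamini-Hochberg adjusted bootstrap p-values.
#' @return an object of class `stressmix`: list with `responses` (one
#'   row per culture x mixture: G, CI, gate), `interactions` (one row
#'   per tested mixture: estimate, CI, null prediction, category),
#'   `panel`, `settings`, `kind` and the per-culture `lattices`.
#' @examples
#' spec <- paperlike_preset(n_cultures = 1, seed = 7)
#' plate <- simulate_plate(spec)
#' aucs <- plate_auc(plate)
#' fit <- stressmix(aucs, kind = "net",
#'                  boot = bootstrap_settings(n_reps = 200, seed = 7),
#'                  mixtures = enumerate_mixtures(spec$panel)[1:12])
#' summary(fit)
#' @export
stressmix <- function(aucs, panel = attr(aucs, "panel"),
                      kind = c("net", "emergent"),
                      boot = bootstrap_settings(),
                      g_floor = 1e-4, cultures = NULL, mixtures = NULL,
                      fdr = c("off", "bh")) {
  kind <- match.arg(kind)
  fdr <- match.arg(fdr)
  stopifnot(inherits(panel, "chemical_panel"),
            inherits(boot, "bootstrap_settings"))
  if (is.null(cultures)) cultures <- unique(aucs$culture)
  lattices <- lapply(cultures, function(cc)
    response_lattice(aucs, cc, g_floor = g_floor))
  names(lattices) <- cultures

  resp <- list(); inter <- list()
  for (cc in cultures) {
    lat <- lattices[[cc]]
    masks <- as.integer(names(lat$g))
    if (!is.null(mixtures)) masks <- intersect(masks, as.integer(mixtures))
    masks <- masks[order(mixture_size(masks), masks)]
    gates <- logical(length(masks)); names(gates) <- as.character(masks)
    for (m in masks) {
      gt <- bootstrap_g(lat$reps[[as.character(m)]], lat$controls, boot,
                        seed = substream_seed(boot$seed, cc, m, "gate"))
      gates[as.character(m)] <- gt$significant
      resp[[length(resp) + 1L]] <- data.frame(
        culture = cc, mixture = m, complexity = mixture_size(m),
        g = gt$g_point, ci_low = gt$ci_low, ci_high = gt$ci_high,
        significant = gt$significant,
        direction = if (!gt$significant) "none"
                    else if (gt$ci_high < 1) "negative" else "positive",
        stringsAsFactors = FALSE)
    }
    for (m in masks[mixture_size(masks) >= 2L]) {
      est <- bootstrap_interaction(lat, m, kind = kind, settings = boot,
                                   gate_significant = gates[[as.character(m)]])
      inter[[length(inter) + 1L]] <- data.frame(
        culture = cc, mixture = m, complexity = mixture_size(m),
        kind = kind, estimate = est$estimate,
        ci_low = est$ci_low, ci_high = est$ci_high,
        null_prediction = est$null_prediction, category = est$category,
        stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, resp)
  interactions <- if (length(inter)) do.call(rbind, inter) else NULL
  if (fdr == "bh" && !is.null(interactions)) {
    # approximate two-sided bootstrap p from CI inversion is not
    # available without the full distribution; recompute a coarse p as
    # the smallest level at which the percentile CI excludes 1
    interactions$p_adj <- stats::p.adjust(
      .ci_pseudo_p(interactions$ci_low, interactions$ci_high), "BH")
  }
  structure(list(responses = responses, interactions = interactions,
                 lattices = lattices, panel = panel, settings = boot,
                 kind = kind),
            class = "stressmix")
}

# crude pseudo p-value from a single CI: 0.049 if excluded, 1 if not;
# only used to order BH adjustment when the user asks for it.
.ci_pseudo_p <- function(lo, hi) ifelse(lo > 1 | hi < 1, 0.049, 1)

#' @export
print.stressmix <- function(x, ...) {
  cat(sprintf("stressmix fit: %d culture(s), %d mixtures, kind = %s\n",
              length(x$lattices), length(unique(x$responses$mixture)),
              x$kind))
  cat(sprintf("  bootstrap: %d reps, %.0f%% CI, seed %d\n",
              x$settings$n_reps, 100 * x$settings$ci_level,
              x$settings$seed))
  if (!is.null(x$interactions)) {
    tab <- table(x$interactions$category)
    cat("  interaction categories:\n")
    for (nm in names(tab)) cat(sprintf("    %-15s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' @export
summary.stressmix <- function(object, ...) {
  resp <- object$responses
  sign_tab <- do.call(rbind, lapply(split(resp, resp$complexity), function(d) {
    data.frame(complexity = d$complexity[1],
               n = nrow(d),
               negative = mean(d$direction == "negative"),
               positive = mean(d$direction == "positive"),
               none = mean(d$direction == "none"))
  }))
  rownames(sign_tab) <- NULL
  cat_tab <- NULL
  if (!is.null(object$interactions)) {
    int <- object$interactions
    cat_tab <- do.call(rbind, lapply(split(int, int$complexity), function(d) {
      out <- data.frame(complexity = d$complexity[1], n = nrow(d))
      for (cat in c("no_response", "multiplicative", "antagonistic", "synergistic"))
        out[[cat]] <- mean(d$category == cat)
      out
    }))
    rownames(cat_tab) <- NULL
  }
  structure(list(kind = object$kind, responses = sign_tab,
                 interactions = cat_tab,
                 n_cultures = length(object$lattices)),
            class = "summary.stressmix")
}

#' @export
print.summary.stressmix <- function(x, ...) {
  cat(sprintf("Responses by mixture complexity (%d cultures):\n", x$n_cultures))
  print(x$responses, row.names = FALSE, digits = 3)
  if (!is.null(x$interactions)) {
    cat(sprintf("\n%s interaction categories by complexity:\n", x$kind))
    print(x$interactions, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.stressmix <- function(object, ...) {
  if (is.null(object$interactions)) return(numeric(0))
  stats::setNames(object$interactions$estimate,
                  paste(object$interactions$culture,
                        mixture_chemicals(object$interactions$mixture,
                                          object$panel),
                        sep = ":"))
}

#' Plot interaction-category proportions by mixture complexity
#'
#' Stacked bars of no-response / multiplicative / antagonistic /
#' synergistic proportions at each complexity level, the standard
#' summary view for a full-factorial stressor experiment.
#'
#' @param x a `stressmix` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.stressmix <- function(x, ...) {
  if (is.null(x$interactions)) {
    warning("no interactions to plot")
    return(invisible(x))
  }
  int <- x$interactions
  cats <- c("no_response", "multiplicative", "antagonistic", "synergistic")
  tab <- sapply(split(int$category, int$complexity),
                function(v) sapply(cats, function(cc) mean(v == cc)))
  graphics::barplot(tab, col = c("grey80", "steelblue", "darkcyan", "goldenrod"),
                    xlab = "Mixture complexity (number of chemicals)",
                    ylab = "Proportion of mixtures",
                    legend.text = cats, args.legend = list(x = "topright",
                                                           bg = "white"),
                    ...)
  invisible(x)
}

#' Write a stressmix fit's interaction table to CSV
#'
#' Columns: culture, mixture (semicolon-joined chemical names), kind,
#' estimate, ci_low, ci_high, null_prediction, category.
#'
#' @param fit a `stressmix` object.
#' @param path output path.
#' @export
write_interactions <- function(fit, path) {
  stopifnot(inherits(fit, "stressmix"))
  int <- fit$interactions
  out <- data.frame(culture = int$culture,
                    mixture = mixture_chemicals(int$mixture, fit$panel),
                    kind = int$kind,
                    estimate = int$estimate, ci_low = int$ci_low,
                    ci_high = int$ci_high,
                    null_prediction = int$null_prediction,
                    category = int$category)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
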