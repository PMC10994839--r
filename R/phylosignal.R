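# Phylogenetic and phenotypic distance analyses: response fingerprints,
# Euclidean distance matrices, hierarchical clustering, Mantel test
# with Kendall's tau (via vegan), Pagel's lambda with a likelihood-
# ratio test and Blomberg's K with a randomization test.

#' Response fingerprints of cultures
#'
#' One row per culture: the G values of every mixture in the canonical
#' enumeration order, forming the culture's overall stressor-response
#' phenotype.
#'
#' @param responses `responses` data.frame of a [stressmix()] fit.
#' @param panel the [chemical_panel()].
#' @param mask_nonsignificant if `TRUE`, G values whose gate retained 1
#'   are replaced by 1 (no-effect); default uses the unmasked means.
#' @return numeric matrix, cultures x mixtures.
#' @export
response_fingerprints <- function(responses, panel,
                                  mask_nonsignificant = FALSE) {
  order_masks <- enumerate_mixtures(panel)
  cultures <- unique(responses$culture)
  mat <- matrix(NA_real_, length(cultures), length(order_masks),
                dimnames = list(cultures, as.character(order_masks)))
  for (i in seq_len(nrow(responses))) {
    g <- responses$g[i]
    if (mask_nonsignificant && !responses$significant[i]) g <- 1
    mat[responses$culture[i], as.character(responses$mixture[i])] <- g
  }
  if (anyNA(mat))
    .stop_class("stressmix_incomplete_lattice",
                "fingerprints incomplete: %d missing culture x mixture cells",
                sum(is.na(mat)))
  mat
}

#' Pairwise Euclidean distances between response fingerprints
#'
#' @param fingerprints matrix from [response_fingerprints()] (rows =
#'   cultures) or any numeric matrix of equal-length profiles.
#' @return symmetric distance matrix with zero diagonal.
#' @export
response_distance_matrix <- function(fingerprints) {
  if (is.list(fingerprints)) {
    len <- lengths(fingerprints)
    if (length(unique(len)) != 1L)
      .stop_class("stressmix_validation", "fingerprint profiles differ in length")
    fingerprints <- do.call(rbind, fingerprints)
  }
  if (nrow(fingerprints) < 2L)
    .stop_class("stressmix_argument", "need at least 2 fingerprints")
  as.matrix(stats::dist(fingerprints, method = "euclidean"))
}

#' Hierarchical clustering of response distances
#'
#' @param distances symmetric distance matrix.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return an [stats::hclust] dendrogram.
#' @export
hierarchical_cluster <- function(distances, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    .stop_class("stressmix_validation", "distance matrix is not symmetric")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(distances), method = method)
}

#' Mantel test with Kendall's rank correlation
#'
#' Association between two distance matrices (e.g. phenotypic response
#' distance vs patristic distance), with Kendall's tau on the
#' vectorised off-diagonal entries and a one-sided permutation p-value
#' `(1 + #\{permuted tau >= observed\}) / (n_perm + 1)`, permuting rows
#' and columns of the second matrix jointly.  Delegates to
#' [vegan::mantel()].
#'
#' @param d1,d2 distance matrices of equal dimension.
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param seed integer seed for the permutations.
#' @return list with `tau` and `p`.
#' @export
mantel_kendall <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    .stop_class("stressmix_validation", "distance matrices differ in dimension")
  if (n_perm < 99L)
    .stop_class("stressmix_argument", "need at least 99 permutations")
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (stats::var(v1) == 0 || stats::var(v2) == 0)
    .stop_class("stressmix_degenerate",
                "constant distance vector; Kendall's tau undefined")
  res <- with_seed(seed,
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  method = "kendall", permutations = n_perm))
  list(tau = unname(res$statistic), p = res$signif)
}

# lambda-scaled Brownian covariance: off-diagonal (shared-history)
# entries multiplied by lambda, diagonal kept.
.lambda_vcv <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# Profile log-likelihood of a Brownian trait on covariance V (GLS mean
# and rate profiled out analytically).
.bm_loglik <- function(x, V) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi_x) / sum(Vi_1)
  r <- x - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vi_r) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda with likelihood-ratio test
#'
#' Maximises the Brownian-motion likelihood of a tip trait with the
#' off-diagonal (shared-history) entries of the tree covariance scaled
#' by lambda, constrained to [0, 1].  lambda = 0 removes all
#' covariance (independent tips); lambda = 1 is plain Brownian motion.
#' The p-value is a likelihood-ratio test against lambda = 0
#' (chi-squared, 1 df).
#'
#' @param tree an [ape::phylo] tree with positive branch lengths.
#' @param values named numeric vector of tip trait values (names must
#'   cover the tips exactly) or an unnamed vector in tip order.
#' @param tol optimisation tolerance on lambda.
#' @return list with `lambda`, `loglik`, `loglik0` (lambda = 0) and `p`.
#' @export
pagels_lambda <- function(tree, values, tol = 1e-8) {
  x <- .match_trait(tree, values)
  if (length(x) < 4L)
    .stop_class("stressmix_insufficient_data", "need >= 4 tips")
  if (stats::var(x) == 0)
    .stop_class("stressmix_degenerate", "zero trait variance")
  C <- ape::vcv(tree)
  C <- C[names(x), names(x)]
  f <- function(l) .bm_loglik(x, .lambda_vcv(C, l))
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = tol)
  # the optimum can sit on a boundary; compare with endpoints explicitly
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  lambda_hat <- cand[best]
  loglik <- ll[best]
  loglik0 <- ll[2]
  lr <- max(0, 2 * (loglik - loglik0))
  list(lambda = lambda_hat, loglik = loglik, loglik0 = loglik0,
       p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Blomberg's K with randomization test
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]`, where MSE0 is the mean squared
#' deviation of tips from the phylogenetically corrected (GLS) mean,
#' MSE is the generalized least-squares error under the tree
#' covariance, and the expectation is the Brownian-motion value for
#' this tree.  K near 1 matches Brownian motion; K > 1 indicates trait
#' conservatism beyond it.  The p-value is the proportion of tip-label
#' shuffles whose MSE is at most the observed MSE (with the +1
#' continuity correction so p is never 0).
#'
#' @inheritParams pagels_lambda
#' @param n_rand number of randomizations (default 1000).
#' @param seed integer seed for the shuffles.
#' @return list with `k` and `p`.
#' @export
blombergs_K <- function(tree, values, n_rand = 1000L, seed = 1L) {
  x <- .match_trait(tree, values)
  n <- length(x)
  if (n < 4L)
    .stop_class("stressmix_insufficient_data", "need >= 4 tips")
  if (stats::var(x) == 0)
    .stop_class("stressmix_degenerate", "zero trait variance")
  C <- ape::vcv(tree)
  C <- C[names(x), names(x)]
  Ci <- solve(C)
  one <- rep(1, n)
  denom_mu <- sum(Ci %*% one)
  mse_of <- function(v) {
    mu <- sum(Ci %*% v) / denom_mu
    r <- v - mu
    list(mse0 = sum(r^2) / (n - 1),
         mse = drop(t(r) %*% Ci %*% r) / (n - 1))
  }
  obs <- mse_of(x)
  expected_ratio <- (sum(diag(C)) - n / denom_mu) / (n - 1)
  k <- (obs$mse0 / obs$mse) / expected_ratio
  shuffled_mse <- with_seed(seed, vapply(seq_len(n_rand), function(i) {
    mse_of(x[sample.int(n)])$mse
  }, numeric(1)))
  p <- (1 + sum(shuffled_mse <= obs$mse)) / (n_rand + 1)
  list(k = k, p = p)
}

# Match a trait vector to tree tips, by names when present.
.match_trait <- function(tree, values) {
  if (!is.null(names(values))) {
    match_tree_cultures(tree, names(values))
    values <- values[tree$tip.label]
  } else {
    if (length(values) != length(tree$tip.label))
      .stop_class("stressmix_validation",
                  "unnamed trait vector must match the number of tips")
    names(values) <- tree$tip.label
  }
  values
}

#' Rank-based inverse-normal transform
#'
#' Deterministic, monotone normalization applied to G values before
#' the lambda test (growth ratios are typically left-skewed).  Uses
#' Blom offsets: `qnorm((rank - 3/8) / (n + 1/4))`, with ties averaged.
#'
#' @param values numeric vector (>= 4 values, not all tied).
#' @return transformed vector (names preserved).
#' @export
normalize_trait <- function(values) {
  if (length(values) < 4L)
    .stop_class("stressmix_insufficient_data", "need >= 4 values")
  if (length(unique(values)) == 1L)
    .stop_class("stressmix_degenerate", "all values tied; cannot normalize")
  r <- rank(values, ties.method = "average")
  out <- stats::qnorm((r - 3/8) / (length(values) + 1/4))
  names(out) <- names(values)
  out
}

#' Phylogenetic-signal report for per-chemical responses
#'
#' Runs Pagel's lambda (on rank-normalized values) and Blomberg's K for
#' the single-chemical response of every panel chemical, plus the
#' whole-profile Mantel test against the tree's patristic distances.
#'
#' @param responses `responses` data.frame of a [stressmix()] fit.
#' @param panel the [chemical_panel()].
#' @param tree an [ape::phylo] tree whose tips are the culture ids.
#' @param n_rand randomizations for K; `n_perm` permutations for the
#'   Mantel test.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return data.frame `test, chemical, statistic, p`.
#' @export
phylosignal_report <- function(responses, panel, tree, n_rand = 1000L,
                               n_perm = 9999L, seed = 1L) {
  match_tree_cultures(tree, unique(responses$culture))
  fp <- response_fingerprints(responses, panel)
  dm <- response_distance_matrix(fp)
  pd <- ape::cophenetic.phylo(tree)[rownames(dm), rownames(dm)]
  mt <- mantel_kendall(dm, pd, n_perm = n_perm,
                       seed = substream_seed(seed, "mantel"))
  rows <- list(data.frame(test = "mantel", chemical = "profile",
                          statistic = mt$tau, p = mt$p))
  singles <- responses[responses$complexity == 1L, , drop = FALSE]
  for (i in seq_len(attr(panel, "size"))) {
    m <- bitwShiftL(1L, i - 1L)
    d <- singles[singles$mixture == m, , drop = FALSE]
    trait <- stats::setNames(d$g, d$culture)
    nm <- unclass(panel)[i]
    lam <- pagels_lambda(tree, normalize_trait(trait))
    kk <- blombergs_K(tree, trait, n_rand = n_rand,
                      seed = substream_seed(seed, "K", nm))
    rows[[length(rows) + 1L]] <- data.frame(
      test = c("lambda", "K"), chemical = nm,
      statistic = c(lam$lambda, kk$k), p = c(lam$p, kk$p))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
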