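# Internal helpers: deterministic seed substreams and misc numerics.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`
#' and restores the previous state on exit, so package functions never
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a character key, for deriving independent
# seed substreams.  Polynomial rolling hash; collisions are harmless for
# this purpose (streams only need to be reproducible and well separated).
.hash31 <- function(key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible seed substream
#'
#' Combines a master seed with a string tag (e.g. "culture|mixture")
#' so that every (culture, mixture) pair gets its own random stream:
#' adding or removing one mixture never perturbs another's bootstrap
#' confidence interval.
#'
#' @param master integer master seed.
#' @param ... components of the tag; coerced to character and joined.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "strain_01", 3, "gate")
#' @export
substream_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  as.integer((as.numeric(master) %% 2147483647 + .hash31(tag)) %% 2147483647)
}

# 5-point Gauss-Legendre nodes/weights on [-1, 1]; exact for polynomials
# up to degree 9, so cubic spline segments are integrated exactly.
.gl5 <- list(
  x = c(-0.906179845938663992797627, -0.538469310105683091036314, 0,
         0.538469310105683091036314,  0.906179845938663992797627),
  w = c(0.236926885056189087514264, 0.478628670499366468041292,
        0.568888888888888888888889,
        0.478628670499366468041292, 0.236926885056189087514264)
)

# stop() with a classed condition so callers/tests can match on class.
.stop_class <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "stressmix_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
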