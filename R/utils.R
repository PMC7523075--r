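#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Run `expr` with a locally-seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from a master seed; stays < 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.double(master) * 48271 + h) %% 2147483629) + 1L
}

quintiles <- function(x) {
  q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  stats::setNames(q, c("min", "q25", "median", "q75", "max"))
}
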