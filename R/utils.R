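# Internal helpers shared across modules.

#' Largest-remainder integer allocation
#'
#' Splits `n` items among named groups so counts equal `n * fraction` rounded
#' by the largest-remainder (Hare) method: quotas are floored and the leftover
#' units go to the groups with the largest fractional parts. The result is
#' deterministic: ties are broken by position in `fractions`.
#'
#' @param n Total number of items (positive integer).
#' @param fractions Named non-negative numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @examples
#' largest_remainder(40000, c(a = 0.008, b = 0.992))
#' @export
largest_remainder <- function(n, fractions) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single positive integer.")
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    abort("`fractions` must be a fully named vector.")
  }
  if (any(fractions < 0)) abort("fractions must be non-negative.")
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1.")
  quota <- n * fractions
  counts <- floor(quota)
  leftover <- as.integer(round(n - sum(counts)))
  if (leftover > 0) {
    # stable order: remainder descending, original position as tie-break
    ord <- order(-(quota - counts), seq_along(quota))
    counts[ord[seq_len(leftover)]] <- counts[ord[seq_len(leftover)]] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

# Derive a child seed from a parent seed and a stage offset, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal draws by rejection; bounds are a few SD wide here so the
# acceptance rate is high and no special sampler is needed.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
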