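#' @keywords internal
"_PACKAGE"

# Validation helper: stop with the offending field named, so callers can
# trace errors in config files back to a parameter.
stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(field, "must be a single finite number")
  ok_lo <- if (allow_equal_lower) x >= lower else x > lower
  ok_hi <- if (allow_equal_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi)
    stop_invalid(field, sprintf("must be in %s%g, %g%s (got %g)",
                                if (allow_equal_lower) "[" else "(",
                                lower, upper,
                                if (allow_equal_upper) "]" else ")", x))
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive per-stage child seeds from one top-level seed, keeping results
# below .Machine$integer.max so they remain valid R integer seeds.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stage_index) %% 2147483587)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions up to label renaming, 0 is the chance level.
#' Used to score recovery of planted subnetwork structure.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("b", "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
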