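# Internal helpers shared across modules.

LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

# Independent leads actually synthesized; the remaining four limb leads are
# derived through the Einthoven/Goldberger relations.
BASIS_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Combine two integer seeds into one valid 32-bit seed
#'
#' Deterministic mixing used to derive per-case and per-member seeds from a
#' global seed, keeping every derived seed inside the signed 32-bit range.
#'
#' @param seed base seed (integer).
#' @param k stream index (non-negative integer).
#' @return a single integer usable with [set.seed()].
#' @keywords internal
mix_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 1e6) * 2017 + as.numeric(k) * 7919 + 1
  as.integer(s %% 2147483647)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single number in [0, 1]", name)
  invisible(x)
}
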