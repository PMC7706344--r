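# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that simulation functions never leak
#' global state.
#'
#' @param seed integer seed (`NULL` leaves the RNG untouched).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific sub-seed from a base seed; kept within 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

stop_pheno <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "phenolidar_error")))
}

warn_pheno <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "phenolidar_warning")))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pheno(sprintf("`%s` must be a finite numeric scalar", name),
               "phenolidar_validation_error")
  }
  if (positive && x <= 0) {
    stop_pheno(sprintf("`%s` must be > 0 (got %g)", name, x),
               "phenolidar_validation_error")
  }
  if (nonneg && x < 0) {
    stop_pheno(sprintf("`%s` must be >= 0 (got %g)", name, x),
               "phenolidar_validation_error")
  }
  invisible(x)
}

#' FNV-1a hash of a character string
#'
#' 32-bit Fowler-Noll-Vo hash, used to stamp run outputs with a config
#' fingerprint.
#'
#' @param x a character scalar.
#' @return an 8-character lowercase hex string.
#' @keywords internal
#' @noRd
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  # 32-bit modular multiply in doubles (split into 16-bit halves so every
  # intermediate stays below 2^53)
  mulmod32 <- function(a, b) {
    a1 <- floor(a / 65536)
    a0 <- a %% 65536
    (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
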