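# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic given their `seed`
#' argument without clobbering the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483587) + 1L
}

#' FNV-1a hash of a character scalar
#'
#' Tiny stable string hash used to fingerprint configurations in output
#' metadata; not cryptographic.
#'
#' @param x Character scalar.
#' @return 8-character lowercase hex string.
#' @keywords internal
#' @noRd
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 16777619 * h mod 2^32, split so intermediates stay exact in a double
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(x) {
  fnv1a_hash(paste(deparse(x, control = "all"), collapse = "\n"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
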