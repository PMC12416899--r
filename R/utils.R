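# Seed derivation and small shared helpers.

#' Derive a child seed from a master seed
#'
#' Expands one master seed into reproducible per-stage / per-subject streams.
#' The derivation is a fixed integer hash (no RNG state consumed), so stages
#' can be recomputed independently and in any order. Results stay below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... further integers or strings naming the stream (stage name,
#'   subject index, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (p in parts) {
    if (is.character(p)) {
      for (ch in utf8ToInt(p)) h <- (h * 131 + ch) %% m
    } else {
      for (v in as.numeric(p)) h <- (h * 131 + (v %% m) + 17) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial hash of an R object's serialized bytes; used for provenance
# stamps (not cryptographic). The serialization header (which encodes the R
# version) is dropped so the stamp depends on content only.
#' @noRd
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  bytes <- bytes[-seq_len(14)]
  m <- 2^31 - 1
  h <- 17
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%010.0f", h)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)
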