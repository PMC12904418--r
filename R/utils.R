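#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Softplus and its inverse
#'
#' Smooth positive mapping used by the synthetic generator to carry a Gaussian
#' latent process onto the non-negative duration scale (hours).
#'
#' @param x numeric vector.
#' @return numeric vector.
#' @keywords internal
softplus <- function(x) {
  # log(1 + exp(x)) computed stably for large |x|
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' @rdname softplus
#' @keywords internal
softplus_inv <- function(x) {
  stopifnot(all(x > 0))
  ifelse(x > 30, x, log(expm1(pmax(x, 1e-12))))
}

#' Salted deterministic string hash
#'
#' Two independent polynomial rolling hashes over the salted UTF-8 bytes,
#' each modulo a prime below 2^26 so every intermediate product stays exact
#' in double precision; the pair gives ~52 bits, ample for injectivity on
#' cohort-sized id sets.
#'
#' @param x character vector to hash.
#' @param salt character scalar mixed into every hash.
#' @return character vector of pseudonyms, format `"p<hex>-<hex>"`.
#' @export
hash_id <- function(x, salt) {
  stopifnot(is.character(x), is.character(salt), length(salt) == 1L)
  p1 <- 67108859; p2 <- 67108837  # primes < 2^26
  m1 <- 131; m2 <- 137
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(paste0(salt, "\x1f", s)))
    h1 <- 0; h2 <- 0
    for (b in bytes) {
      h1 <- (h1 * m1 + b) %% p1
      h2 <- (h2 * m2 + b) %% p2
    }
    sprintf("p%07x-%07x", h1, h2)
  }, character(1), USE.NAMES = FALSE)
}

#' Parse HealthKit-style timestamps into a study timezone
#'
#' Timestamps like `"2024-04-01 23:10:00 +0200"` carry their own UTC offset;
#' they are parsed with that offset and re-expressed in the configured study
#' timezone so that clock-time rules (nightly windows) are local.
#'
#' @param x character vector of timestamps.
#' @param tz study timezone (Olson name).
#' @return POSIXct vector in `tz`.
#' @export
parse_hk_time <- function(x, tz = "Europe/Brussels") {
  out <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S %z", tz = tz)
  if (anyNA(out) && !all(is.na(x))) {
    bad <- x[is.na(out) & !is.na(x)]
    stop("unparseable timestamp(s): ", paste(utils::head(bad, 3), collapse = ", "))
  }
  out
}

# deterministic per-purpose sub-seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- as.integer(charToRaw(tag))
  h <- seed %% 2147483629
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# file content hash for provenance manifests (hex, 52 bits)
hash_file <- function(path) {
  stopifnot(file.exists(path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  p1 <- 67108859; p2 <- 67108837
  h1 <- 0; h2 <- 0
  ints <- as.integer(raw)
  # block the loop for speed: fold 512-byte chunks via vectorized Horner
  for (start in seq(1, length(ints), by = 512L)) {
    chunk <- ints[start:min(start + 511L, length(ints))]
    for (b in chunk) {
      h1 <- (h1 * 131 + b) %% p1
      h2 <- (h2 * 137 + b) %% p2
    }
  }
  sprintf("%07x%07x", h1, h2)
}
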