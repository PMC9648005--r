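#' @keywords internal
"_PACKAGE"

# Clamp values into [0, 1].
clamp01 <- function(x) pmin(1, pmax(0, x))

#' Derive a child RNG seed from a master seed
#'
#' Monte Carlo replicates, screen conditions and scorer targets each get a
#' deterministic child seed so that runs are reproducible and individual
#' conditions can be re-run in isolation. The derivation is a multiplicative
#' hash kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param k integer index (1-based) of the child stream.
#' @return an integer seed.
#' @export
derive_seed <- function(master, k) {
  master <- as.double(master %% 2147483647L)
  k <- as.double(k)
  as.integer((master * 48271 + k * 16807 + 12345) %% 2147483647)
}

# Tiny FNV-1a string hash used to stamp output files with a config fingerprint
# (no cryptographic intent; just a stable identifier).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Read a YAML or JSON config file depending on extension.
read_config_file <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
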