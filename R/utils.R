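#' @importFrom withr with_seed
NULL

# Hierarchical seed derivation: one user-facing seed fans out to
# per-stage/per-replicate streams. Lehmer-style mixing keeps results in
# [1, 2^31 - 2] so they are always valid arguments to set.seed().
deriveSeed <- function(seed, ...) {
  offs <- as.double(c(...))
  s <- as.double(seed %% 2147483646L) + 1
  for (o in offs) {
    s <- (s * 48271 + (o %% 2147483647) + 1) %% 2147483647
    if (s == 0) s <- 1
  }
  as.integer(s)
}

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertCount <- function(x, name, min = 1L) {
  if (length(x) < 1L || any(!is.finite(x)) || any(x != floor(x)) || any(x < min))
    .stopf("'%s' must be integer-valued and >= %d", name, min)
}

# Polynomial rolling hash (mod 2^31 - 1) of character input; used for run
# manifests so a rerun with the same configuration is recognisable.
.configHash <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
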