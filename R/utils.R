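# Shared internal helpers.

# Stable hash of an R object (config fingerprinting): serialize a canonical
# text rendering to a temp file and md5 it.
config_hash <- function(obj) {
  txt <- paste(deparse(obj, control = c("keepNA", "keepInteger")),
               collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

# Min-max normalization to [0, 1]; returns NULL for a degenerate
# (zero-range) series.
minmax_norm <- function(x) {
  r <- max(x) - min(x)
  # a range at floating-point noise level is degenerate, not signal
  if (r <= 1e-9 * max(abs(x), 1)) return(NULL)
  (x - min(x)) / r
}

# Derive a bounded child seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}
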