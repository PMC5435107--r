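#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: one master seed, one stream per
# purpose, so every stage of the pipeline is replay-exact while stages
# stay statistically independent. Constants are the Lehmer/Park-Miller
# multiplier and modulus; results stay below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  x <- (as.double(seed) %% m)
  for (k in c(stream, 12345)) {
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% m
  }
  as.integer(x)
}

# Locale-independent character ordering (byte order), used everywhere a
# character sort feeds an output file or a tie-break.
radix_order <- function(...) order(..., method = "radix")

# Collapse duplicated ancestral groups: entries sharing a non-missing
# group id contribute the group's (maximal) score once.
dedup_scores <- function(scores, groups) {
  if (is.null(groups)) return(scores)
  idx <- which(!is.na(groups) & nzchar(groups))
  if (length(idx) < 2L || !anyDuplicated(groups[idx])) return(scores)
  o <- idx[order(groups[idx], -scores[idx], method = "radix")]
  drop <- o[duplicated(groups[o])]
  scores[-drop]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
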