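# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

# Validate a samples x SVs numeric matrix.
.check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'", what, "' must be a numeric matrix (samples x SVs)")
  }
  if (is.null(rownames(counts))) {
    stop("'", what, "' must have sample ids as rownames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids in '", what, "'")
  }
  invisible(counts)
}
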