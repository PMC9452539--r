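# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

seq_chars <- function(seq) {
  strsplit(seq$residues, "", fixed = TRUE)[[1]]
}

reverse_residues <- function(residues) {
  paste(rev(strsplit(residues, "", fixed = TRUE)[[1]]), collapse = "")
}

DNA_BASES <- c("A", "C", "G", "T")
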