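# Seeded synthetic sequence generator with controllable class separation,
# plus the hand-checkable worked examples used in the regression tests.

#' Simulation specification
#'
#' Defines a synthetic two-layer dataset drawn i.i.d. per position from
#' class-specific nucleotide distributions. Non-enhancers are uniform
#' (0.25 each); enhancers shift probability mass towards G and C by
#' `effect`/4 per base, mimicking GC-rich regulatory signal; strong and weak
#' enhancers sit at `effect`/4 +/- `effect`/16 (a difference of `effect`/8),
#' with shifts clamped so probabilities stay in `[0, 0.5]`. `effect = 0`
#' makes all classes draws from one distribution; `effect = 1` makes the
#' class compositions maximally divergent. Defaults mirror the benchmark
#' shape: 1484 sequences per layer-1 class, an even strong/weak split and
#' 200 bp sequences.
#'
#' @param n_enhancer,n_non_enhancer Sequences per layer-1 class.
#' @param length Sequence length in bp (default 200).
#' @param effect Compositional divergence in `[0, 1]` (default 0.5).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_enhancer = 1484L, n_non_enhancer = 1484L,
                            length = 200L, effect = 0.5, seed = 7L) {
  stopifnot(is_count(n_enhancer), n_enhancer >= 2,
            is_count(n_non_enhancer), is_count(length), length >= 4,
            is.numeric(effect), length(effect) == 1L, effect >= 0, effect <= 1,
            is.numeric(seed), length(seed) == 1L, seed == as.integer(seed))
  structure(list(n_enhancer = as.integer(n_enhancer),
                 n_non_enhancer = as.integer(n_non_enhancer),
                 length = as.integer(length), effect = effect,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Per-class base probabilities in A, C, G, T order.
class_probabilities <- function(effect) {
  shift <- function(s) {
    s <- min(max(s, 0), 0.25)
    c(A = 0.25 - s, C = 0.25 + s, G = 0.25 + s, T = 0.25 - s)
  }
  list(non_enhancer = shift(0),
       weak = shift(effect / 4 - effect / 16),
       strong = shift(effect / 4 + effect / 16))
}

#' Simulate a labelled two-layer dataset
#'
#' @param spec A [simulation_spec()].
#' @return A [labeled_dataset()] with ids `strong_0001`, `weak_0001`,
#'   `non_0001`, ... Deterministic given the spec (the caller's RNG state is
#'   left untouched).
#' @examples
#' ds <- simulate_dataset(simulation_spec(n_enhancer = 10, n_non_enhancer = 10,
#'                                        effect = 1, seed = 1))
#' dataset_counts(ds)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  probs <- class_probabilities(spec$effect)
  n_strong <- ceiling(spec$n_enhancer / 2)
  n_weak <- spec$n_enhancer - n_strong
  draw <- function(n, p) {
    vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, spec$length, replace = TRUE, prob = p),
            collapse = "")
    }, "")
  }
  with_seed(spec$seed, {
    strong <- draw(n_strong, probs$strong)
    weak <- draw(n_weak, probs$weak)
    non <- draw(spec$n_non_enhancer, probs$non_enhancer)
  })
  mkseq <- function(prefix, residues) {
    lapply(seq_along(residues), function(i) {
      nucleotide_sequence(sprintf("%s_%04d", prefix, i), residues[[i]])
    })
  }
  labeled_dataset(
    c(mkseq("strong", strong), mkseq("weak", weak), mkseq("non", non)),
    layer1 = rep(c("enhancer", "non_enhancer"),
                 c(spec$n_enhancer, spec$n_non_enhancer)),
    layer2 = c(rep("strong", n_strong), rep("weak", n_weak),
               rep(NA_character_, spec$n_non_enhancer)))
}

#' Hand-checkable worked examples
#'
#' A fixed, immutable set of tiny sequences with their expected positional
#' vectors, PRIM rows and square reshapes, used as regression anchors.
#'
#' @return Named list; each entry has `seq` (a [nucleotide_sequence()]) plus
#'   expected values (`fdv`, `aapiv`, `raapiv`, and where stated `prim_rows`
#'   and `reshape`).
#' @export
worked_examples <- function() {
  ex <- list(
    ACGT = list(
      seq = nucleotide_sequence("ex_acgt", "ACGT"),
      fdv = c(A = 1, C = 1, G = 1, T = 1),
      aapiv = c(A = 1, C = 2, G = 3, T = 4),
      raapiv = c(A = 4, C = 3, G = 2, T = 1)),
    AACG = list(
      seq = nucleotide_sequence("ex_aacg", "AACG"),
      fdv = c(A = 2, C = 1, G = 1, T = 0),
      aapiv = c(A = 3, C = 3, G = 4, T = 0),
      raapiv = c(A = 7, C = 2, G = 1, T = 0),
      prim_rows = list(A = c(A = 1, C = 2, G = 3, T = 0),
                       C = c(A = -3, C = 0, G = 1, T = 0),
                       T = c(A = 0, C = 0, G = 0, T = 0))),
    AAAA = list(
      seq = nucleotide_sequence("ex_aaaa", "AAAA"),
      fdv = c(A = 4, C = 0, G = 0, T = 0),
      aapiv = c(A = 10, C = 0, G = 0, T = 0),
      raapiv = c(A = 10, C = 0, G = 0, T = 0)),
    ACGTACGTA = list(
      seq = nucleotide_sequence("ex_acgtacgta", "ACGTACGTA"),
      fdv = c(A = 3, C = 2, G = 2, T = 2),
      aapiv = c(A = 15, C = 8, G = 10, T = 12),
      raapiv = c(A = 15, C = 12, G = 10, T = 8),
      reshape = matrix(c(1, 2, 3, 4, 1, 2, 3, 4, 1), nrow = 3, byrow = TRUE)),
    ACGT50 = list(
      seq = nucleotide_sequence("ex_acgt50", strrep("ACGT", 50)),
      fdv = c(A = 50, C = 50, G = 50, T = 50),
      reshape_dim = 15L)
  )
  ex
}
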