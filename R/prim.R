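# Position-relative incidence matrices (forward and reverse).

all_kmers <- function(order) {
  if (order == 1L) return(DNA_BASES)
  g <- do.call(expand.grid,
               c(rep(list(DNA_BASES), order), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic order
  sort(do.call(paste0, g[, rev(seq_len(order)), drop = FALSE]))
}

#' Position-relative incidence matrix of a sequence
#'
#' Tokenises the sequence into overlapping k-mers (step 1) of length `order`
#' and accumulates, for every ordered symbol pair (x, y), the signed
#' positional offsets of all occurrences of y relative to the first
#' occurrence of x:
#' \deqn{entry(x, y) = \sum_{p \in occ(y)} (p - f(x))}
#' with 1-based token positions and f(x) the first occurrence of x. Rows for
#' symbols absent from the sequence are zero. `direction = "reverse"`
#' applies the same rule to the reversed residue string.
#'
#' @param seq A [nucleotide_sequence()].
#' @param order k-mer order: 1 (mono-), 2 (di-) or 3 (trinucleotide).
#' @param direction `"forward"` or `"reverse"`.
#' @return A 4^order x 4^order numeric matrix with k-mer dimnames
#'   (class `prim_matrix`; attributes `order` and `direction`).
#' @examples
#' prim_matrix(nucleotide_sequence("s", "AACG"))["A", ]
#' @export
prim_matrix <- function(seq, order = 1L, direction = c("forward", "reverse")) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  direction <- match.arg(direction)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3", call. = FALSE)
  residues <- seq$residues
  if (direction == "reverse") residues <- reverse_residues(residues)
  n <- nchar(residues)
  if (n < order) {
    stop("sequence '", seq$id, "' is shorter than the k-mer order ", order,
         call. = FALSE)
  }
  n_tok <- n - order + 1L
  tokens <- substring(residues, seq_len(n_tok), order:n)
  syms <- all_kmers(order)
  K <- length(syms)
  idx <- match(tokens, syms)
  pos <- seq_len(n_tok)
  cnt <- tabulate(idx, nbins = K)
  pos_sum <- numeric(K)
  agg <- rowsum(pos, idx)
  pos_sum[as.integer(rownames(agg))] <- agg[, 1L]
  first <- rep(NA_real_, K)
  lead <- !duplicated(idx)
  first[idx[lead]] <- pos[lead]
  m <- matrix(pos_sum, nrow = K, ncol = K, byrow = TRUE) - outer(first, cnt)
  m[is.na(first), ] <- 0
  dimnames(m) <- list(syms, syms)
  structure(m, order = order, direction = direction, class = c("prim_matrix", "matrix"))
}

#' Forward/reverse PRIM moment block of a sequence
#'
#' The 30-moment block (raw, central, Hahn) of the forward order-1 PRIM
#' followed by the same block for the reverse-direction PRIM: 60 values.
#' The Hahn basis is built at N = 4.
#'
#' @param seq A [nucleotide_sequence()].
#' @param hahn_x,hahn_y Hahn shape parameters (default 0).
#' @return Named numeric vector of 60 values (`prim_raw_00` ...
#'   `rprim_hahn_03`).
#' @export
prim_moment_block <- function(seq, hahn_x = 0, hahn_y = 0) {
  fwd <- moment_block(unclass_matrix(prim_matrix(seq, 1L, "forward")),
                      hahn_x, hahn_y)
  rev <- moment_block(unclass_matrix(prim_matrix(seq, 1L, "reverse")),
                      hahn_x, hahn_y)
  stats::setNames(c(fwd, rev),
                  c(paste0("prim_", names(fwd)), paste0("rprim_", names(rev))))
}

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Dataset-level PRIM heatmap table
#'
#' Elementwise sum of the per-sequence PRIM matrices of a dataset at a given
#' k-mer order — the matrix underlying the composition heatmaps. Written to
#' TSV with [write_prim_table()] if needed.
#'
#' @param dataset A [labeled_dataset()].
#' @param order k-mer order (1, 2 or 3).
#' @param direction `"forward"` or `"reverse"`.
#' @return A 4^order x 4^order labelled numeric matrix.
#' @export
prim_heatmap_table <- function(dataset, order = 1L, direction = "forward") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset$sequences) == 0L) stop("empty dataset", call. = FALSE)
  mats <- lapply(dataset$sequences, prim_matrix, order = order,
                 direction = direction)
  out <- Reduce(`+`, lapply(mats, unclass_matrix))
  dimnames(out) <- dimnames(mats[[1L]])
  out
}

#' Write a PRIM heatmap table as TSV
#'
#' @param table Matrix from [prim_heatmap_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prim_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
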