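#' Validated DNA sequence
#'
#' Constructs a single DNA sequence record over the strict four-letter
#' alphabet A/C/G/T. Residues are upper-cased; ambiguity codes (N, R, Y, ...)
#' are rejected rather than imputed. Sequences shorter than 4 residues are
#' rejected because the square-matrix reshape and the positional features are
#' not meaningful below that length.
#'
#' @param id Record identifier (single string).
#' @param residues Residue string; case-insensitive, A/C/G/T only.
#' @return An object of class `nucleotide_sequence` with fields `id`,
#'   `residues` and `length`.
#' @examples
#' nucleotide_sequence("s1", "acgt")
#' @export
nucleotide_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 4L) {
    stop("sequence '", id, "' is shorter than 4 residues (length ",
         nchar(residues), ")", call. = FALSE)
  }
  bad <- regmatches(residues, regexpr("[^ACGT]", residues))
  if (length(bad) > 0L) {
    stop("sequence '", id, "' contains non-ACGT character '", bad, "'",
         call. = FALSE)
  }
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "nucleotide_sequence")
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  res <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat("<nucleotide_sequence> ", x$id, " (", x$length, " bp): ", res, "\n", sep = "")
  invisible(x)
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file and validates every
#' record against the strict A/C/G/T alphabet. Headers may be arbitrary; the
#' identifier is the first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @param policy `"strict"` aborts on the first record containing a non-ACGT
#'   character (or shorter than 4 bp); `"skip_invalid"` drops such records and
#'   reports how many were skipped.
#' @return A list of [nucleotide_sequence()] objects, in file order.
#' @export
read_fasta <- function(path, policy = c("strict", "skip_invalid")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  residues <- toupper(as.character(set))
  out <- vector("list", length(set))
  skipped <- 0L
  for (k in seq_along(set)) {
    rec <- tryCatch(nucleotide_sequence(ids[[k]], residues[[k]]), error = identity)
    if (inherits(rec, "error")) {
      if (policy == "strict") stop(conditionMessage(rec), call. = FALSE)
      skipped <- skipped + 1L
    } else {
      out[[k]] <- rec
    }
  }
  if (skipped > 0L) {
    message("read_fasta: skipped ", skipped, " invalid record",
            if (skipped > 1L) "s", " in ", path)
  }
  Filter(Negate(is.null), out)
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences A list of [nucleotide_sequence()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(length(sequences) > 0L)
  set <- Biostrings::DNAStringSet(vapply(sequences, `[[`, "", "residues"))
  names(set) <- vapply(sequences, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Two-layer labelled dataset
#'
#' Bundles sequences with their layer-1 label (enhancer vs. non-enhancer) and,
#' for enhancers, a layer-2 strength label (strong / weak / unknown). The
#' dataset mirrors the two-level set structure D = D+ \eqn{\cup} D-,
#' D+ = D+strong \eqn{\cup} D+weak.
#'
#' @param sequences List of [nucleotide_sequence()] objects with unique ids.
#' @param layer1 Character or factor, one of `"enhancer"`/`"non_enhancer"` per
#'   sequence.
#' @param layer2 Optional character or factor per sequence: `"strong"`,
#'   `"weak"` or `"unknown"` for enhancers, `NA` for non-enhancers. Defaults
#'   to `"unknown"` for every enhancer.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, layer1, layer2 = NULL) {
  stopifnot(is.list(sequences), length(sequences) > 0L)
  ids <- vapply(sequences, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  layer1 <- factor(as.character(layer1), levels = c("non_enhancer", "enhancer"))
  stopifnot(length(layer1) == length(sequences), !anyNA(layer1))
  if (is.null(layer2)) {
    layer2 <- ifelse(layer1 == "enhancer", "unknown", NA_character_)
  }
  layer2 <- factor(as.character(layer2), levels = c("weak", "strong", "unknown"))
  stopifnot(length(layer2) == length(sequences))
  if (any(!is.na(layer2) & layer1 == "non_enhancer")) {
    stop("layer-2 labels are only defined for enhancer sequences", call. = FALSE)
  }
  if (any(is.na(layer2) & layer1 == "enhancer")) {
    stop("every enhancer needs a layer-2 label (use 'unknown')", call. = FALSE)
  }
  lens <- vapply(sequences, `[[`, 0L, "length")
  if (length(unique(lens)) > 1L) {
    warning("heterogeneous sequence lengths (", min(lens), "-", max(lens),
            " bp); the square-matrix reshape adapts per sequence", call. = FALSE)
  }
  structure(list(sequences = sequences, ids = ids,
                 layer1 = layer1, layer2 = layer2),
            class = "labeled_dataset")
}

#' Per-class sequence counts of a labelled dataset
#'
#' @param dataset A [labeled_dataset()].
#' @return Named integer vector with components `non_enhancer`, `enhancer`,
#'   `strong`, `weak` and `unknown`.
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  l2 <- table(dataset$layer2[dataset$layer1 == "enhancer"])
  c(non_enhancer = sum(dataset$layer1 == "non_enhancer"),
    enhancer = sum(dataset$layer1 == "enhancer"),
    strong = unname(l2[["strong"]]),
    weak = unname(l2[["weak"]]),
    unknown = unname(l2[["unknown"]]))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  ct <- dataset_counts(x)
  cat("<labeled_dataset> ", length(x$sequences), " sequences: ",
      ct[["enhancer"]], " enhancers (", ct[["strong"]], " strong / ",
      ct[["weak"]], " weak / ", ct[["unknown"]], " unknown), ",
      ct[["non_enhancer"]], " non-enhancers\n", sep = "")
  invisible(x)
}

#' Load a two-layer dataset from per-class FASTA files
#'
#' Labels are assigned by file grouping, mirroring how the benchmark data is
#' organised: one file of enhancers, one of non-enhancers, and optionally one
#' each of strong and weak enhancers. Strong/weak membership is matched by
#' record id against the enhancer file; if `enhancer_source` is `NULL`, the
#' enhancer set is taken as the union of the strong and weak files.
#'
#' @param enhancer_source Path to the enhancer FASTA (or `NULL`, see above).
#' @param non_enhancer_source Path to the non-enhancer FASTA.
#' @param strong_source,weak_source Optional paths to strong/weak enhancer
#'   FASTA files.
#' @param policy Validation policy passed to [read_fasta()].
#' @return A [labeled_dataset()]; per-class totals are reported via `message`.
#' @export
load_dataset <- function(enhancer_source = NULL, non_enhancer_source,
                         strong_source = NULL, weak_source = NULL,
                         policy = "strict") {
  strong <- if (!is.null(strong_source)) read_fasta(strong_source, policy)
  weak <- if (!is.null(weak_source)) read_fasta(weak_source, policy)
  if (xor(is.null(strong), is.null(weak))) {
    stop("provide both strong_source and weak_source, or neither", call. = FALSE)
  }
  strong_ids <- vapply(strong %||% list(), `[[`, "", "id")
  weak_ids <- vapply(weak %||% list(), `[[`, "", "id")
  clash <- intersect(strong_ids, weak_ids)
  if (length(clash) > 0L) {
    stop("label conflict: id(s) present in both strong and weak sources: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(enhancer_source)) {
    if (is.null(strong)) {
      stop("enhancer_source is required when strong/weak sources are absent",
           call. = FALSE)
    }
    enh <- c(strong, weak)
  } else {
    enh <- read_fasta(enhancer_source, policy)
  }
  non <- read_fasta(non_enhancer_source, policy)
  enh_ids <- vapply(enh, `[[`, "", "id")
  non_ids <- vapply(non, `[[`, "", "id")
  dup <- intersect(enh_ids, non_ids)
  if (length(dup) > 0L) {
    stop("duplicate id(s) across enhancer and non-enhancer sources: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  layer2 <- rep(NA_character_, length(enh) + length(non))
  if (!is.null(strong)) {
    missing <- setdiff(c(strong_ids, weak_ids), enh_ids)
    if (length(missing) > 0L) {
      stop("strong/weak id(s) absent from the enhancer set: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    l2 <- rep("unknown", length(enh))
    l2[enh_ids %in% strong_ids] <- "strong"
    l2[enh_ids %in% weak_ids] <- "weak"
    layer2[seq_along(enh)] <- l2
  } else {
    layer2[seq_along(enh)] <- "unknown"
  }
  ds <- labeled_dataset(c(enh, non),
                        layer1 = rep(c("enhancer", "non_enhancer"),
                                     c(length(enh), length(non))),
                        layer2 = layer2)
  ct <- dataset_counts(ds)
  message("load_dataset: ", ct[["enhancer"]], " enhancers (",
          ct[["strong"]], " strong, ", ct[["weak"]], " weak), ",
          ct[["non_enhancer"]], " non-enhancers")
  ds
}

#' Read a two-column tab-separated label map
#'
#' @param path Path to a TSV file with columns `id` and `label` (no header).
#'   Valid labels: `enhancer`, `non_enhancer`, `strong`, `weak` (the last two
#'   imply enhancer).
#' @return Named character vector of labels keyed by id.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("label map not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  ok <- c("enhancer", "non_enhancer", "strong", "weak")
  bad <- setdiff(unique(tab$label), ok)
  if (length(bad) > 0L) {
    stop("unknown label(s) in map: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$id)) stop("duplicate ids in label map", call. = FALSE)
  stats::setNames(tab$label, tab$id)
}

#' Load a labelled dataset from a single FASTA plus a label map
#'
#' @param fasta_source Path to a FASTA file containing all sequences.
#' @param label_map Either a path to a TSV label map (see [read_label_map()])
#'   or a named character vector of labels keyed by id.
#' @param policy Validation policy passed to [read_fasta()].
#' @return A [labeled_dataset()].
#' @export
load_dataset_map <- function(fasta_source, label_map, policy = "strict") {
  seqs <- read_fasta(fasta_source, policy)
  if (is.character(label_map) && length(label_map) == 1L && is.null(names(label_map))) {
    label_map <- read_label_map(label_map)
  }
  ids <- vapply(seqs, `[[`, "", "id")
  missing <- setdiff(ids, names(label_map))
  if (length(missing) > 0L) {
    stop("no label for id(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  lab <- unname(label_map[ids])
  layer1 <- ifelse(lab == "non_enhancer", "non_enhancer", "enhancer")
  layer2 <- ifelse(lab %in% c("strong", "weak"), lab,
                   ifelse(lab == "enhancer", "unknown", NA_character_))
  labeled_dataset(seqs, layer1, layer2)
}

#' Write a labelled dataset back to per-class FASTA files
#'
#' Produces `enhancers.fasta` and `non_enhancers.fasta`, plus `strong.fasta`
#' and `weak.fasta` when strength labels are present, matching the
#' [load_dataset()] convention so that a written dataset re-reads losslessly.
#'
#' @param dataset A [labeled_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enh <- dataset$layer1 == "enhancer"
  paths <- c(enhancers = file.path(dir, "enhancers.fasta"),
             non_enhancers = file.path(dir, "non_enhancers.fasta"))
  write_fasta(dataset$sequences[enh], paths[["enhancers"]])
  write_fasta(dataset$sequences[!enh], paths[["non_enhancers"]])
  strong <- enh & dataset$layer2 == "strong"
  weak <- enh & dataset$layer2 == "weak"
  strong[is.na(strong)] <- FALSE
  weak[is.na(weak)] <- FALSE
  if (any(strong) && any(weak)) {
    paths <- c(paths, strong = file.path(dir, "strong.fasta"),
               weak = file.path(dir, "weak.fasta"))
    write_fasta(dataset$sequences[strong], paths[["strong"]])
    write_fasta(dataset$sequences[weak], paths[["weak"]])
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
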