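# Assembly of the 102-dimensional super feature vector and feature tables.

#' Feature extraction configuration
#'
#' Collects the tunable choices of the feature pipeline: the
#' nucleotide-to-integer encoding (the single most consequential choice, since
#' every numeric moment depends on it), the Hahn shape parameters, and whether
#' the composition block is normalised.
#'
#' @param encoding Named map of A, C, G, T to distinct positive integers
#'   (default alphabetical 1..4).
#' @param hahn_x,hahn_y Non-negative Hahn shape parameters (default 0).
#' @param normalize_fdv Divide the FDV block by sequence length (default
#'   `FALSE`; the pipeline mixes unnormalised quantities).
#' @return Object of class `sfv_config`.
#' @export
sfv_config <- function(encoding = c(A = 1, C = 2, G = 3, T = 4),
                       hahn_x = 0, hahn_y = 0, normalize_fdv = FALSE) {
  check_encoding(encoding)
  stopifnot(is.numeric(hahn_x), hahn_x >= 0, is.numeric(hahn_y), hahn_y >= 0,
            is.logical(normalize_fdv))
  structure(list(encoding = encoding[DNA_BASES], hahn_x = hahn_x,
                 hahn_y = hahn_y, normalize_fdv = normalize_fdv),
            class = "sfv_config")
}

#' Block boundaries of the super feature vector
#'
#' The fixed layout is `seq_moments[30]`, `prim_moments[30]`,
#' `rprim_moments[30]`, `fdv[4]`, `aapiv[4]`, `raapiv[4]`.
#'
#' @return Named integer vector of cumulative end positions
#'   (30, 60, 90, 94, 98, 102).
#' @export
sfv_block_bounds <- function() {
  cumsum(c(seq_moments = 30L, prim_moments = 30L, rprim_moments = 30L,
           fdv = 4L, aapiv = 4L, raapiv = 4L))
}

#' Super feature vector of one sequence
#'
#' Concatenates, in fixed order: the 30-moment block of the row-major
#' sequence matrix (encoded residues, zero-padded d x d reshape), the
#' 30-moment blocks of the forward and reverse order-1 position-relative
#' incidence matrices, and the FDV / AAPIV / RAAPIV positional vectors.
#' Deterministic given sequence and configuration.
#'
#' @param seq A [nucleotide_sequence()].
#' @param config An [sfv_config()].
#' @return Named numeric vector of 102 finite values.
#' @examples
#' v <- super_feature_vector(nucleotide_sequence("s", strrep("ACGT", 50)))
#' length(v)
#' @export
super_feature_vector <- function(seq, config = sfv_config()) {
  stopifnot(inherits(seq, "nucleotide_sequence"), inherits(config, "sfv_config"))
  out <- tryCatch({
    series <- encode_sequence(seq, config$encoding)
    m <- reshape_to_square(series)
    seq_block <- moment_block(m, config$hahn_x, config$hahn_y)
    names(seq_block) <- paste0("seq_", names(seq_block))
    pos_block <- c(fdv(seq, normalize = config$normalize_fdv), aapiv(seq),
                   raapiv(seq))
    names(pos_block) <- paste(rep(c("fdv", "aapiv", "raapiv"), each = 4L),
                              DNA_BASES, sep = "_")
    c(seq_block,
      prim_moment_block(seq, config$hahn_x, config$hahn_y),
      pos_block)
  }, error = function(e) {
    stop("feature extraction failed for sequence '", seq$id, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (any(!is.finite(out))) {
    stop("non-finite feature value for sequence '", seq$id, "'", call. = FALSE)
  }
  out
}

#' Extract a feature table from a labelled dataset
#'
#' One 102-value super feature vector per sequence, in dataset order, with
#' ids and both label layers. Extraction provenance (encoding, Hahn
#' parameters, package version) is attached as the `provenance` attribute and
#' written into the header by [write_feature_table()].
#'
#' @param dataset A [labeled_dataset()].
#' @param config An [sfv_config()].
#' @return A `feature_table` (data.frame with columns `id`, `layer1`,
#'   `layer2` followed by the 102 feature columns).
#' @export
extract_dataset <- function(dataset, config = sfv_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset$sequences) == 0L) stop("empty dataset", call. = FALSE)
  feats <- t(vapply(dataset$sequences, super_feature_vector,
                    numeric(102L), config = config))
  tab <- data.frame(id = dataset$ids, layer1 = dataset$layer1,
                    layer2 = dataset$layer2, feats,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  attr(tab, "provenance") <- list(
    encoding = paste(names(config$encoding), config$encoding,
                     sep = "=", collapse = ","),
    hahn_x = config$hahn_x, hahn_y = config$hahn_y,
    normalize_fdv = config$normalize_fdv, prim_orders = 1L,
    package_version = as.character(utils::packageVersion("enhancerRF")))
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Numeric feature matrix of a feature table
#'
#' @param table A `feature_table` from [extract_dataset()] (or any data.frame
#'   with `id`, `layer1`, `layer2` followed by feature columns).
#' @return Numeric matrix with ids as rownames.
#' @export
feature_matrix <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("id", "layer1", "layer2") %in% names(table)))
  m <- as.matrix(table[, setdiff(names(table), c("id", "layer1", "layer2")),
                       drop = FALSE])
  rownames(m) <- table$id
  m
}

#' Write / read a feature table as annotated TSV
#'
#' The TSV carries extraction provenance in leading `#`-prefixed header
#' lines, then one row per sequence.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @return `write_feature_table`: `path`, invisibly. `read_feature_table`:
#'   a `feature_table` with the provenance attribute restored.
#' @export
write_feature_table <- function(table, path) {
  prov <- attr(table, "provenance")
  hdr <- vapply(names(prov), function(k) paste0("# ", k, ": ", prov[[k]]), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  prov <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    prov[[key]] <- sub("^[^:]*: ", "", kv)
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  tab$layer1 <- factor(tab$layer1, levels = c("non_enhancer", "enhancer"))
  tab$layer2 <- factor(tab$layer2, levels = c("weak", "strong", "unknown"))
  attr(tab, "provenance") <- prov
  class(tab) <- c("feature_table", "data.frame")
  tab
}
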