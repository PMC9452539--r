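# Two-layer random-forest cascade with OOB tracking and tree-count tuning.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 100, the tuned operating point;
#'   forests beyond ~100 trees add little accuracy but grow the model).
#' @param search_space Integer range `c(lower, upper)` searched by
#'   [tune_n_estimators()] (default 5-500).
#' @param seed Integer seed making every fit reproducible.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, search_space = c(5L, 500L), seed = 7L) {
  stopifnot(is_count(n_trees), length(search_space) == 2L,
            is_count(search_space[1L]), is_count(search_space[2L]),
            search_space[1L] <= search_space[2L], is_count(abs(seed) + 1))
  structure(list(n_trees = as.integer(n_trees),
                 search_space = as.integer(search_space),
                 seed = as.integer(seed)),
            class = "forest_config")
}

layer_training_data <- function(table, layer) {
  x <- feature_matrix(table)
  if (layer == 1L) {
    y <- factor(table$layer1, levels = c("non_enhancer", "enhancer"))
  } else if (layer == 2L) {
    keep <- table$layer1 == "enhancer" & table$layer2 %in% c("weak", "strong")
    dropped <- sum(table$layer1 == "enhancer") - sum(keep)
    if (dropped > 0L) {
      warning(dropped, " enhancer row(s) with unknown strength excluded from layer 2",
              call. = FALSE)
    }
    x <- x[keep, , drop = FALSE]
    y <- factor(table$layer2[keep], levels = c("weak", "strong"))
  } else {
    stop("layer must be 1 or 2", call. = FALSE)
  }
  if (nlevels(droplevels(y)) < 2L) {
    stop("layer ", layer, " training data contains a single class", call. = FALSE)
  }
  list(x = x, y = y)
}

positive_class <- function(layer) if (layer == 1L) "enhancer" else "strong"

fit_forest <- function(x, y, n_trees, seed) {
  with_seed(seed, randomForest::randomForest(x = x, y = y, ntree = n_trees))
}

#' Train one layer of the cascade
#'
#' Fits a bootstrap-aggregated forest with random feature subsetting at each
#' split (`mtry = floor(sqrt(p))`, the classification default) and records
#' the out-of-bag error at the final tree count. Layer 2 trains on true
#' enhancers with known strong/weak labels only.
#'
#' @param table A `feature_table` from [extract_dataset()].
#' @param layer 1 (enhancer vs. non-enhancer) or 2 (strong vs. weak).
#' @param config A [forest_config()].
#' @return Object of class `fitted_layer` with fields `layer`, `forest`,
#'   `oob_error`, `config`, `feature_names` and `provenance`. With a single
#'   tree the OOB error covers only the out-of-bag rows of that tree and may
#'   be `NaN`.
#' @export
train_layer <- function(table, layer, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  dat <- layer_training_data(table, layer)
  rf <- fit_forest(dat$x, dat$y, config$n_trees, config$seed)
  oob <- unname(rf$err.rate[config$n_trees, "OOB"])
  structure(list(layer = as.integer(layer), forest = rf,
                 oob_error = oob, config = config,
                 feature_names = colnames(dat$x),
                 provenance = list(mtry = rf$mtry,
                                   n_trees = config$n_trees,
                                   seed = config$seed,
                                   n_train = nrow(dat$x),
                                   feature_layout = paste0(
                                     "sfv", length(colnames(dat$x))))),
            class = "fitted_layer")
}

#' @export
print.fitted_layer <- function(x, ...) {
  cat("<fitted_layer> layer ", x$layer, ": ", x$config$n_trees, " trees, OOB error ",
      format(x$oob_error, digits = 4), " (n = ", x$provenance$n_train, ")\n",
      sep = "")
  invisible(x)
}

#' Train the full two-layer cascade
#'
#' @param table A `feature_table`.
#' @param config A [forest_config()].
#' @return Object of class `cascade_model` with fields `layer1` and `layer2`.
#' @export
train_cascade <- function(table, config = forest_config()) {
  structure(list(layer1 = train_layer(table, 1L, config),
                 layer2 = train_layer(table, 2L, config)),
            class = "cascade_model")
}

#' Out-of-bag error as a function of tree count
#'
#' One forest is grown to the largest requested count; the OOB error recorded
#' at the addition of each tree is read off at the requested counts, so all
#' points share one seed and bootstrap stream. Supports the inspection that
#' the error stabilises near 100 trees.
#'
#' @param table A `feature_table`.
#' @param layer 1 or 2.
#' @param tree_counts Ascending integer vector of tree counts.
#' @param config A [forest_config()].
#' @return data.frame with columns `n_trees` and `oob_error`.
#' @export
oob_curve <- function(table, layer, tree_counts, config = forest_config()) {
  stopifnot(length(tree_counts) >= 1L, all(diff(tree_counts) > 0),
            all(tree_counts >= 1))
  dat <- layer_training_data(table, layer)
  rf <- fit_forest(dat$x, dat$y, max(tree_counts), config$seed)
  data.frame(n_trees = as.integer(tree_counts),
             oob_error = unname(rf$err.rate[tree_counts, "OOB"]))
}

#' Tune the tree count by successive halving
#'
#' Candidate tree counts are spread geometrically over the configured search
#' space. Each rung evaluates the surviving candidates on a stratified
#' fraction of the training data (the fraction doubles per rung, reaching the
#' full set at the last rung) using out-of-bag error as the criterion, and
#' eliminates the worse half (ties break towards fewer trees).
#'
#' @param table A `feature_table`.
#' @param layer 1 or 2.
#' @param config A [forest_config()]; `config$search_space` defines the range.
#' @param n_candidates Number of candidate counts (default 8).
#' @return The winning tree count (integer).
#' @export
tune_n_estimators <- function(table, layer, config = forest_config(),
                              n_candidates = 8L) {
  lo <- config$search_space[1L]
  hi <- config$search_space[2L]
  cand <- unique(pmin(hi, pmax(lo, round(exp(
    seq(log(lo), log(hi), length.out = n_candidates))))))
  if (length(cand) == 1L) return(as.integer(cand))
  dat <- layer_training_data(table, layer)
  n <- nrow(dat$x)
  rungs <- ceiling(log2(length(cand)))
  for (r in seq_len(rungs)) {
    frac <- 1 / 2^(rungs - r)
    idx <- if (frac >= 1) seq_len(n) else {
      with_seed(config$seed + r, {
        unlist(lapply(split(seq_len(n), dat$y), function(ix) {
          take <- max(2L, floor(length(ix) * frac))
          sample(ix, take)
        }), use.names = FALSE)
      })
    }
    scores <- vapply(cand, function(nt) {
      rf <- fit_forest(dat$x[idx, , drop = FALSE], dat$y[idx], nt,
                       config$seed + r)
      unname(rf$err.rate[nt, "OOB"])
    }, 0)
    keep <- order(scores, cand)[seq_len(max(1L, ceiling(length(cand) / 2)))]
    cand <- sort(cand[keep])
    if (length(cand) == 1L) break
  }
  as.integer(cand[1L])
}

check_layout <- function(model_features, x) {
  if (identical(colnames(x), model_features)) return(invisible(TRUE))
  diff_at <- which(!(colnames(x) == model_features[seq_len(ncol(x))]))[1L]
  if (is.na(diff_at)) diff_at <- min(ncol(x), length(model_features)) + 1L
  bounds <- sfv_block_bounds()
  block <- names(bounds)[which(diff_at <= bounds)[1L]]
  stop("feature layout mismatch at column ", diff_at,
       if (!is.na(block)) paste0(" (block '", block, "')"), call. = FALSE)
}

newdata_matrix <- function(newdata) {
  if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
}

#' Predict with a single fitted layer
#'
#' @param object A `fitted_layer`.
#' @param newdata A `feature_table` or numeric feature matrix.
#' @param ... Unused.
#' @return data.frame with columns `id`, `score` (class-vote fraction of the
#'   positive class) and `label`.
#' @export
predict.fitted_layer <- function(object, newdata, ...) {
  x <- newdata_matrix(newdata)
  check_layout(object$feature_names, x)
  pos <- positive_class(object$layer)
  prob <- stats::predict(object$forest, x, type = "prob")[, pos]
  neg <- setdiff(object$forest$classes, pos)
  data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
             score = unname(prob),
             label = ifelse(prob >= 0.5, pos, neg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict with the two-layer cascade
#'
#' `"layers_separate"` returns each layer's predictions independently (layer
#' 2 is meaningful for true or putative enhancers). `"cascade"` applies layer
#' 2 only to layer-1 positives (vote fraction >= 0.5) and returns one of
#' `non_enhancer`, `weak_enhancer`, `strong_enhancer`.
#'
#' @param object A `cascade_model`.
#' @param newdata A `feature_table` or numeric feature matrix.
#' @param mode `"layers_separate"` (default) or `"cascade"`.
#' @param ... Unused.
#' @return `layers_separate`: list with `layer1` and `layer2` data.frames.
#'   `cascade`: data.frame with `id`, `label`, `layer1_score`, `layer2_score`
#'   (`NA` when layer 2 is not consulted).
#' @export
predict.cascade_model <- function(object, newdata,
                                  mode = c("layers_separate", "cascade"), ...) {
  mode <- match.arg(mode)
  x <- newdata_matrix(newdata)
  p1 <- predict(object$layer1, x)
  p2 <- predict(object$layer2, x)
  if (mode == "layers_separate") {
    return(list(layer1 = p1, layer2 = p2))
  }
  is_enh <- p1$score >= 0.5
  data.frame(id = p1$id,
             label = ifelse(!is_enh, "non_enhancer",
                            ifelse(p2$score >= 0.5, "strong_enhancer",
                                   "weak_enhancer")),
             layer1_score = p1$score,
             layer2_score = ifelse(is_enh, p2$score, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Save / load a cascade model
#'
#' The model is serialised with `saveRDS`; a JSON sidecar records training
#' provenance (tree counts, seeds, OOB errors, feature layout) for human
#' inspection.
#'
#' @param model A `cascade_model`.
#' @param dir Output directory (created if needed).
#' @return `save_model`: `dir`, invisibly. `load_model`: the restored
#'   `cascade_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "cascade_model.rds"))
  sidecar <- list(
    layer1 = model$layer1$provenance,
    layer2 = model$layer2$provenance,
    oob_error = list(layer1 = model$layer1$oob_error,
                     layer2 = model$layer2$oob_error))
  jsonlite::write_json(sidecar, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "cascade_model.rds")
  if (!file.exists(path)) stop("no saved model in ", dir, call. = FALSE)
  readRDS(path)
}
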