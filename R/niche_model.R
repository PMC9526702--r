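#' Random-forest configuration
#'
#' @param n_trees number of trees (default 200).
#' @param purity_stop node-purity stopping fraction in (0.5, 1]: a node
#'   stops splitting once its majority class reaches this share of the node
#'   (default 0.95). `1.0` grows trees to purity.
#' @param features_per_split candidate features per split; default
#'   `floor(sqrt(p))`.
#' @param train_frac stratified training fraction (default 0.8).
#' @param split_by `"region"` keeps technical duplicates of the same
#'   patient-niche region in one fold (no leakage, the default) or
#'   `"sample"` splits individual columns.
#' @param zscore_training if `TRUE` (default) the reference matrix is
#'   z-scored per sample with the same transform applied to bulk cohorts,
#'   so training and application scales match.
#' @param seed master seed; per-tree seeds are derived from it.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200L, purity_stop = 0.95,
                          features_per_split = NULL, train_frac = 0.8,
                          split_by = c("region", "sample"),
                          zscore_training = TRUE, seed = 1L) {
  if (length(features_per_split) == 0) features_per_split <- NULL
  stopifnot(n_trees >= 1, purity_stop > 0.5, purity_stop <= 1,
            train_frac > 0, train_frac < 1)
  split_by <- match.arg(split_by)
  structure(list(n_trees = as.integer(n_trees), purity_stop = purity_stop,
                 features_per_split = features_per_split,
                 train_frac = train_frac, split_by = split_by,
                 zscore_training = zscore_training, seed = as.integer(seed)),
            class = "forest_config")
}

#' Stratified train/test split of labelled samples
#'
#' Per niche, `ceiling(train_frac * n)` units go to training and the rest to
#' testing; the two sets are disjoint and exhaustive. With
#' `group_of_sample` given (e.g. patient-region ids), whole units are kept
#' together so technical duplicates never straddle the split.
#'
#' @param labels named character/factor vector: sample id -> niche label.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @param group_of_sample optional named vector mapping sample ids to split
#'   units (duplicates of one region share a unit).
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L,
                             group_of_sample = NULL) {
  stopifnot(train_frac > 0, train_frac < 1)
  ids <- names(labels)
  if (is.null(group_of_sample)) group_of_sample <- stats::setNames(ids, ids)
  units <- unique(group_of_sample[ids])
  unit_label <- stats::setNames(
    as.character(labels[match(units, group_of_sample[ids])]), units)
  set.seed(seed)
  train_units <- character()
  for (lv in unique(unit_label)) {
    u <- units[unit_label == lv]
    if (length(u) < 2) stop("niche '", lv, "' has < 2 units; cannot split")
    n_tr <- ceiling(train_frac * length(u))
    if (n_tr >= length(u)) n_tr <- length(u) - 1L
    train_units <- c(train_units, sample(u, n_tr))
  }
  tr <- ids[group_of_sample[ids] %in% train_units]
  list(train = tr, test = setdiff(ids, tr))
}

#' Train the niche random forest on a reference atlas
#'
#' Grows an ensemble of Gini classification trees on bootstrap resamples of
#' the reference regions. Node expansion stops when the node's majority
#' class reaches `purity_stop`, the node is pure, or it is too small.
#' Features are internally ordered by protein id so the model is invariant
#' to the row order of the input. The model stores its feature list and the
#' canonical class order.
#'
#' @param reference a `reference_atlas`, or a [protein_matrix()] together
#'   with `labels`.
#' @param config a [forest_config()].
#' @param labels optional named vector sample id -> niche, required when
#'   `reference` is a bare matrix.
#' @return An object of class `niche_forest`.
#' @export
train_random_forest <- function(reference, config = forest_config(),
                                labels = NULL) {
  if (inherits(reference, "reference_atlas")) {
    mat <- reference$matrix
    labels <- reference$niche_of_sample
  } else {
    mat <- reference
    if (is.null(labels)) {
      if ("group" %in% names(mat$sample_meta))
        labels <- stats::setNames(mat$sample_meta$group, mat$sample_meta$sample_id)
      else stop("labels required when training on a bare matrix")
    }
  }
  stopifnot(inherits(mat, "protein_matrix"), inherits(config, "forest_config"))
  if (anyNA(mat$values))
    stop("training matrix has missing values; run impute_downshifted_gaussian first")
  if (config$zscore_training && mat$scale_tag != "zscored")
    mat <- zscore_within_sample(mat)

  feats <- sort(protein_ids(mat))
  X <- t(mat$values[feats, , drop = FALSE])   # samples x proteins
  y <- factor(labels[rownames(X)], levels = NICHE_LEVELS)
  if (anyNA(y)) stop("every training sample needs a niche label")
  yi <- as.integer(y)
  K <- length(NICHE_LEVELS)
  mtry <- config$features_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))

  set.seed(config$seed)
  tree_seeds <- sample.int(.Machine$integer.max, config$n_trees)
  trees <- vector("list", config$n_trees)
  n <- nrow(X)
  for (b in seq_len(config$n_trees)) {
    set.seed(tree_seeds[b])
    bs <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(X[bs, , drop = FALSE], yi[bs], K, mtry,
                            config$purity_stop, tree_seeds[b])
  }
  structure(list(trees = trees, features = feats, classes = NICHE_LEVELS,
                 config = config, n_train = n),
            class = "niche_forest")
}

#' @export
print.niche_forest <- function(x, ...) {
  cat(sprintf("niche_forest: %d trees on %d features, trained on %d samples\n",
              length(x$trees), length(x$features), x$n_train))
  invisible(x)
}

# z-score + restrict to model features, in model feature order
prepare_for_model <- function(model, mat, strict_scale = FALSE) {
  missing_feats <- setdiff(model$features, protein_ids(mat))
  if (length(missing_feats) > 0)
    stop(sprintf("matrix lacks %d model features (e.g. %s); use intersect_features before training",
                 length(missing_feats), missing_feats[1]))
  if (mat$scale_tag != "zscored") {
    msg <- "input is not z-scored; applying zscore_within_sample"
    if (strict_scale) stop(msg) else warning(msg)
    mat <- zscore_within_sample(mat)
  }
  t(mat$values[model$features, , drop = FALSE])
}

#' Predict niche composition of bulk samples
#'
#' For each bulk sample the forest's trees each cast one hard vote; the
#' vote fractions over the five niches are read out as the niche
#' composition estimate (they are non-negative and sum to one by
#' construction). The dominant niche is the argmax, with ties broken by the
#' canonical order LE < IT < CT < MVP < PAN.
#'
#' @param model a trained [train_random_forest()] model.
#' @param bulk a `bulk_cohort` or a [protein_matrix()] restricted (or
#'   restrictable) to the model features. Input that is not z-scored is
#'   z-scored with a warning (`strict_scale = TRUE` turns this into an
#'   error).
#' @param strict_scale hard-fail on non-z-scored input.
#' @return A data.frame with one row per sample: `sample_id`, one
#'   probability column per niche, and `dominant`.
#' @export
predict_niche_composition <- function(model, bulk, strict_scale = FALSE) {
  stopifnot(inherits(model, "niche_forest"))
  mat <- if (inherits(bulk, "bulk_cohort")) bulk$matrix else bulk
  stopifnot(inherits(mat, "protein_matrix"))
  if (anyNA(mat$values))
    stop("bulk matrix has missing values; impute first")
  X <- prepare_for_model(model, mat, strict_scale)
  probs <- forest_votes(model$trees, X, length(model$classes))
  colnames(probs) <- model$classes
  dominant <- model$classes[apply(probs, 1, which.max)]  # which.max -> first max
  out <- data.frame(sample_id = rownames(X), probs, dominant = dominant,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate a trained forest on held-out reference samples
#'
#' @param model a [train_random_forest()] model.
#' @param test a `reference_atlas` (or [protein_matrix()] plus `labels`)
#'   of held-out samples.
#' @param labels named vector sample id -> niche when `test` is a matrix.
#' @return list of class `eval_report`: `confusion` (5 x 5 count matrix,
#'   rows = true, cols = predicted), `per_class_auc` (one-vs-rest, from vote
#'   fractions), `auc` (macro average), `accuracy`.
#' @export
evaluate_forest <- function(model, test, labels = NULL) {
  if (inherits(test, "reference_atlas")) {
    mat <- test$matrix; labels <- test$niche_of_sample
  } else mat <- test
  comp <- predict_niche_composition(model, mat)
  truth <- as.character(labels[comp$sample_id])
  if (!all(truth %in% model$classes))
    stop("test set contains labels unseen by the model: ",
         paste(setdiff(truth, model$classes), collapse = ", "))
  tf <- factor(truth, levels = model$classes)
  pf <- factor(comp$dominant, levels = model$classes)
  confusion <- table(true = tf, predicted = pf)
  per_class_auc <- vapply(model$classes, function(cl)
    binary_auc(comp[[cl]], truth == cl), numeric(1))
  structure(list(confusion = unclass(confusion),
                 per_class_auc = per_class_auc,
                 auc = mean(per_class_auc, na.rm = TRUE),
                 accuracy = mean(truth == comp$dominant)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.3f, macro one-vs-rest AUC %.4f\n",
              x$accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Long-format composition table
#'
#' Reshapes per-sample composition estimates into the long layout (sample,
#' niche, probability, dominant flag) used for stacked-bar visualization.
#'
#' @param comps output of [predict_niche_composition()].
#' @return data.frame with `5 * nrow(comps)` rows.
#' @export
composition_table <- function(comps) {
  stopifnot(all(c("sample_id", NICHE_LEVELS, "dominant") %in% names(comps)))
  long <- do.call(rbind, lapply(NICHE_LEVELS, function(nc)
    data.frame(sample_id = comps$sample_id, niche = nc,
               probability = comps[[nc]],
               dominant = comps$dominant == nc,
               stringsAsFactors = FALSE)))
  long$niche <- factor(long$niche, levels = NICHE_LEVELS)
  long[order(match(long$sample_id, comps$sample_id), long$niche), ,
       drop = FALSE] -> long
  rownames(long) <- NULL
  long
}

#' Stacked-bar plot of niche compositions
#'
#' @param comps output of [predict_niche_composition()].
#' @return a ggplot object.
#' @export
plot_composition <- function(comps) {
  long <- composition_table(comps)
  ggplot2::ggplot(long, ggplot2::aes(x = sample_id, y = probability,
                                     fill = niche)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "tree-vote fraction", fill = "niche") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5))
}

#' Serialize / load a trained forest as JSON
#'
#' The model (tree arrays, feature list, class order, config) round-trips
#' losslessly through a single JSON file.
#'
#' @param model a `niche_forest`.
#' @param path JSON path.
#' @return `path` / the restored `niche_forest`.
#' @export
write_forest_json <- function(model, path) {
  obj <- list(format_version = 1L,
              features = model$features, classes = model$classes,
              n_train = model$n_train,
              config = unclass(model$config),
              trees = lapply(model$trees, function(tr)
                lapply(tr, function(v) unname(v))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow(obj$trees)), function(i) {
    list(var = as.integer(obj$trees$var[[i]]),
         split = as.numeric(obj$trees$split[[i]]),
         left = as.integer(obj$trees$left[[i]]),
         right = as.integer(obj$trees$right[[i]]),
         pred = as.integer(obj$trees$pred[[i]]))
  })
  cfg <- obj$config
  config <- forest_config(n_trees = cfg$n_trees, purity_stop = cfg$purity_stop,
                          features_per_split = cfg$features_per_split,
                          train_frac = cfg$train_frac, split_by = cfg$split_by,
                          zscore_training = cfg$zscore_training, seed = cfg$seed)
  structure(list(trees = trees, features = obj$features, classes = obj$classes,
                 config = config, n_train = obj$n_train),
            class = "niche_forest")
}
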