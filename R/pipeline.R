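# Deterministic byte hash of "seed:stage" reduced mod 2^31 - 1: gives every
# pipeline stage its own reproducible 32-bit seed derived from the master
# seed without per-stage configuration. The multiplier keeps intermediate
# values below 2^53 so the arithmetic is exact in doubles.
stage_seed <- function(master_seed, stage) {
  bytes <- utf8ToInt(paste0(master_seed, ":", stage))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- (h * 69069 + b + 1) %% 2147483647
  }
  as.integer(h)
}

#' Pipeline run configuration
#'
#' Bundles the stage parameter sets plus output paths and a master seed from
#' which every stage seed is derived deterministically, so a config + seed
#' pair identifies a run bit-for-bit. Round-trips losslessly through YAML.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()].
#' @param imputation an [imputation_params()].
#' @param forest a [forest_config()].
#' @param volcano a [volcano_params()].
#' @param stages character subset of
#'   `c("simulate", "preprocess", "train", "deconvolute", "stats")` in
#'   pipeline order.
#' @param min_frac presence-filter threshold (default 0.6).
#' @param master_seed master integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "nichedeconv_run",
                       sim = sim_config(),
                       imputation = imputation_params(),
                       forest = forest_config(),
                       volcano = volcano_params(),
                       stages = c("simulate", "preprocess", "train",
                                  "deconvolute", "stats"),
                       min_frac = 0.6,
                       master_seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, sim = sim, imputation = imputation,
                 forest = forest, volcano = volcano, stages = stages,
                 min_frac = min_frac, master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  # yaml serializes named atomic vectors as plain sequences; promote them to
  # lists so the names survive the round trip
  to_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), to_plain)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_plain(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(out_dir = obj$out_dir,
             sim = do.call(sim_config, obj$sim),
             imputation = do.call(imputation_params, obj$imputation),
             forest = do.call(forest_config, obj$forest),
             volcano = do.call(volcano_params, obj$volcano),
             stages = obj$stages, min_frac = obj$min_frac,
             master_seed = obj$master_seed)
}

#' Run the end-to-end niche-deconvolution pipeline
#'
#' Executes the enabled stages in fixed order — simulate (reference atlas +
#' bulk cohort), preprocess (presence filter, imputation, z-scoring), train
#' (random forest on the reference), deconvolute (niche compositions of the
#' bulk cohort), stats (subtype x dominant-niche chi-squared enrichment with
#' the proneural/IT focus) — writing each stage's outputs under
#' `config$out_dir` and a manifest of parameters, file checksums and stage
#' seeds. Identical config + master seed reproduce identical checksums.
#' Stages later in the order than the enabled set rely on the files written
#' by their predecessors; a missing predecessor output is an error naming
#' the required stage.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  need <- function(f, stage_needed) {
    if (!file.exists(f))
      stop(sprintf("missing '%s': run the '%s' stage first", f, stage_needed))
    f
  }
  st <- config$stages
  seeds <- vapply(c("simulate", "impute_ref", "impute_bulk", "train", "volcano"),
                  function(s) stage_seed(config$master_seed, s), integer(1))
  log_info <- function(...) message(sprintf(...))

  if ("simulate" %in% st) {
    sim <- config$sim
    sim$seed <- seeds[["simulate"]]
    atlas <- generate_reference_atlas(sim)
    bulk <- generate_bulk_cohort(atlas, sim)
    write_matrix_tsv(atlas$matrix, path("atlas.tsv"))
    write_matrix_tsv(bulk$matrix, path("bulk.tsv"))
    write_truth_json(atlas, path("atlas_truth.json"))
    write_truth_json(bulk, path("bulk_truth.json"))
    log_info("simulate: atlas %d x %d, bulk %d x %d",
             nrow(atlas$matrix$values), ncol(atlas$matrix$values),
             nrow(bulk$matrix$values), ncol(bulk$matrix$values))
  }

  if ("preprocess" %in% st) {
    atlas_m <- read_matrix_tsv(need(path("atlas.tsv"), "simulate"))
    bulk_m <- read_matrix_tsv(need(path("bulk.tsv"), "simulate"))
    n0 <- nrow(atlas_m$values)
    atlas_m <- filter_by_group_presence(atlas_m, min_frac = config$min_frac)
    log_info("preprocess: presence filter kept %d of %d atlas proteins",
             nrow(atlas_m$values), n0)
    ip <- config$imputation
    ip$seed <- seeds[["impute_ref"]]
    n_miss <- sum(is.na(atlas_m$values))
    atlas_m <- impute_downshifted_gaussian(atlas_m, ip)
    log_info("preprocess: imputed %d missing atlas cells", n_miss)
    ip$seed <- seeds[["impute_bulk"]]
    n_miss <- sum(is.na(bulk_m$values))
    bulk_m <- impute_downshifted_gaussian(bulk_m, ip)
    log_info("preprocess: imputed %d missing bulk cells", n_miss)
    shared <- intersect_features(atlas_m, bulk_m)
    atlas_m <- zscore_within_sample(shared$a)
    bulk_m <- zscore_within_sample(shared$b)
    write_matrix_tsv(atlas_m, path("atlas_proc.tsv"))
    write_matrix_tsv(bulk_m, path("bulk_proc.tsv"))
  }

  if ("train" %in% st) {
    atlas_m <- read_matrix_tsv(need(path("atlas_proc.tsv"), "preprocess"))
    fc <- config$forest
    fc$seed <- seeds[["train"]]
    labels <- stats::setNames(atlas_m$sample_meta$group, atlas_m$sample_meta$sample_id)
    region <- stats::setNames(paste(atlas_m$sample_meta$patient,
                                    atlas_m$sample_meta$group, sep = "_"),
                              atlas_m$sample_meta$sample_id)
    split <- stratified_split(labels, fc$train_frac, fc$seed,
                              group_of_sample = if (fc$split_by == "region") region)
    model <- train_random_forest(subset_samples(atlas_m, split$train), fc,
                                 labels = labels[split$train])
    report <- evaluate_forest(model, subset_samples(atlas_m, split$test),
                              labels = labels[split$test])
    write_forest_json(model, path("model.json"))
    utils::write.table(report$confusion, path("confusion.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    jsonlite::write_json(list(macro_auc = report$auc,
                              per_class_auc = as.list(report$per_class_auc),
                              accuracy = report$accuracy),
                         path("evaluation.json"), auto_unbox = TRUE, digits = NA)
    log_info("train: held-out macro AUC %.4f, accuracy %.3f", report$auc,
             report$accuracy)
  }

  if ("deconvolute" %in% st) {
    model <- read_forest_json(need(path("model.json"), "train"))
    bulk_m <- read_matrix_tsv(need(path("bulk_proc.tsv"), "preprocess"))
    comps <- predict_niche_composition(model, bulk_m)
    utils::write.table(comps, path("compositions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_info("deconvolute: %d bulk samples classified", nrow(comps))
  }

  if ("stats" %in% st) {
    comps <- utils::read.table(need(path("compositions.tsv"), "deconvolute"),
                               sep = "\t", header = TRUE, check.names = FALSE,
                               stringsAsFactors = FALSE)
    bulk_m <- read_matrix_tsv(need(path("bulk_proc.tsv"), "preprocess"))
    dominant <- stats::setNames(comps$dominant, comps$sample_id)
    subtype <- stats::setNames(bulk_m$sample_meta$group, bulk_m$sample_meta$sample_id)
    enr <- chi_squared_niche_enrichment(dominant, subtype[names(dominant)],
                                        focus = c("proneural", "IT"))
    jsonlite::write_json(list(chi2 = enr$chi2, df = enr$df, p = enr$p_value,
                              focus_chi2 = enr$focus_chi2, focus_p = enr$focus_p,
                              observed = apply(enr$observed, 1, as.list)),
                         path("enrichment.json"), auto_unbox = TRUE, digits = NA)
    log_info("stats: subtype x niche chi-squared p = %.4g (focus p = %.4g)",
             enr$p_value, enr$focus_p)
  }

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("nichedeconv")),
    master_seed = config$master_seed,
    stage_seeds = as.list(seeds),
    stages = config$stages,
    parameters = list(sim = unclass(config$sim)[
                        !vapply(unclass(config$sim), is.list, logical(1))],
                      imputation = unclass(config$imputation),
                      forest = unclass(config$forest),
                      volcano = unclass(config$volcano),
                      min_frac = config$min_frac),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Ingest an external abundance matrix
#'
#' Reads a TSV or GCT 1.2 matrix into a [protein_matrix()]. The scale tag is
#' supplied by the caller, never guessed from the data. Duplicate gene
#' symbols are resolved by keeping the row with the highest median abundance
#' (ties: first row), with a message reporting the count.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param scale_tag scale of the stored values (e.g. `"raw"`, `"log2"`).
#' @param platform_tag recorded in the sample metadata `platform` column.
#' @param meta_path optional sample-metadata TSV (TSV format only).
#' @return A [protein_matrix()].
#' @export
ingest_external_matrix <- function(path, format = c("tsv", "gct"),
                                   scale_tag = "raw", platform_tag = "unknown",
                                   meta_path = NULL) {
  format <- match.arg(format)
  df <- if (format == "gct") {
    hdr <- readLines(path, n = 2)
    if (length(hdr) < 2 || trimws(hdr[1]) != "#1.2") stop("not a GCT 1.2 file")
    utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                      check.names = FALSE, na.strings = c("", "NA"),
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  } else {
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      na.strings = c("", "NA"), stringsAsFactors = FALSE,
                      quote = "", comment.char = "")
  }
  drop_cols <- if (format == "gct") 1:2 else 1
  ids <- as.character(df[[1]])
  sample_names <- colnames(df)[-drop_cols]   # before [.data.frame dedupes them
  if (anyDuplicated(sample_names)) stop("duplicate sample ids in ", path)
  vals <- as.matrix(df[, -drop_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- sample_names
  if (format == "gct") {
    dims <- as.integer(strsplit(readLines(path, n = 2)[2], "\t")[[1]][1:2])
    if (!identical(dims, dim(vals)))
      stop("GCT dims line does not match table body")
  }
  if (anyDuplicated(ids)) {
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(ids), ids), function(ii)
      ii[which.max(med[ii])]), use.names = FALSE)
    keep <- sort(keep)
    message(length(ids) - length(keep),
            " duplicate gene symbols resolved by highest median abundance")
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(vals) <- ids
  meta <- NULL
  if (!is.null(meta_path))
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  if (is.null(meta))
    meta <- data.frame(sample_id = colnames(vals), stringsAsFactors = FALSE)
  meta$platform <- platform_tag
  protein_matrix(vals, meta, scale_tag = scale_tag)
}
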