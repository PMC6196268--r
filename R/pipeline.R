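#' Default pipeline configuration
#'
#' All numeric decisions of the workflow surfaced as one config list:
#' preprocessing floor, univariate alpha / minimum fold change / test /
#' adjustment, selection B / test fraction / inner folds / phi, validation
#' repetition counts and ridge penalty, enrichment minimum genes and
#' alpha, and the top-level seed from which every stage derives its own
#' substream. The list round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param ... named overrides of any default.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    floor = 1.0, batch = TRUE, center = FALSE,
    detect_theta = 1.0, detect_fraction = 0.5,
    alpha = 0.05, fc_min = 2.0, test = "welch_t", adjust = "BH",
    B = 5L, test_fraction = 0.25, inner_folds = 4L, phi = 0.5,
    mu = 0.1, R_true = 100L, R_perm = 100L,
    min_genes = 3L, enrich_alpha = 0.05,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  do.call(default_config, jsonlite::fromJSON(path))
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates the stages in study order — preprocessing, detection
#' calls, univariate differential expression, nested-CV multivariate
#' selection, Monte-Carlo validation of the aggregated signature, and
#' (when gene sets and target tables are supplied) hypergeometric
#' enrichment — writing every stage's table plus a machine-readable run
#' log into `out_dir`.
#'
#' @param mat linear-scale [expr_matrix()] (raw intensities).
#' @param metadata sample metadata.
#' @param config a [default_config()] list.
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param gene_sets,reference,target_tables optional enrichment inputs
#'   (see [hypergeometric_enrichment()], [aggregate_targets()]).
#' @return list with `detection`, `de_table`, `selection`, `validation`,
#'   `enrichment` (or NULL), `config`.
#' @export
run_pipeline <- function(mat, metadata, config = default_config(),
                         out_dir = NULL, gene_sets = NULL,
                         reference = NULL, target_tables = NULL) {
  if (is.null(metadata)) stop("stage preprocess: metadata is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  seeds <- .stage_seeds(config$seed)
  norm <- stage("preprocess",
                preprocess_chain(mat, metadata, floor = config$floor,
                                 batch = config$batch,
                                 center = config$center))
  detection <- stage("detection",
                     detection_call(norm, metadata,
                                    theta = config$detect_theta,
                                    f = config$detect_fraction))
  de <- stage("univariate",
              differential_expression(norm, metadata, alpha = config$alpha,
                                      fc_min = config$fc_min,
                                      test = config$test,
                                      adjust = config$adjust,
                                      detect_theta = config$detect_theta))
  sel <- stage("selection",
               nested_cv_select(norm, metadata, B = config$B,
                                test_fraction = config$test_fraction,
                                inner_folds = config$inner_folds,
                                phi = config$phi,
                                seed = seeds[["selection"]]))
  val <- stage("validation", {
    sig <- sel$signature
    if (!length(sig)) stop("empty aggregated signature")
    validate_signature(subset_matrix(norm, sig), metadata, mu = config$mu,
                       R_true = config$R_true, R_perm = config$R_perm,
                       test_fraction = config$test_fraction,
                       seed = seeds[["validation"]])
  })
  enr <- NULL
  if (!is.null(gene_sets) && !is.null(reference) &&
      !is.null(target_tables)) {
    enr <- stage("enrichment", {
      targets <- aggregate_targets(target_tables)
      sig_genes <- unique(targets$gene[targets$mirna %in% sel$signature])
      hypergeometric_enrichment(sig_genes, gene_sets, reference,
                                min_genes = config$min_genes,
                                alpha = config$enrich_alpha)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signature_tsv(de, file.path(out_dir, "de_table.tsv"))
    write_selection_json(sel, file.path(out_dir, "selection.json"))
    jsonlite::write_json(list(counts = as.list(detection$counts),
                              shared = detection$shared,
                              exclusive = detection$exclusive),
                         file.path(out_dir, "detection.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(mean_accuracy = val$mean_accuracy,
                              D = val$D, p = val$p,
                              acc_true = val$acc_true,
                              acc_perm = val$acc_perm),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(enr))
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log <- list(timestamp = format(Sys.time(), tz = "UTC"),
                package_version = as.character(
                  utils::packageVersion("nkmir")),
                config = unclass(config), stage_seeds = as.list(seeds),
                n_features = nrow(mat), n_samples = ncol(mat),
                signature_size = length(sel$signature),
                univariate_calls = sum(de$status != "unchanged"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(detection = detection, de_table = de, selection = sel,
       validation = val, enrichment = enr, config = config)
}

# named per-stage substreams derived from the single top-level seed
.stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("simulate", "selection", "validation"))
}
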