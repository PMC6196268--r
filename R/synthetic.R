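#' Synthetic two-group miRNA microarray experiment
#'
#' Generates a linear-scale intensity matrix with the statistical
#' structure of a paired two-subset NK-cell profiling study: `n_per_group`
#' paired donors each contributing one bright and one dim sample, `d`
#' features with log-normal intensities (Gaussian on the log2 scale, with
#' the scanner's detection floor at 1 light unit applied downstream),
#' `n_up`/`n_down` features shifted up/down in the dim group by
#' `effect_log2` log2 units (at least a two-fold median difference at the
#' default 1.5), `n_exclusive_each` features expressed in only one group
#' (the other group sits below the detection floor), two acquisition
#' batches (donors split half and half, so batch and group are not
#' confounded) offset by `batch_offset` log2 units, and optional Gaussian
#' donor random intercepts.
#'
#' @param n_per_group samples per group (default 10).
#' @param d number of features (default 2000).
#' @param n_up,n_down features planted up/down in the dim group
#'   (defaults 15 and 15).
#' @param n_exclusive_each features exclusive to each group (default 2).
#' @param effect_log2 planted shift, log2 units (default 1.5).
#' @param sigma per-measurement Gaussian noise sd, log2 units
#'   (default 0.3).
#' @param batch_offset additive log2 shift of the second batch
#'   (default 0.5).
#' @param donor_sd sd of the per-donor random intercept (default 0).
#' @param baseline_range log2 range of feature baselines
#'   (default c(-2, 8); the detection floor at 1 LU = 0 log2 leaves part
#'   of the features undetected, as on a real array).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `matrix` (linear-scale [expr_matrix()]), `metadata`
#'   (sample_id, group, donor_id, batch_id), and `truth` (class
#'   `synthetic_truth`: planted feature ids and effects, exclusive sets,
#'   baselines, batch assignment, noise sd, seed).
#' @export
generate_microarray <- function(n_per_group = 10L, d = 2000L,
                                n_up = 15L, n_down = 15L,
                                n_exclusive_each = 2L,
                                effect_log2 = 1.5, sigma = 0.3,
                                batch_offset = 0.5, donor_sd = 0,
                                baseline_range = c(-2, 8), seed = 1L) {
  if (n_up + n_down + 2L * n_exclusive_each > d)
    stop("planted feature counts exceed d")
  if (effect_log2 <= 0 || sigma < 0) stop("invalid effect or noise sd")
  set.seed(seed)
  feature_ids <- sprintf("mir-%04d", seq_len(d))
  baseline <- stats::runif(d, baseline_range[1], baseline_range[2])
  # plant effects on well-expressed features so they are detectable
  high <- which(baseline >= 3 & baseline <= 6.5)
  n_planted <- n_up + n_down + 2L * n_exclusive_each
  if (length(high) < n_planted)
    stop("only ", length(high), " well-expressed features available for ",
         n_planted, " planted ones; increase d or widen baseline_range")
  planted <- sample(high, n_planted)
  up <- planted[seq_len(n_up)]
  down <- planted[n_up + seq_len(n_down)]
  excl_bright <- planted[n_up + n_down + seq_len(n_exclusive_each)]
  excl_dim <- planted[n_up + n_down + n_exclusive_each +
                        seq_len(n_exclusive_each)]

  donors <- sprintf("donor%02d", seq_len(n_per_group))
  groups <- c("bright", "dim")
  md <- expand.grid(donor_id = donors, group = groups,
                    stringsAsFactors = FALSE)
  md$sample_id <- paste(md$group, md$donor_id, sep = "_")
  md$batch_id <- ifelse(match(md$donor_id, donors) <= n_per_group / 2,
                        "batch1", "batch2")
  md <- md[, c("sample_id", "group", "donor_id", "batch_id")]

  mean_mat <- matrix(baseline, d, nrow(md))
  dim_cols <- md$group == "dim"
  mean_mat[up, dim_cols] <- mean_mat[up, dim_cols] + effect_log2
  mean_mat[down, dim_cols] <- mean_mat[down, dim_cols] - effect_log2
  # exclusive features: silent group far below the 1 LU floor
  mean_mat[excl_bright, dim_cols] <- -2
  mean_mat[excl_dim, !dim_cols] <- -2
  mean_mat[excl_bright, !dim_cols] <- baseline[excl_bright]
  mean_mat[excl_dim, dim_cols] <- baseline[excl_dim]

  donor_eff <- stats::setNames(stats::rnorm(n_per_group, 0, donor_sd),
                               donors)
  log2_vals <- mean_mat +
    matrix(donor_eff[md$donor_id], d, nrow(md), byrow = TRUE) +
    matrix(batch_offset * (md$batch_id == "batch2"), d, nrow(md),
           byrow = TRUE) +
    matrix(stats::rnorm(d * nrow(md), 0, sigma), d, nrow(md))
  dimnames(log2_vals) <- list(feature_ids, md$sample_id)

  truth <- structure(list(
    up = feature_ids[up], down = feature_ids[down],
    exclusive_bright = feature_ids[excl_bright],
    exclusive_dim = feature_ids[excl_dim],
    effect_log2 = effect_log2, sigma = sigma,
    batch_offset = batch_offset, donor_sd = donor_sd,
    baseline = stats::setNames(baseline, feature_ids),
    batch = stats::setNames(md$batch_id, md$sample_id),
    seed = seed), class = "synthetic_truth")
  list(matrix = expr_matrix(2^log2_vals, scale = "linear"),
       metadata = md, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic truth: %d up, %d down (effect %.2g log2), %d+%d exclusive, sigma %.2g, seed %d\n",
    length(x$up), length(x$down), x$effect_log2,
    length(x$exclusive_bright), length(x$exclusive_dim), x$sigma, x$seed))
  invisible(x)
}

#' Planted feature ids of a synthetic experiment
#'
#' @param truth a `synthetic_truth`.
#' @param include_exclusive also include the exclusively-expressed
#'   features (default TRUE).
#' @return character vector of planted feature ids.
#' @export
planted_features <- function(truth, include_exclusive = TRUE) {
  out <- c(truth$up, truth$down)
  if (include_exclusive)
    out <- c(out, truth$exclusive_bright, truth$exclusive_dim)
  out
}

#' Add an intermediate maturation group to a synthetic experiment
#'
#' Appends `bright_cd16dim` samples whose planted-feature means are the
#' convex combination `(1 - mixing) * bright + mixing * dim` of the two
#' parent-group means — the transitional-subset pattern in which marker
#' miRNAs sit halfway between the extremes at `mixing = 0.5`. Enables the
#' three-group ANOVA trend analysis.
#'
#' @param sim a [generate_microarray()] result.
#' @param n_samples intermediate samples to add (default 10).
#' @param mixing mixing weight in `[0, 1]` (default 0.5).
#' @param sigma noise sd; defaults to the parent simulation's.
#' @param seed integer seed.
#' @return list with augmented `matrix` and `metadata` (and the original
#'   `truth`).
#' @export
generate_intermediate_group <- function(sim, n_samples = 10L, mixing = 0.5,
                                        sigma = NULL, seed = 1L) {
  if (mixing < 0 || mixing > 1) stop("'mixing' must lie in [0, 1]")
  truth <- sim$truth
  if (is.null(sigma)) sigma <- truth$sigma
  set.seed(seed)
  feats <- rownames(sim$matrix)
  base <- truth$baseline[feats]
  bright_mean <- base; dim_mean <- base
  dim_mean[truth$up] <- dim_mean[truth$up] + truth$effect_log2
  dim_mean[truth$down] <- dim_mean[truth$down] - truth$effect_log2
  dim_mean[truth$exclusive_bright] <- -2
  bright_mean[truth$exclusive_dim] <- -2
  mid <- (1 - mixing) * bright_mean + mixing * dim_mean
  ids <- sprintf("bright_cd16dim_donor%02d", seq_len(n_samples))
  batch <- ifelse(seq_len(n_samples) <= n_samples / 2, "batch1", "batch2")
  vals <- matrix(mid, length(feats), n_samples) +
    matrix(truth$batch_offset * (batch == "batch2"), length(feats),
           n_samples, byrow = TRUE) +
    matrix(stats::rnorm(length(feats) * n_samples, 0, sigma),
           length(feats), n_samples)
  dimnames(vals) <- list(feats, ids)
  new_md <- data.frame(sample_id = ids, group = "bright_cd16dim",
                       donor_id = sprintf("idonor%02d", seq_len(n_samples)),
                       batch_id = batch, stringsAsFactors = FALSE)
  list(matrix = expr_matrix(cbind(unclass(sim$matrix), 2^vals),
                            scale = "linear"),
       metadata = rbind(sim$metadata, new_md),
       truth = truth)
}

#' Synthetic qPCR cohort consistent with planted microarray effects
#'
#' Emits a long-format triplicate Ct table for a new cohort: per target
#' miRNA, the dim-group Ct is lowered by the planted dim-vs-bright log2
#' difference (higher expression, earlier amplification), the reference
#' gene (RNU6B) is flat across samples, and Gaussian replicate noise is
#' added on the Ct scale. Null (unplanted) targets have equal group means.
#'
#' @param truth a `synthetic_truth`.
#' @param targets feature ids to assay; must be planted or null features
#'   of the simulated array.
#' @param n_per_group samples per group in the new cohort (default 3).
#' @param ct_baseline target-gene baseline Ct, cycles (default 25).
#' @param ref_ct reference-gene Ct (default 20).
#' @param sigma_ct replicate noise sd, cycles (default 0.15).
#' @param n_replicates replicates per (sample, target) (default 3).
#' @param seed integer seed.
#' @return data frame: sample_id, group, target, replicate, ct,
#'   is_reference (reference rows carry target = "RNU6B").
#' @export
generate_qpcr <- function(truth, targets, n_per_group = 3L,
                          ct_baseline = 25, ref_ct = 20, sigma_ct = 0.15,
                          n_replicates = 3L, seed = 1L) {
  known <- names(truth$baseline)
  bad <- setdiff(targets, known)
  if (length(bad))
    stop("unknown targets: ", paste(bad, collapse = ", "))
  set.seed(seed)
  delta <- stats::setNames(numeric(length(targets)), targets)
  delta[targets %in% truth$up] <- truth$effect_log2
  delta[targets %in% truth$down] <- -truth$effect_log2
  delta[targets %in% truth$exclusive_dim] <- 5      # off -> on
  delta[targets %in% truth$exclusive_bright] <- -5  # on -> off
  md <- expand.grid(donor = seq_len(n_per_group),
                    group = c("bright", "dim"), stringsAsFactors = FALSE)
  md$sample_id <- sprintf("q_%s_%02d", md$group, md$donor)
  rows <- list()
  for (i in seq_len(nrow(md))) {
    g <- md$group[i]; sid <- md$sample_id[i]
    for (t in targets) {
      mu <- ct_baseline - if (g == "dim") delta[[t]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = g, target = t,
        replicate = seq_len(n_replicates),
        ct = stats::rnorm(n_replicates, mu, sigma_ct),
        is_reference = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, group = g, target = "RNU6B",
      replicate = seq_len(n_replicates),
      ct = stats::rnorm(n_replicates, ref_ct, sigma_ct),
      is_reference = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample relative expression matrix from a qPCR table
#'
#' Converts a long-format Ct table to a features x samples matrix of
#' -dCt values (reference-normalized, log2-like scale), the harmonized
#' input for [cross_technology_predict()].
#'
#' @param table qPCR table as in [delta_delta_ct()].
#' @return numeric matrix, targets x samples.
#' @export
qpcr_expression_matrix <- function(table) {
  ref <- table[table$is_reference, ]
  tgt <- table[!table$is_reference, ]
  if (!nrow(ref) || !nrow(tgt)) stop("table needs target and reference rows")
  ref_mean <- tapply(ref$ct, ref$sample_id, mean)
  agg <- stats::aggregate(ct ~ sample_id + target, data = tgt, FUN = mean)
  agg$neg_dct <- -(agg$ct - as.numeric(ref_mean[agg$sample_id]))
  samples <- unique(table$sample_id)
  targets <- unique(tgt$target)
  out <- matrix(NA_real_, length(targets), length(samples),
                dimnames = list(targets, samples))
  out[cbind(match(agg$target, targets), match(agg$sample_id, samples))] <-
    agg$neg_dct
  if (anyNA(out)) stop("missing (sample, target) combinations")
  out
}
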