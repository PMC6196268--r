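#' Relative quantification by the delta-delta-Ct method
#'
#' For each (sample, target): replicate Ct values are averaged on the Ct
#' scale, dCt = mean Ct(target) - mean Ct(reference gene) within the
#' sample, ddCt = dCt(sample) - dCt(calibrator), and the relative quantity
#' RQ = 2^(-ddCt). The calibrator may be a single sample id (its RQ is then
#' exactly 1) or a group label (calibrator dCt = unweighted mean dCt over
#' the group's samples).
#'
#' @param table long-format qPCR data frame with columns `sample_id`,
#'   `group`, `target`, `ct`, `is_reference` (logical; the reference-gene
#'   rows, e.g. RNU6B for miRNA or GAPDH for mRNA), one row per replicate.
#' @param calibrator a sample id or group label present in `table`.
#' @return data frame with sample_id, group, target, d_ct, dd_ct, rq.
#' @export
delta_delta_ct <- function(table, calibrator) {
  need <- c("sample_id", "group", "target", "ct", "is_reference")
  if (!all(need %in% names(table)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (any(table$ct <= 0 | table$ct >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  ref <- table[table$is_reference, ]
  tgt <- table[!table$is_reference, ]
  if (!nrow(ref)) stop("no reference-gene rows in table")
  ref_mean <- tapply(ref$ct, ref$sample_id, mean)
  agg <- stats::aggregate(ct ~ sample_id + group + target, data = tgt,
                          FUN = mean)
  if (!all(agg$sample_id %in% names(ref_mean)))
    stop("missing reference Ct for samples: ",
         paste(setdiff(agg$sample_id, names(ref_mean)), collapse = ", "))
  agg$d_ct <- agg$ct - as.numeric(ref_mean[agg$sample_id])
  out <- do.call(rbind, lapply(split(agg, agg$target), function(df) {
    cal_dct <- if (calibrator %in% df$sample_id) {
      df$d_ct[df$sample_id == calibrator]
    } else if (calibrator %in% as.character(df$group)) {
      mean(df$d_ct[as.character(df$group) == calibrator])
    } else {
      stop("calibrator '", calibrator,
           "' is neither a sample id nor a group in the table")
    }
    df$dd_ct <- df$d_ct - cal_dct
    df$rq <- 2^(-df$dd_ct)
    df
  }))
  rownames(out) <- NULL
  out[, c("sample_id", "group", "target", "d_ct", "dd_ct", "rq")]
}

#' Dual-reporter relative activity
#'
#' Per well, reporter activity = firefly / Renilla luminescence; each
#' ratio is then divided by the mean ratio of the control wells, so the
#' control-group mean is exactly 1.
#'
#' @param firefly,renilla paired positive luminescence readings per well.
#' @param is_control logical, marks the control (e.g. scrambled-miRNA)
#'   wells; at least one required.
#' @return numeric vector of normalized activities, one per well.
#' @export
reporter_relative_activity <- function(firefly, renilla, is_control) {
  if (length(firefly) != length(renilla) ||
      length(firefly) != length(is_control))
    stop("firefly, renilla, is_control must have equal length")
  if (any(renilla <= 0)) stop("Renilla readings must be positive")
  if (!any(is_control)) stop("control group is empty")
  ratio <- firefly / renilla
  ratio / mean(ratio[is_control])
}

#' Group comparison of assay measurements
#'
#' Thin wrapper over [group_mean_test()]: a two-group Welch t (or
#' Mann-Whitney) test, or one-way ANOVA with Bonferroni-adjusted pairwise
#' post-tests for three or more groups (the three-NK-subset design).
#'
#' @param values numeric measurements (e.g. RQ values).
#' @param group group labels.
#' @param design `"two_group_t"`, `"mann_whitney"`, or
#'   `"anova_bonferroni"`.
#' @return as [group_mean_test()].
#' @export
group_compare <- function(values, group,
                          design = c("two_group_t", "mann_whitney",
                                     "anova_bonferroni")) {
  design <- match.arg(design)
  kind <- switch(design, two_group_t = "welch_t",
                 mann_whitney = "mann_whitney",
                 anova_bonferroni = "anova_bonferroni")
  group_mean_test(values, group, kind = kind)
}
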