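#' Analysis thresholds for the joint expression/splicing pipeline
#'
#' Bundles every cutoff used downstream: the abundance filter (mean RPKM),
#' the enlarged-proportion variance filter, the fold-change bounds that
#' separate up/down/no-change at the gene level, and the differential-splicing
#' significance rule on \eqn{-\ln(\mathrm{FDR})}.
#'
#' Defaults reproduce the published analysis: genes (and isoforms) are removed
#' when their mean RPKM is below 1 in both conditions; proportions are
#' "enlarged" by a factor 100 and a gene is kept as a splicing candidate only
#' when the replicate variance of every enlarged isoform proportion stays
#' below 150 in each condition; up-regulation is fold change > 1.25,
#' down-regulation < 0.8; differential splicing is significant when
#' \eqn{-\ln(\mathrm{FDR}) > 3} (i.e. FDR < \eqn{e^{-3}} ~= 0.0498).
#'
#' @param min_avg_rpkm Minimum mean RPKM; entities below this in *both*
#'   conditions are filtered out (strict `<`).
#' @param enlargement_factor Multiplier turning proportions into
#'   "enlarged proportions" / pseudo counts (100 turns 0.9 into 90).
#' @param variance_cutoff Upper bound (strict `<`) on the replicate variance
#'   of each isoform's enlarged proportion, per condition.
#' @param fc_up,fc_down Fold-change bounds for up-/down-regulation; the
#'   closed interval `[fc_down, fc_up]` is "no change".
#' @param ds_neglog_fdr Significance threshold on \eqn{-\ln(\mathrm{FDR})}.
#' @param fdr_alpha Nominal FDR level quoted in summaries (0.05).
#' @param require_both_conditions If `TRUE`, the abundance filter keeps an
#'   entity only when its mean RPKM reaches `min_avg_rpkm` in *both*
#'   conditions (the stricter reading); default `FALSE` keeps entities
#'   expressed in at least one condition.
#' @param renormalize_proportions If `TRUE` (default), proportions entering
#'   the variance filter and the proportion matrix are recomputed over the
#'   isoforms that survived the abundance filter.
#' @param variance_denominator `"n-1"` (unbiased sample variance, default) or
#'   `"n"` for the population variance in the variance filter.
#' @param yates One of `"2x2"` (Yates continuity correction only for 2x2
#'   tables, mirroring `chisq.test`), `"always"`, or `"never"`.
#' @param region_orientation `"up_right"` (default): regions 5/6 are the
#'   up-regulated side, 1/2 the down-regulated side. `"down_right"` swaps
#'   them (the even/odd split and region 3/4 are unaffected).
#'
#' @return A list of class `analysis_thresholds`.
#' @examples
#' thr <- analysis_thresholds()
#' thr$variance_cutoff
#' @export
analysis_thresholds <- function(min_avg_rpkm = 1.0,
                                enlargement_factor = 100,
                                variance_cutoff = 150.0,
                                fc_up = 1.25,
                                fc_down = 0.8,
                                ds_neglog_fdr = 3.0,
                                fdr_alpha = 0.05,
                                require_both_conditions = FALSE,
                                renormalize_proportions = TRUE,
                                variance_denominator = c("n-1", "n"),
                                yates = c("2x2", "always", "never"),
                                region_orientation = c("up_right", "down_right")) {
  variance_denominator <- match.arg(variance_denominator)
  yates <- match.arg(yates)
  region_orientation <- match.arg(region_orientation)
  stopifnot(fc_down < 1, 1 < fc_up,
            min_avg_rpkm > 0, enlargement_factor > 0, variance_cutoff > 0,
            ds_neglog_fdr > 0, fdr_alpha > 0)
  structure(
    list(min_avg_rpkm = min_avg_rpkm,
         enlargement_factor = enlargement_factor,
         variance_cutoff = variance_cutoff,
         fc_up = fc_up, fc_down = fc_down,
         ds_neglog_fdr = ds_neglog_fdr, fdr_alpha = fdr_alpha,
         require_both_conditions = require_both_conditions,
         renormalize_proportions = renormalize_proportions,
         variance_denominator = variance_denominator,
         yates = yates,
         region_orientation = region_orientation),
    class = "analysis_thresholds")
}

as_thresholds <- function(thr) {
  if (is.null(thr)) return(analysis_thresholds())
  if (inherits(thr, "analysis_thresholds")) return(thr)
  do.call(analysis_thresholds, thr)
}

#' Validate a sample-to-condition design table
#'
#' @param design A data frame with columns `sample_id` and `condition`
#'   (values `"control"` / `"case"`), optionally `path` (per-sample input)
#'   and `junction_path`.
#' @param require_replicates Minimum samples per condition.
#' @return The design as a tibble, invisibly validated.
#' @export
check_design <- function(design, require_replicates = 1L) {
  design <- as_tibble(design)
  needed <- c("sample_id", "condition")
  if (!all(needed %in% names(design)))
    abort(paste0("design must have columns: ", paste(needed, collapse = ", ")))
  if (anyDuplicated(design$sample_id))
    abort("design sample_id values must be unique")
  bad <- setdiff(unique(design$condition), c("control", "case"))
  if (length(bad))
    abort(paste0("design conditions must be 'control'/'case'; found: ",
                 paste(bad, collapse = ", ")))
  tab <- table(factor(design$condition, c("control", "case")))
  if (any(tab < require_replicates))
    abort(sprintf("each condition needs >= %d sample(s); got control=%d, case=%d",
                  require_replicates, tab[["control"]], tab[["case"]]))
  design
}
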