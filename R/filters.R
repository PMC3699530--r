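#' Gene-level abundance filter
#'
#' Removes very low-abundance genes: a gene fails when its mean RPKM is below
#' `thr$min_avg_rpkm` in *both* conditions (strict `<`; a gene at exactly the
#' cutoff in either condition is kept). With
#' `thr$require_both_conditions = TRUE` the stricter reading applies: the
#' mean must reach the cutoff in both conditions.
#'
#' @param quant An `iso_quant`.
#' @param thr [analysis_thresholds()] (or a compatible list).
#' @return Filter report tibble: `entity_id`, `rule`, `control_mean`,
#'   `case_mean`, `pass` — one row per gene.
#' @export
abundance_filter_genes <- function(quant, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  check_design(quant$design, require_replicates = 1L)
  cm <- condition_means(quant$genes, "rpkm", "gene_id")
  pass <- if (thr$require_both_conditions)
    cm$control >= thr$min_avg_rpkm & cm$case >= thr$min_avg_rpkm
  else
    !(cm$control < thr$min_avg_rpkm & cm$case < thr$min_avg_rpkm)
  tibble(entity_id = cm$gene_id, rule = "gene_abundance",
         control_mean = cm$control, case_mean = cm$case, pass = pass)
}

#' Isoform-level abundance filter
#'
#' Same rule as [abundance_filter_genes()], applied to isoform RPKM and
#' restricted to isoforms of genes that survived the gene filter.
#'
#' @param quant An `iso_quant`.
#' @param thr Thresholds.
#' @param surviving_genes Character vector of gene ids that passed the gene
#'   filter.
#' @return Filter report tibble with one row per isoform of a surviving
#'   gene (`gene_id` carried alongside `entity_id`).
#' @export
abundance_filter_isoforms <- function(quant, thr = analysis_thresholds(),
                                      surviving_genes) {
  thr <- as_thresholds(thr)
  iso <- quant$isoforms[quant$isoforms$gene_id %in% surviving_genes, ]
  cm <- condition_means(iso, "rpkm", c("gene_id", "transcript_id"))
  pass <- if (thr$require_both_conditions)
    cm$control >= thr$min_avg_rpkm & cm$case >= thr$min_avg_rpkm
  else
    !(cm$control < thr$min_avg_rpkm & cm$case < thr$min_avg_rpkm)
  tibble(entity_id = cm$transcript_id, gene_id = cm$gene_id,
         rule = "isoform_abundance",
         control_mean = cm$control, case_mean = cm$case, pass = pass)
}

# replicate-level proportions over a set of surviving isoforms, optionally
# renormalized within (sample, gene) after dropping filtered isoforms
surviving_proportions <- function(quant, surviving_isoforms, renormalize = TRUE) {
  iso <- quant$isoforms[quant$isoforms$transcript_id %in% surviving_isoforms, ]
  if (renormalize) {
    iso <- iso |>
      group_by(.data$sample_id, .data$gene_id) |>
      mutate(proportion = .data$est_count / sum(.data$est_count)) |>
      ungroup()
  }
  iso
}

#' Enlarged-proportion variance filter
#'
#' Multiplies replicate-level isoform proportions by
#' `thr$enlargement_factor` (100) and computes, per isoform and per
#' condition, the variance across replicates. A gene passes only when
#' *every* isoform's enlarged-proportion variance is below
#' `thr$variance_cutoff` (150, strict `<`) in *each* condition — i.e. its
#' isoform proportions are consistent across replicates. Genes with an
#' undefined proportion in any replicate (zero gene reads) fail with rule
#' `"undefined_proportion"`.
#'
#' @param quant An `iso_quant`.
#' @param thr Thresholds; `thr$variance_denominator` selects the unbiased
#'   (`"n-1"`, default) or population (`"n"`) variance, and
#'   `thr$renormalize_proportions` controls whether proportions are
#'   recomputed over the surviving isoforms.
#' @param surviving_isoforms Character vector of isoform ids that passed the
#'   abundance filter; defaults to all isoforms.
#' @return Filter report tibble: one row per tested gene with
#'   `max_variance` (worst isoform x condition) and `pass`.
#' @export
variance_filter <- function(quant, thr = analysis_thresholds(),
                            surviving_isoforms = unique(quant$isoforms$transcript_id)) {
  thr <- as_thresholds(thr)
  check_design(quant$design, require_replicates = 2L)
  iso <- surviving_proportions(quant, surviving_isoforms,
                               thr$renormalize_proportions)
  if (nrow(iso) == 0)
    return(tibble(entity_id = character(), rule = character(),
                  max_variance = numeric(), pass = logical()))
  denom_n <- identical(thr$variance_denominator, "n")
  per_iso <- iso |>
    mutate(enlarged = .data$proportion * thr$enlargement_factor) |>
    group_by(.data$gene_id, .data$transcript_id, .data$condition) |>
    summarise(v = {
      x <- .data$enlarged
      if (anyNA(x)) NA_real_
      else if (denom_n) mean((x - mean(x))^2) else var(x)
    }, .groups = "drop")
  rep_counts <- table(quant$design$condition)
  if (any(rep_counts < 2))
    abort("variance filter needs >= 2 replicates per condition")
  per_gene <- per_iso |>
    group_by(.data$gene_id) |>
    summarise(max_variance = if (anyNA(.data$v)) NA_real_ else max(.data$v),
              .groups = "drop")
  tibble(entity_id = per_gene$gene_id,
         rule = ifelse(is.na(per_gene$max_variance),
                       "undefined_proportion", "proportion_variance"),
         max_variance = per_gene$max_variance,
         pass = !is.na(per_gene$max_variance) &
           per_gene$max_variance < thr$variance_cutoff)
}

#' Select differential-splicing candidate genes
#'
#' A gene is a candidate when it passed the gene abundance filter, has more
#' than one isoform surviving the isoform abundance filter ("more than 1
#' expressed isoform"), and passed the enlarged-proportion variance filter.
#'
#' @param gene_report,isoform_report,variance_report Filter reports from the
#'   three filter functions.
#' @return Sorted character vector of candidate gene ids.
#' @export
select_ds_candidates <- function(gene_report, isoform_report, variance_report) {
  genes_ok <- gene_report$entity_id[gene_report$pass]
  multi_iso <- isoform_report |>
    filter(.data$pass) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n >= 2) |>
    pull("gene_id")
  var_ok <- variance_report$entity_id[variance_report$pass]
  sort(intersect(intersect(genes_ok, multi_iso), var_ok))
}

#' Run all three filters and collect the candidate set
#'
#' Convenience wrapper: gene abundance filter, isoform abundance filter on
#' the survivors, variance filter on the surviving isoforms, then
#' [select_ds_candidates()].
#'
#' @param quant An `iso_quant`.
#' @param thr Thresholds.
#' @return List with the three reports (`genes`, `isoforms`, `variance`),
#'   `surviving_isoforms`, and `candidates`.
#' @export
run_filters <- function(quant, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  g <- abundance_filter_genes(quant, thr)
  i <- abundance_filter_isoforms(quant, thr, g$entity_id[g$pass])
  surv_iso <- i$entity_id[i$pass]
  multi <- i |> filter(.data$pass) |> dplyr::count(.data$gene_id) |>
    filter(.data$n >= 2) |> pull("gene_id")
  v <- variance_filter(quant, thr, surv_iso)
  v <- v[v$entity_id %in% multi, ]
  list(genes = g, isoforms = i, variance = v,
       surviving_isoforms = surv_iso,
       candidates = select_ds_candidates(g, i, v))
}
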