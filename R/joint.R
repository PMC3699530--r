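#' Gene- or isoform-level fold change
#'
#' Mean case RPKM over mean control RPKM. A zero control mean with positive
#' case mean yields `Inf`; both zero yields `NA` (excluded from region
#' classification downstream).
#'
#' @param quant An `iso_quant`.
#' @param ids Gene ids (`level = "gene"`) or transcript ids
#'   (`level = "isoform"`).
#' @param level `"gene"` or `"isoform"`.
#' @return Tibble: id column, `control_mean`, `case_mean`, `fold_change`.
#' @export
fold_change <- function(quant, ids, level = c("gene", "isoform")) {
  level <- match.arg(level)
  if (level == "gene") {
    cm <- condition_means(quant$genes[quant$genes$gene_id %in% ids, ],
                          "rpkm", "gene_id")
    cm <- cm[match(ids, cm$gene_id), ]
    id_col <- tibble(gene_id = ids)
  } else {
    iso <- quant$isoforms[quant$isoforms$transcript_id %in% ids, ]
    cm <- condition_means(iso, "rpkm", "transcript_id")
    cm <- cm[match(ids, cm$transcript_id), ]
    id_col <- tibble(transcript_id = ids)
  }
  fc <- ifelse(cm$control > 0, cm$case / cm$control,
               ifelse(cm$case > 0, Inf, NA_real_))
  dplyr::bind_cols(id_col, tibble(control_mean = cm$control,
                                  case_mean = cm$case, fold_change = fc))
}

#' Categorize gene-level differential expression from fold change
#'
#' Up-regulation is fold change > `thr$fc_up` (1.25), down-regulation
#' < `thr$fc_down` (0.8); anything in the closed interval between them —
#' including the endpoints — is `no_change`. `Inf` maps to `up`; `NA` stays
#' `NA` (gene excluded from regions).
#'
#' @param fc Numeric fold change(s).
#' @param thr Thresholds.
#' @return Character vector in `{down, no_change, up}` (or `NA`).
#' @examples
#' de_category(c(0.93, 0.5, 1.25, 2))
#' @export
de_category <- function(fc, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  dplyr::case_when(is.na(fc) ~ NA_character_,
                   fc > thr$fc_up ~ "up",
                   fc < thr$fc_down ~ "down",
                   TRUE ~ "no_change")
}

#' Is differential splicing significant?
#'
#' `TRUE` iff \eqn{-\ln(\mathrm{FDR})} exceeds `thr$ds_neglog_fdr` (3, i.e.
#' FDR below \eqn{e^{-3}} ~= 0.0498). An FDR of exactly 0 is significant
#' (infinite negative log).
#'
#' @param fdr FDR value(s) in `[0, 1]`.
#' @param thr Thresholds.
#' @return Logical vector.
#' @examples
#' ds_significant(c(1.48e-09, 0.5))
#' @export
ds_significant <- function(fdr, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) abort("fdr must lie in [0, 1]")
  -log(fdr) > thr$ds_neglog_fdr
}

#' Joint-analysis region (1-6) from DE category and DS significance
#'
#' The DE-vs-DS plane is partitioned into six regions: odd regions hold
#' genes without significant differential splicing, even regions with.
#' Region 3/4 are the no-change column; with the default orientation the
#' down-regulated side is 1/2 and the up-regulated side 5/6
#' (`thr$region_orientation = "down_right"` swaps 1/2 with 5/6).
#'
#' @param de Character vector in `{down, no_change, up}`.
#' @param ds Logical differential-splicing significance.
#' @param thr Thresholds.
#' @return Integer region 1-6 (`NA` when either input is `NA`).
#' @examples
#' classify_region("no_change", TRUE)  # 4
#' @export
classify_region <- function(de, ds, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  bad <- setdiff(unique(de[!is.na(de)]), c("down", "no_change", "up"))
  if (length(bad)) abort(paste0("unknown DE category: ", paste(bad, collapse = ", ")))
  left <- if (thr$region_orientation == "up_right") "down" else "up"
  right <- if (thr$region_orientation == "up_right") "up" else "down"
  base <- dplyr::case_when(de == left ~ 1L, de == "no_change" ~ 3L,
                           de == right ~ 5L, TRUE ~ NA_integer_)
  out <- base + as.integer(ds)
  out[is.na(de) | is.na(ds)] <- NA_integer_
  out
}

#' Detect a major-minor isoform switch
#'
#' The major isoform per condition is the argmax of that column of the
#' gene's proportion matrix; a switch occurs when the two argmax identities
#' differ. A tie for the maximum in either column is flagged and reported as
#' no switch.
#'
#' @param m A `proportion_matrix`.
#' @return One-row tibble: `gene_id`, `switch`, `major_control`,
#'   `major_case`, `tie`.
#' @examples
#' detect_switch(proportion_matrix(c(77.35, 22.65), c(27.10, 72.90)))
#' @export
detect_switch <- function(m) {
  stopifnot(nrow(m) >= 1)
  tie <- FALSE
  majors <- vapply(c("control", "case"), function(col) {
    x <- m[[col]]
    mx <- max(x)
    if (sum(x == mx) > 1) { tie <<- TRUE; return(NA_character_) }
    m$transcript_id[which.max(x)]
  }, "")
  tibble(gene_id = m$gene_id[1],
         switch = !tie && majors[1] != majors[2],
         major_control = unname(majors[1]), major_case = unname(majors[2]),
         tie = tie)
}

#' Assemble the joint DE/DS result table
#'
#' One record per candidate gene: gene fold change, DS FDR and
#' \eqn{-\ln(\mathrm{FDR})}, DE category, region 1-6, major isoforms per
#' condition and the switch flag, plus the DE-vs-DS scatter coordinates
#' (`ln_fc`, `neglog_fdr`). Region counts over 1-6 are attached as the
#' `region_counts` attribute.
#'
#' @param ds_results Output of [run_ds_analysis()].
#' @param quant An `iso_quant`.
#' @param thr Thresholds.
#' @param surviving_isoforms Isoforms surviving the abundance filter
#'   (default all), used for the proportion matrices.
#' @return A `joint_table` tibble.
#' @export
joint_table <- function(ds_results, quant, thr = analysis_thresholds(),
                        surviving_isoforms = NULL) {
  thr <- as_thresholds(thr)
  fc <- fold_change(quant, ds_results$gene_id, level = "gene")
  sw <- purrr::map_dfr(ds_results$gene_id, function(g)
    detect_switch(build_proportion_matrix(quant, g, thr, surviving_isoforms)))
  out <- ds_results |>
    select("gene_id", "n_isoforms", "p_value", "fdr") |>
    rename(ds_fdr = "fdr") |>
    left_join(select(fc, "gene_id", "fold_change"), by = "gene_id") |>
    left_join(sw, by = "gene_id") |>
    mutate(neglog_fdr = -log(.data$ds_fdr),
           ln_fc = log(.data$fold_change),
           de_category = de_category(.data$fold_change, thr),
           ds_sig = ds_significant(.data$ds_fdr, thr),
           region = classify_region(.data$de_category, .data$ds_sig, thr)) |>
    select("gene_id", "n_isoforms", "fold_change", "ln_fc", "p_value",
           "ds_fdr", "neglog_fdr", "de_category", "ds_sig", "region",
           "switch", "major_control", "major_case", "tie")
  counts <- table(factor(out$region, levels = 1:6))
  attr(out, "region_counts") <- setNames(as.integer(counts), names(counts))
  class(out) <- c("joint_table", class(out))
  out
}

#' @exportS3Method generics::glance
glance.joint_table <- function(x, ...) {
  rc <- attr(x, "region_counts")
  tibble(n_genes = nrow(x),
         n_ds_significant = sum(x$ds_sig, na.rm = TRUE),
         n_switch = sum(x$switch, na.rm = TRUE),
         n_region4 = rc[["4"]])
}

#' @export
print.joint_table <- function(x, ...) {
  rc <- attr(x, "region_counts")
  cat("Joint DE/DS table:", nrow(x), "genes; region counts",
      paste(sprintf("%s:%d", names(rc), rc), collapse = " "), "\n")
  NextMethod()
}
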