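#' Run the full joint expression/splicing pipeline
#'
#' Orchestrates the stages end-to-end: isoform/gene quantification (RAEM +
#' RPKM), abundance and variance filtering, the pseudo-count chi-square
#' differential-splicing test with BH FDR, the six-region joint
#' classification with switch calls, and (optionally) novel-junction
#' detection, transcript composition, annotation augmentation and a second
#' quantification + joint analysis pass on the augmented annotation. Each
#' stage writes a TSV into `out_dir`; a run log records thresholds and
#' per-stage entity counts. The pipeline itself is deterministic: rerunning
#' on the same inputs reproduces the tables byte for byte.
#'
#' @param annotation Annotation tibble or path to a GTF file.
#' @param design Design tibble (or TSV path) with `sample_id`, `condition`,
#'   `path` (per-sample SAM/BAM or compatibility TSV) and, when the novel
#'   stage runs, `junction_path` (per-sample junctions BED12).
#' @param out_dir Output directory (created if needed).
#' @param thr [analysis_thresholds()].
#' @param run_novel Run the novel-transcript stage? Default `TRUE` when
#'   every sample has a `junction_path`.
#' @param min_support,min_case_samples Novel-junction thresholds (see
#'   [find_novel_junctions()]).
#' @param tol,max_iter EM settings.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`quant`, `filters`, `ds`, `joint`, `novel_calls`, `augmented`,
#'   `joint_augmented`) and the written `files`.
#' @export
run_pipeline <- function(annotation, design, out_dir,
                         thr = analysis_thresholds(),
                         run_novel = NULL, min_support = 2,
                         min_case_samples = 1,
                         tol = 1e-6, max_iter = 1000) {
  thr <- as_thresholds(thr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("spliceswitch %s",
                         as.character(utils::packageVersion("spliceswitch"))),
                 sprintf("thresholds: min_avg_rpkm=%g variance_cutoff=%g fc=(%g,%g) neglog_fdr=%g",
                         thr$min_avg_rpkm, thr$variance_cutoff,
                         thr$fc_down, thr$fc_up, thr$ds_neglog_fdr))
  say <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  if (is.character(annotation)) annotation <- read_gtf(annotation)
  if (is.character(design))
    design <- readr::read_tsv(design, comment = "#", show_col_types = FALSE)
  design <- check_design(design)
  if (is.null(run_novel))
    run_novel <- "junction_path" %in% names(design) &&
      all(!is.na(design$junction_path))

  stage <- "quantify"
  res <- tryCatch({
    quant <- quantify_samples(annotation, design, tol = tol, max_iter = max_iter)
    say("quantify: %d genes, %d isoforms, %d samples",
        dplyr::n_distinct(quant$genes$gene_id),
        dplyr::n_distinct(quant$isoforms$transcript_id), nrow(design))
    readr::write_tsv(quant$isoforms, file.path(out_dir, "abundance_isoforms.tsv"))
    readr::write_tsv(quant$genes, file.path(out_dir, "abundance_genes.tsv"))

    stage <- "filter"
    flt <- run_filters(quant, thr)
    say("filter: %d/%d genes pass abundance, %d isoforms expressed, %d candidates",
        sum(flt$genes$pass), nrow(flt$genes), sum(flt$isoforms$pass),
        length(flt$candidates))
    report <- bind_rows(
      select(flt$genes, "entity_id", "rule", "pass"),
      select(flt$isoforms, "entity_id", "rule", "pass"),
      select(flt$variance, "entity_id", "rule", "pass"))
    readr::write_tsv(report, file.path(out_dir, "filter_report.tsv"))

    if (!length(flt$candidates))
      abort("no differential-splicing candidates survive the filters")

    stage <- "ds-test"
    ds <- run_ds_analysis(quant, flt$candidates, thr, flt$surviving_isoforms)
    say("ds-test: %d candidates, %d at FDR < %g",
        nrow(ds), sum(ds$fdr < thr$fdr_alpha), thr$fdr_alpha)
    readr::write_tsv(ds, file.path(out_dir, "ds_results.tsv"))

    stage <- "joint"
    jt <- joint_table(ds, quant, thr, flt$surviving_isoforms)
    rc <- attr(jt, "region_counts")
    say("joint: regions %s; %d switch genes",
        paste(sprintf("%s:%d", names(rc), rc), collapse = " "),
        sum(jt$switch, na.rm = TRUE))
    readr::write_tsv(as_tibble(jt), file.path(out_dir, "joint_table.tsv"))

    novel_calls <- NULL; augmented <- NULL; jt2 <- NULL
    if (run_novel) {
      stage <- "novel"
      if (!"junction_path" %in% names(design))
        abort("novel stage needs a 'junction_path' column in the design")
      observed <- purrr::map_dfr(seq_len(nrow(design)), function(i)
        read_junction_bed(design$junction_path[i], design$sample_id[i]))
      novel_calls <- find_novel_junctions(observed, annotation, design,
                                          min_support = min_support,
                                          min_case_samples = min_case_samples)
      say("novel: %d junction calls (%d condition-specific)",
          nrow(novel_calls), sum(novel_calls$condition_specific))
      readr::write_tsv(novel_calls, file.path(out_dir, "novel_junctions.tsv"))
      cs <- novel_calls[novel_calls$condition_specific, ]
      if (nrow(cs)) {
        novel_tx <- compose_novel_transcripts(annotation, cs)
        augmented <- augment_annotation(annotation, novel_tx)
        write_gtf(augmented, file.path(out_dir, "augmented_annotation.gtf"))
        stage <- "requantify"
        q2 <- quantify_samples(augmented, design, tol = tol, max_iter = max_iter)
        f2 <- run_filters(q2, thr)
        if (length(f2$candidates)) {
          d2 <- run_ds_analysis(q2, f2$candidates, thr, f2$surviving_isoforms)
          jt2 <- joint_table(d2, q2, thr, f2$surviving_isoforms)
          readr::write_tsv(as_tibble(jt2),
                          file.path(out_dir, "joint_table_augmented.tsv"))
          say("requantify: %d candidates on augmented annotation", nrow(d2))
        }
      }
    }
    list(quant = quant, filters = flt, ds = ds, joint = jt,
         novel_calls = novel_calls, augmented = augmented,
         joint_augmented = jt2)
  }, error = function(e) {
    writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s",
                                    stage, conditionMessage(e))), log_path)
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  writeLines(log_lines, log_path)
  res$files <- list.files(out_dir, full.names = TRUE)
  invisible(res)
}
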