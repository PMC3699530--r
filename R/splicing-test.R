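#' Build a gene's n x 2 matrix of condition-averaged enlarged proportions
#'
#' Each entry is the mean over one condition's replicates of the isoform's
#' proportion multiplied by 100 ("enlarged proportion"); the two columns are
#' the control and case averages, used directly as pseudo counts by the
#' differential-splicing test. Columns are renormalized to sum to 100 only
#' when numerical drift exceeds 1e-6.
#'
#' @param quant An `iso_quant`.
#' @param gene_id Gene to build the matrix for.
#' @param thr Thresholds (enlargement factor, renormalization policy).
#' @param surviving_isoforms Isoforms to include (default: all of the
#'   gene's isoforms). With `thr$renormalize_proportions` the replicate
#'   proportions are recomputed over this set first.
#' @return A `proportion_matrix`: tibble with `gene_id`, `transcript_id`,
#'   `control`, `case`.
#' @examples
#' # a gene whose major isoform carries ~77% in control and ~27% in case
#' @export
build_proportion_matrix <- function(quant, gene_id, thr = analysis_thresholds(),
                                    surviving_isoforms = NULL) {
  thr <- as_thresholds(thr)
  stopifnot(gene_id %in% quant$isoforms$gene_id)
  iso_ids <- unique(quant$isoforms$transcript_id[quant$isoforms$gene_id == gene_id])
  keep <- if (is.null(surviving_isoforms)) iso_ids else
    intersect(iso_ids, surviving_isoforms)
  iso <- surviving_proportions(quant, keep, thr$renormalize_proportions)
  iso <- iso[iso$gene_id == gene_id, ]
  bad <- iso$sample_id[is.na(iso$proportion)]
  if (length(bad))
    abort(paste0("undefined isoform proportion for gene ", gene_id,
                 " in sample(s): ", paste(unique(bad), collapse = ", ")))
  m <- iso |>
    mutate(enlarged = .data$proportion * thr$enlargement_factor) |>
    group_by(.data$transcript_id, .data$condition) |>
    summarise(avg = mean(.data$enlarged), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "avg") |>
    mutate(gene_id = gene_id) |>
    select("gene_id", "transcript_id", "control", "case")
  total <- thr$enlargement_factor
  for (col in c("control", "case")) {
    s <- sum(m[[col]])
    if (abs(s - total) > 1e-6) m[[col]] <- m[[col]] * total / s
  }
  class(m) <- c("proportion_matrix", class(m))
  m
}

#' Construct a proportion matrix from plain numbers
#'
#' For working directly with published condition-averaged enlarged
#' proportions (percentages).
#'
#' @param control,case Numeric vectors of enlarged proportions (sum 100).
#' @param transcript_id Optional isoform ids.
#' @param gene_id Optional gene id.
#' @return A `proportion_matrix` tibble.
#' @examples
#' proportion_matrix(control = c(77.35, 22.65), case = c(27.10, 72.90))
#' @export
proportion_matrix <- function(control, case,
                              transcript_id = paste0("iso", seq_along(control)),
                              gene_id = "gene") {
  stopifnot(length(control) == length(case))
  m <- tibble(gene_id = gene_id, transcript_id = transcript_id,
              control = as.numeric(control), case = as.numeric(case))
  class(m) <- c("proportion_matrix", class(m))
  m
}

#' Pseudo-count chi-square test of differential splicing
#'
#' Pearson's chi-square test of independence on a gene's n x 2 matrix of
#' condition-averaged enlarged proportions, treating the averaged
#' percentages as pseudo counts. Yates' continuity correction is applied for
#' 2 x 2 tables (each cell contribution uses `max(0, |O - E| - 0.5)`),
#' mirroring `chisq.test`; larger tables use the uncorrected statistic.
#' Rows summing to zero (isoform absent in both conditions) are dropped with
#' a warning before testing, reducing the degrees of freedom.
#'
#' @param m A `proportion_matrix` (or an n x 2 numeric matrix).
#' @param yates `"2x2"` (default), `"always"`, or `"never"`.
#' @return One-row tibble: `gene_id`, `n_isoforms`, `statistic`, `df`,
#'   `p_value`, `yates_applied`.
#' @examples
#' chisq_yates_test(proportion_matrix(c(77.35, 22.65), c(27.10, 72.90)))
#' @export
chisq_yates_test <- function(m, yates = c("2x2", "always", "never")) {
  yates <- match.arg(yates)
  if (is.matrix(m)) m <- proportion_matrix(m[, 1], m[, 2])
  O <- cbind(m$control, m$case)
  if (any(O < 0)) abort("proportion matrix entries must be non-negative")
  gene_id <- m$gene_id[1]
  zero <- rowSums(O) == 0
  if (any(zero)) {
    warn(sprintf("gene %s: dropping %d isoform row(s) with zero proportion in both conditions",
                 gene_id, sum(zero)))
    O <- O[!zero, , drop = FALSE]
  }
  n <- nrow(O)
  if (n < 2) abort("need >= 2 isoform rows with non-zero proportions to test")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  use_yates <- yates == "always" || (yates == "2x2" && n == 2)
  dev <- abs(O - E)
  if (use_yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  df <- n - 1
  tibble(gene_id = gene_id, n_isoforms = n, statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         yates_applied = use_yates)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min_{j: p_j >= p_i} p_j * m / rank_j`,
#' capped at 1 (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-splicing analysis over the candidate set
#'
#' Builds each candidate gene's n x 2 pseudo-count matrix, runs the
#' Yates-corrected chi-square test, and adjusts the raw p-values by
#' Benjamini-Hochberg across exactly the candidate set.
#'
#' @param quant An `iso_quant`.
#' @param candidates Character vector of candidate gene ids.
#' @param thr Thresholds.
#' @param surviving_isoforms Isoforms surviving the abundance filter
#'   (default: all).
#' @return Tibble sorted by FDR: `gene_id`, `n_isoforms`, `statistic`, `df`,
#'   `p_value`, `fdr`, `yates_applied`.
#' @export
run_ds_analysis <- function(quant, candidates, thr = analysis_thresholds(),
                            surviving_isoforms = NULL) {
  thr <- as_thresholds(thr)
  if (!length(candidates)) abort("candidate list is empty")
  res <- purrr::map_dfr(candidates, function(g) {
    m <- build_proportion_matrix(quant, g, thr, surviving_isoforms)
    chisq_yates_test(m, yates = thr$yates)
  })
  res$fdr <- bh_fdr(res$p_value)
  arrange(res, .data$fdr, .data$p_value)
}
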