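#' Find novel splice junctions supported by alignment evidence
#'
#' A junction call requires: (i) the junction is absent from the annotated
#' junction universe; (ii) its donor end coincides with an annotated exon
#' end and its acceptor start with an annotated exon start of the *same*
#' gene; (iii) summed read support reaches `min_support`. Junctions whose
#' boundary match spans two genes are ambiguous and excluded (with a
#' message). A call is condition-specific when it was observed in at least
#' `min_case_samples` case samples and in no control sample.
#'
#' Mechanism labels: `skipping_exon` by default; two calls of the same gene
#' whose intron intervals overlap without one containing the other are
#' relabelled `mutually_exclusive` (complementary skipping junctions).
#'
#' @param observed Junction tibble (rows from [read_junction_bed()] across
#'   samples: `chrom`, `donor_end`, `acceptor_start`, `strand`,
#'   `read_support`, `sample_id`).
#' @param ann Annotation tibble.
#' @param design Design tibble mapping `sample_id` to `condition`.
#' @param min_support Minimum summed read support (default 2).
#' @param min_case_samples Minimum number of case samples observing the
#'   junction for condition-specificity (default 1).
#' @return Tibble of calls: junction coordinates, `gene_id`, `parents`
#'   (comma-separated transcripts containing both flanking exons),
#'   `mechanism`, `read_support`, `n_case_samples`, `n_control_samples`,
#'   `condition_specific`.
#' @export
find_novel_junctions <- function(observed, ann, design, min_support = 2,
                                 min_case_samples = 1) {
  ann <- validate_annotation(ann)
  design <- check_design(design)
  annotated <- extract_annotated_junctions(ann)
  ann_key <- paste(annotated$chrom, annotated$donor_end,
                   annotated$acceptor_start, sep = ":")
  obs <- as_tibble(observed) |>
    left_join(select(design, "sample_id", "condition"), by = "sample_id") |>
    group_by(.data$chrom, .data$donor_end, .data$acceptor_start) |>
    summarise(read_support = sum(.data$read_support),
              n_case_samples = dplyr::n_distinct(
                .data$sample_id[.data$condition == "case"]),
              n_control_samples = dplyr::n_distinct(
                .data$sample_id[.data$condition == "control"]),
              .groups = "drop")
  # junctions are matched irrespective of strand (may be undetermined)
  obs <- obs[!(paste(obs$chrom, obs$donor_end, obs$acceptor_start, sep = ":")
               %in% ann_key), ]
  obs <- obs[obs$read_support >= min_support, ]
  if (!nrow(obs)) return(empty_novel_calls())

  exon_ends <- distinct(ann, .data$gene_id, .data$chrom, boundary = .data$end)
  exon_starts <- distinct(ann, .data$gene_id, .data$chrom, boundary = .data$start)
  calls <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    j <- obs[i, ]
    g_d <- exon_ends$gene_id[exon_ends$chrom == j$chrom &
                               exon_ends$boundary == j$donor_end]
    g_a <- exon_starts$gene_id[exon_starts$chrom == j$chrom &
                                 exon_starts$boundary == j$acceptor_start]
    genes <- intersect(unique(g_d), unique(g_a))
    if (!length(genes)) return(NULL)
    if (length(genes) > 1) {
      inform(sprintf("junction %s:%d-%d matches %d genes; excluded as ambiguous",
                     j$chrom, j$donor_end, j$acceptor_start, length(genes)))
      return(NULL)
    }
    gene_ann <- ann[ann$gene_id == genes, ]
    parents <- gene_ann |>
      group_by(.data$transcript_id) |>
      summarise(has_both = any(.data$end == j$donor_end) &&
                  any(.data$start == j$acceptor_start) &&
                  any(.data$start >= j$donor_end & .data$end <= j$acceptor_start),
                .groups = "drop") |>
      filter(.data$has_both) |>
      pull("transcript_id")
    if (!length(parents)) return(NULL)  # no parent with a skippable exon between
    tibble(chrom = j$chrom, donor_end = j$donor_end,
           acceptor_start = j$acceptor_start,
           strand = gene_ann$strand[1], gene_id = genes,
           parents = paste(parents, collapse = ","),
           read_support = j$read_support,
           n_case_samples = j$n_case_samples,
           n_control_samples = j$n_control_samples,
           condition_specific = j$n_control_samples == 0 &
             j$n_case_samples >= min_case_samples)
  })
  if (is.null(calls) || !nrow(calls)) return(empty_novel_calls())
  calls$mechanism <- "skipping_exon"
  for (g in unique(calls$gene_id)) {
    idx <- which(calls$gene_id == g)
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      ov <- calls$donor_end[a] < calls$acceptor_start[b] &&
        calls$donor_end[b] < calls$acceptor_start[a]
      contained <- (calls$donor_end[a] <= calls$donor_end[b] &&
                      calls$acceptor_start[a] >= calls$acceptor_start[b]) ||
        (calls$donor_end[b] <= calls$donor_end[a] &&
           calls$acceptor_start[b] >= calls$acceptor_start[a])
      if (ov && !contained)
        calls$mechanism[c(a, b)] <- "mutually_exclusive"
    }
  }
  arrange(calls, .data$chrom, .data$donor_end, .data$acceptor_start)
}

empty_novel_calls <- function() {
  tibble(chrom = character(), donor_end = numeric(),
         acceptor_start = numeric(), strand = character(),
         gene_id = character(), parents = character(),
         read_support = numeric(), n_case_samples = integer(),
         n_control_samples = integer(), condition_specific = logical(),
         mechanism = character())
}

#' Compose a novel transcript by exon skipping
#'
#' Given an annotated parent transcript and a novel junction whose ends lie
#' on two of the parent's exon boundaries, builds the transcript that splices
#' those exons together: the parent's exon chain minus every exon strictly
#' inside the junction's intron. The new id is the parent id suffixed `"_N"`
#' (`suffix` lets callers disambiguate several junctions on one parent).
#'
#' @param ann Annotation tibble (must contain the parent).
#' @param parent_id Parent transcript id.
#' @param donor_end,acceptor_start Novel junction coordinates (0-based
#'   half-open intron interval).
#' @param suffix Id suffix, default `"_N"`.
#' @return Annotation tibble rows for the new transcript
#'   (`is_novel = TRUE`, `parent_id` set).
#' @examples
#' ann <- annotation_tbl("g", "g.t1", "chr1",
#'                       c(100, 300, 500), c(200, 400, 600), "+")
#' compose_novel_transcript(ann, "g.t1", 200, 500)
#' @export
compose_novel_transcript <- function(ann, parent_id, donor_end, acceptor_start,
                                     suffix = "_N") {
  ann <- validate_annotation(ann)
  par <- ann[ann$transcript_id == parent_id, ]
  if (!nrow(par)) abort(paste0("parent transcript not found: ", parent_id))
  if (!any(par$end == donor_end) || !any(par$start == acceptor_start))
    abort("junction ends must coincide with exon boundaries of the parent")
  skipped <- par$start >= donor_end & par$end <= acceptor_start
  if (!any(skipped))
    abort("junction skips no exon of the parent (adjacent exons would make it an annotated junction)")
  novel <- par[!skipped, ]
  novel$transcript_id <- paste0(parent_id, suffix)
  novel$is_novel <- TRUE
  novel$parent_id <- parent_id
  novel
}

#' Compose novel transcripts for a set of junction calls
#'
#' Applies [compose_novel_transcript()] to every (parent, junction) pair in
#' a call table; when one parent receives several junctions, the second and
#' later transcripts are suffixed `"_N2"`, `"_N3"`, ... to keep ids unique.
#'
#' @param ann Annotation tibble.
#' @param calls Output of [find_novel_junctions()] (optionally filtered,
#'   e.g. to condition-specific calls).
#' @return Annotation tibble of all composed novel transcripts.
#' @export
compose_novel_transcripts <- function(ann, calls) {
  seen <- character()
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    for (p in strsplit(calls$parents[i], ",")[[1]]) {
      k <- sum(seen == p) + 1L
      seen <- c(seen, p)
      sfx <- if (k == 1) "_N" else paste0("_N", k)
      rows[[length(rows) + 1L]] <- compose_novel_transcript(
        ann, p, calls$donor_end[i], calls$acceptor_start[i], suffix = sfx)
    }
  }
  bind_rows(rows)
}

#' Augment an annotation with novel transcripts
#'
#' Appends composed novel transcripts to their genes so that
#' quantification, filtering, the splicing test and the joint analysis can
#' be re-run on the augmented annotation.
#'
#' @param ann Annotation tibble.
#' @param novel Annotation tibble of novel transcripts (e.g. from
#'   [compose_novel_transcripts()]); may be empty.
#' @return The augmented, validated annotation.
#' @export
augment_annotation <- function(ann, novel) {
  ann <- validate_annotation(ann)
  if (is.null(novel) || nrow(novel) == 0) return(ann)
  dup <- intersect(unique(novel$transcript_id), unique(ann$transcript_id))
  if (length(dup))
    abort(paste0("duplicate transcript_id on augmentation: ",
                 paste(dup, collapse = ", ")))
  validate_annotation(bind_rows(ann, novel))
}
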