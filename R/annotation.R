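#' Exon-level transcript annotation tables
#'
#' The package represents an annotation as a tidy tibble with one row per
#' exon and columns `gene_id`, `transcript_id`, `chrom`, `start`, `end`,
#' `strand`, `is_novel`, `parent_id`. Coordinates are 0-based half-open
#' throughout the package; conversion from the 1-based inclusive GTF
#' convention (and from 0-based BED) happens only at the I/O boundary.
#'
#' @param gene_id,transcript_id,chrom,start,end,strand,is_novel,parent_id
#'   Vectors, one element per exon. `strand` must be `"+"` or `"-"`;
#'   `parent_id` is the annotated parent of a novel transcript (otherwise
#'   `NA`).
#' @return A validated annotation tibble, exons sorted by ascending start
#'   within each transcript.
#' @examples
#' ann <- annotation_tbl(
#'   gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+")
#' transcript_lengths(ann)
#' @export
annotation_tbl <- function(gene_id, transcript_id, chrom, start, end, strand,
                           is_novel = FALSE, parent_id = NA_character_) {
  ann <- tibble(gene_id = as.character(gene_id),
                transcript_id = as.character(transcript_id),
                chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end),
                strand = as.character(strand),
                is_novel = as.logical(is_novel),
                parent_id = as.character(parent_id))
  validate_annotation(ann)
}

#' Validate an annotation tibble
#'
#' Checks the invariants the rest of the pipeline relies on: positive-width
#' exons, a single chromosome and strand per transcript, non-overlapping
#' sorted exons within a transcript, explicit `+`/`-` strands, and a
#' non-empty `parent_id` plus an `"_N"`-suffixed id for novel transcripts.
#'
#' @param ann An exon-level annotation data frame.
#' @return The annotation as a sorted tibble (invisibly usable in pipes).
#' @export
validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  needed <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(needed %in% names(ann)))
    abort(paste0("annotation must have columns: ", paste(needed, collapse = ", ")))
  if (!"is_novel" %in% names(ann)) ann$is_novel <- FALSE
  if (!"parent_id" %in% names(ann)) ann$parent_id <- NA_character_
  ann$is_novel[is.na(ann$is_novel)] <- FALSE
  if (nrow(ann) == 0) return(ann)
  if (any(ann$start >= ann$end))
    abort("exon start must be < end (0-based half-open)")
  if (!all(ann$strand %in% c("+", "-")))
    abort("transcript exons must have strand '+' or '-'")
  ann <- arrange(ann, .data$gene_id, .data$transcript_id, .data$start)
  per_tx <- ann |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom),
              n_strand = dplyr::n_distinct(.data$strand),
              overlap = any(.data$start[-1] < .data$end[-dplyr::n()]),
              novel = any(.data$is_novel),
              parent = dplyr::first(.data$parent_id),
              .groups = "drop")
  if (any(per_tx$n_chrom > 1))
    abort(paste0("transcript spans multiple chromosomes: ",
                 paste(per_tx$transcript_id[per_tx$n_chrom > 1], collapse = ", ")))
  if (any(per_tx$n_strand > 1))
    abort(paste0("transcript has mixed strands: ",
                 paste(per_tx$transcript_id[per_tx$n_strand > 1], collapse = ", ")))
  if (any(per_tx$overlap))
    abort(paste0("overlapping exons within transcript: ",
                 paste(per_tx$transcript_id[per_tx$overlap], collapse = ", ")))
  bad_novel <- per_tx$novel & (is.na(per_tx$parent) | per_tx$parent == "" |
                                 !grepl("_N[0-9]*$", per_tx$transcript_id))
  if (any(bad_novel))
    abort(paste0("novel transcripts need a parent_id and an '_N' id suffix: ",
                 paste(per_tx$transcript_id[bad_novel], collapse = ", ")))
  ann
}

#' Transcript lengths (sum of exon lengths)
#'
#' @param ann Annotation tibble.
#' @return Tibble with `gene_id`, `transcript_id`, `length`.
#' @export
transcript_lengths <- function(ann) {
  ann |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(length = sum(.data$end - .data$start), .groups = "drop")
}

#' Gene union-exon lengths
#'
#' Length of the union of all exon intervals of a gene's transcripts; the
#' denominator of gene-level RPKM ("exon model" length).
#'
#' @param ann Annotation tibble.
#' @return Tibble with `gene_id`, `union_length`.
#' @export
gene_union_lengths <- function(ann) {
  ann |>
    group_by(.data$gene_id) |>
    summarise(union_length = {
      ir <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1, end = .data$end))
      sum(IRanges::width(ir))
    }, .groups = "drop")
}

#' Extract the annotated splice-junction universe
#'
#' One junction per adjacent exon pair per transcript, de-duplicated over
#' `(chrom, donor_end, acceptor_start, strand)`. `donor_end` is the
#' (exclusive, 0-based) end of the upstream exon; `acceptor_start` the start
#' of the downstream exon.
#'
#' @param ann Annotation tibble.
#' @return Junction tibble: `chrom`, `donor_end`, `acceptor_start`, `strand`.
#' @examples
#' ann <- annotation_tbl("g", "g.t", "chr1", c(100, 300), c(200, 400), "+")
#' extract_annotated_junctions(ann)  # donor_end 200, acceptor_start 300
#' @export
extract_annotated_junctions <- function(ann) {
  ann <- validate_annotation(ann)
  ann |>
    group_by(.data$gene_id, .data$transcript_id) |>
    filter(dplyr::n() > 1) |>
    dplyr::reframe(chrom = .data$chrom[-dplyr::n()],
                   donor_end = .data$end[-dplyr::n()],
                   acceptor_start = .data$start[-1],
                   strand = .data$strand[-dplyr::n()]) |>
    select("chrom", "donor_end", "acceptor_start", "strand") |>
    distinct()
}

#' Per-transcript junction sets
#'
#' Like [extract_annotated_junctions()] but keeping `gene_id` and
#' `transcript_id`, without de-duplication across transcripts.
#' @param ann Annotation tibble.
#' @return Tibble: `gene_id`, `transcript_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `strand`.
#' @export
transcript_junctions <- function(ann) {
  ann <- validate_annotation(ann)
  ann |>
    group_by(.data$gene_id, .data$transcript_id) |>
    filter(dplyr::n() > 1) |>
    dplyr::reframe(chrom = .data$chrom[-dplyr::n()],
                   donor_end = .data$end[-dplyr::n()],
                   acceptor_start = .data$start[-1],
                   strand = .data$strand[-dplyr::n()])
}
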