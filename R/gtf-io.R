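#' Read an Ensembl-dialect GTF into an annotation tibble
#'
#' Exon records are grouped into transcripts and genes. GTF 1-based inclusive
#' coordinates are converted to the package's internal 0-based half-open
#' convention at this boundary. Novel transcripts written by
#' [write_gtf()]/[augment_annotation()] are recognized by the attribute
#' `tag "novel"` (plus `parent_id`).
#'
#' @param path Path to a GTF file.
#' @param biotype Optional character vector; when given, only records whose
#'   `gene_biotype` (or `gene_type`) attribute is in this set are kept
#'   (e.g. `"protein_coding"`). Records without the attribute are kept.
#' @return An annotation tibble (see [annotation_tbl()]).
#' @examples
#' ann <- annotation_tbl("g1", "g1.t1", "chr1", 100, 200, "+")
#' f <- tempfile(fileext = ".gtf")
#' write_gtf(ann, f)
#' read_gtf(f)
#' @export
read_gtf <- function(path, biotype = NULL) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    lineno <- which(body)[which(nf != 9)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                  lineno, nf[which(nf != 9)[1]]))
  }
  feat <- vapply(strsplit(lines[body], "\t", fixed = TRUE), `[[`, "", 3)
  attrs <- vapply(strsplit(lines[body], "\t", fixed = TRUE), `[[`, "", 9)
  is_exon <- feat == "exon"
  miss <- is_exon & !(grepl("gene_id", attrs) & grepl("transcript_id", attrs))
  if (any(miss)) {
    lineno <- which(body)[which(miss)[1]]
    abort(sprintf("malformed GTF line %d: exon record lacks gene_id/transcript_id",
                  lineno))
  }
  if (!any(is_exon)) {
    return(annotation_tbl(character(), character(), character(),
                          numeric(), numeric(), character()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  md <- S4Vectors::mcols(gr)
  if (!is.null(biotype)) {
    bt_col <- intersect(c("gene_biotype", "gene_type"), names(md))[1]
    if (!is.na(bt_col)) {
      bt <- as.character(md[[bt_col]])
      gr <- gr[is.na(bt) | bt %in% biotype]
      md <- S4Vectors::mcols(gr)
    }
  }
  strand_chr <- as.character(BiocGenerics::strand(gr))
  if (any(strand_chr == "*"))
    abort("GTF exon records with strand '.' are not supported for transcripts")
  tag <- if ("tag" %in% names(md)) as.character(md$tag) else NA_character_
  parent <- if ("parent_id" %in% names(md)) as.character(md$parent_id) else NA_character_
  ann <- tibble(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(BiocGenerics::end(gr)),
    strand = strand_chr,
    is_novel = !is.na(tag) & tag == "novel",
    parent_id = parent)
  validate_annotation(ann)
}

#' Write an annotation tibble as GTF
#'
#' Emits one `exon` record per row, with `gene_id` and `transcript_id`
#' attributes; novel transcripts additionally carry `tag "novel"` and
#' `parent_id`, so that `read_gtf(write_gtf(x))` round-trips ids,
#' coordinates and novelty flags exactly.
#'
#' @param ann Annotation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ann <- validate_annotation(ann)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(ann) == 0) return(invisible(path))
  attr_str <- paste0("gene_id \"", ann$gene_id,
                     "\"; transcript_id \"", ann$transcript_id, "\";")
  novel <- ann$is_novel
  attr_str[novel] <- paste0(attr_str[novel],
                            " tag \"novel\"; parent_id \"",
                            ann$parent_id[novel], "\";")
  lines <- paste(ann$chrom, "spliceswitch", "exon",
                 format(ann$start + 1, scientific = FALSE, trim = TRUE),
                 format(ann$end, scientific = FALSE, trim = TRUE),
                 ".", ann$strand, ".", attr_str, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a TopHat-style junctions BED12 file
#'
#' Each record carries two blocks flanking one intron; the junction's
#' `donor_end`/`acceptor_start` (0-based half-open, i.e. the intron interval)
#' are computed from `chromStart`, the first block's size and the second
#' block's start. The BED `score` column is the junction read support.
#' Records whose `blockCount` is not 2 are skipped with a warning.
#'
#' @param path Path to a BED12 file (a leading `track` line is tolerated).
#' @param sample_id Sample identifier recorded in the output.
#' @return Junction tibble: `chrom`, `donor_end`, `acceptor_start`, `strand`,
#'   `read_support`, `sample_id`. Strand may be `"*"` (undetermined).
#' @export
read_junction_bed <- function(path, sample_id) {
  if (!file.exists(path)) abort(paste0("junction BED file not found: ", path))
  empty <- tibble(chrom = character(), donor_end = numeric(),
                  acceptor_start = numeric(), strand = character(),
                  read_support = numeric(), sample_id = character())
  lines <- readr::read_lines(path)
  if (!length(lines) || !any(nzchar(trimws(lines)))) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) return(empty)
  blocks <- gr$blocks
  if (is.null(blocks))
    abort("junction BED must be BED12 (blockCount/blockSizes/blockStarts)")
  nb <- lengths(blocks)
  if (any(nb != 2)) {
    warn(sprintf("skipping %d junction record(s) with blockCount != 2",
                 sum(nb != 2)))
    gr <- gr[nb == 2]
    blocks <- gr$blocks
  }
  if (!length(gr)) return(empty)
  chrom_start <- BiocGenerics::start(gr) - 1  # back to 0-based
  b_end1 <- vapply(blocks, function(b) IRanges::end(b)[1], 0)
  b_start2 <- vapply(blocks, function(b) IRanges::start(b)[2], 0)
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         donor_end = chrom_start + b_end1,
         acceptor_start = chrom_start + b_start2 - 1,
         strand = as.character(BiocGenerics::strand(gr)),
         read_support = as.numeric(gr$score),
         sample_id = sample_id)
}

#' Write junctions in TopHat BED12 dialect
#'
#' Inverse of [read_junction_bed()]: each junction becomes a two-block BED12
#' record with 50 bp flanks (clipped at the chromosome start) and the read
#' support in the score column.
#'
#' @param junctions Junction tibble with `chrom`, `donor_end`,
#'   `acceptor_start`, `strand`, `read_support`.
#' @param path Output path.
#' @param flank Flanking block size in bp.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path, flank = 50) {
  j <- as_tibble(junctions)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track name=junctions description=\"splice junctions\"", con)
  if (nrow(j) == 0) return(invisible(path))
  left <- pmin(flank, j$donor_end)
  chrom_start <- j$donor_end - left
  chrom_end <- j$acceptor_start + flank
  strand <- ifelse(j$strand %in% c("+", "-"), j$strand, ".")
  lines <- paste(j$chrom,
                 format(chrom_start, scientific = FALSE, trim = TRUE),
                 format(chrom_end, scientific = FALSE, trim = TRUE),
                 paste0("JUNC", seq_len(nrow(j))),
                 format(j$read_support, scientific = FALSE, trim = TRUE),
                 strand,
                 format(chrom_start, scientific = FALSE, trim = TRUE),
                 format(chrom_end, scientific = FALSE, trim = TRUE),
                 "255,0,0", "2",
                 paste0(format(left, scientific = FALSE, trim = TRUE), ",", flank),
                 paste0("0,", format(j$acceptor_start - chrom_start,
                                     scientific = FALSE, trim = TRUE)),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
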