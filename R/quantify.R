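#' Read a per-sample read-isoform compatibility table
#'
#' The TSV alternative to SAM input: one row per read equivalence class with
#' columns `gene_id`, `isoform_set` (comma-separated transcript ids) and
#' `read_count`. Lines starting with `#` are ignored.
#'
#' @param path TSV path.
#' @return Tibble with those three columns.
#' @export
read_compat_table <- function(path) {
  if (!file.exists(path)) abort(paste0("compatibility table not found: ", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", isoform_set = "c",
                                          read_count = "d"))
}

#' Read single-end alignments from a SAM/BAM file
#'
#' Keeps primary, mapped records; multi-mapped reads (NH tag > 1) are
#' skipped, mirroring a unique-alignment policy. Aligned blocks are derived
#' from the CIGAR (N gaps define spanned junctions) and returned 0-based
#' half-open.
#'
#' @param path SAM or BAM path.
#' @return Tibble: `read_id`, `chrom`, list-column `blocks` (2-column
#'   matrices of block start/end).
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    abort("SAM input needs the Rsamtools and GenomicAlignments packages")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = FALSE))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags, tag = "NH", what = "qname")
  gal <- GenomicAlignments::readGAlignments(bam, param = par, use.names = FALSE)
  nh <- S4Vectors::mcols(gal)$NH
  if (!is.null(nh)) gal <- gal[is.na(nh) | nh == 1]
  grl <- GenomicAlignments::grglist(gal)
  starts <- BiocGenerics::start(grl)
  ends <- BiocGenerics::end(grl)
  blocks <- lapply(seq_along(grl), function(i) {
    m <- cbind(start = starts[[i]] - 1, end = ends[[i]])
    m[order(m[, 1]), , drop = FALSE]
  })
  tibble(read_id = as.character(S4Vectors::mcols(gal)$qname),
         chrom = as.character(GenomicRanges::seqnames(gal)),
         blocks = blocks)
}

per_sample_classes <- function(path, ann) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    aln <- read_sam_alignments(path)
    spans <- ann |>
      group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], lo = min(.data$start),
                hi = max(.data$end), .groups = "drop")
    read_lo <- vapply(aln$blocks, function(b) b[1, 1], 0)
    read_hi <- vapply(aln$blocks, function(b) b[nrow(b), 2], 0)
    rows <- lapply(seq_len(nrow(spans)), function(g) {
      sel <- aln$chrom == spans$chrom[g] & read_lo < spans$hi[g] & read_hi > spans$lo[g]
      cm <- build_compatibility(aln[sel, , drop = FALSE],
                                ann[ann$gene_id == spans$gene_id[g], ])
      if (!nrow(cm$classes)) return(NULL)
      tibble(gene_id = cm$gene_id,
             isoform_set = vapply(cm$classes$iso_set, function(s)
               paste(cm$isoform_ids[s], collapse = ","), ""),
             read_count = cm$classes$count)
    })
    list(classes = bind_rows(rows), total_mapped = nrow(aln))
  } else {
    cls <- read_compat_table(path)
    list(classes = cls, total_mapped = sum(cls$read_count))
  }
}

#' Quantify isoform and gene abundances across samples
#'
#' Runs RAEM per gene per sample on read-isoform compatibility classes
#' (from SAM alignments or precomputed tables), then computes expected read
#' counts, RPKM (isoform length = summed exon lengths; gene length = union
#' exon length) and within-gene isoform proportions. The per-million
#' denominator is the sample's total uniquely aligned read count.
#'
#' @param ann Annotation tibble.
#' @param design Design tibble with `sample_id`, `condition` and `path`
#'   (per-sample SAM/BAM or compatibility TSV).
#' @param tol,max_iter EM settings passed to [raem_em()].
#' @return An `iso_quant` object: list with tibbles `isoforms` (per
#'   sample x isoform: `est_count`, `rpkm`, `proportion`), `genes` (per
#'   sample x gene: `count`, `rpkm`), `samples` (library sizes), and the
#'   `design`. Genes with zero reads in a sample get RPKM 0 and `NA`
#'   proportions.
#' @export
quantify_samples <- function(ann, design, tol = 1e-6, max_iter = 1000) {
  ann <- validate_annotation(ann)
  design <- check_design(design)
  if (!"path" %in% names(design))
    abort("design needs a 'path' column pointing at per-sample inputs")
  missing_in <- design$sample_id[!file.exists(design$path)]
  if (length(missing_in))
    abort(paste0("missing input file for sample(s): ",
                 paste(missing_in, collapse = ", ")))
  tx_len <- transcript_lengths(ann)
  g_len <- gene_union_lengths(ann)
  iso_index <- distinct(ann, .data$gene_id, .data$transcript_id) |>
    left_join(tx_len, by = c("gene_id", "transcript_id"))
  genes <- split(iso_index, iso_index$gene_id)

  iso_rows <- list(); gene_rows <- list(); samp_rows <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    inp <- per_sample_classes(design$path[s], ann)
    total_n <- inp$total_mapped
    cls_by_gene <- if (nrow(inp$classes))
      split(inp$classes, inp$classes$gene_id) else list()
    for (gid in names(genes)) {
      gi <- genes[[gid]]
      cls <- cls_by_gene[[gid]]
      if (is.null(cls)) {
        fit <- structure(list(proportions = setNames(rep(NA_real_, nrow(gi)),
                                                     gi$transcript_id),
                              est_counts = setNames(rep(0, nrow(gi)),
                                                    gi$transcript_id),
                              zero_reads = TRUE), class = "raem_fit")
        gcount <- 0
      } else {
        cm <- compat_matrix(gid, gi$transcript_id, cls$isoform_set, cls$read_count)
        fit <- raem_em(cm, gi$length, tol = tol, max_iter = max_iter)
        gcount <- cm$total_reads
        if (fit$zero_reads) fit$proportions[] <- NA_real_
      }
      iso_rows[[length(iso_rows) + 1L]] <- tibble(
        sample_id = sid, condition = design$condition[s], gene_id = gid,
        transcript_id = gi$transcript_id, length = gi$length,
        est_count = unname(fit$est_counts[gi$transcript_id]),
        proportion = unname(fit$proportions[gi$transcript_id]))
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        sample_id = sid, condition = design$condition[s], gene_id = gid,
        count = gcount)
    }
    samp_rows[[length(samp_rows) + 1L]] <- tibble(
      sample_id = sid, condition = design$condition[s], total_mapped = total_n)
  }
  samples <- bind_rows(samp_rows)
  isoforms <- bind_rows(iso_rows) |>
    left_join(select(samples, "sample_id", "total_mapped"), by = "sample_id") |>
    mutate(rpkm = 1e9 * .data$est_count / (.data$total_mapped * .data$length)) |>
    select(-"total_mapped")
  genes_tbl <- bind_rows(gene_rows) |>
    left_join(g_len, by = "gene_id") |>
    left_join(select(samples, "sample_id", "total_mapped"), by = "sample_id") |>
    mutate(rpkm = 1e9 * .data$count / (.data$total_mapped * .data$union_length)) |>
    select(-"total_mapped")
  structure(list(isoforms = isoforms, genes = genes_tbl,
                 samples = samples, design = design),
            class = "iso_quant")
}

#' Assemble an `iso_quant` from in-memory per-sample class tables
#'
#' Same computation as [quantify_samples()] but taking a single long tibble
#' of equivalence classes (`sample_id`, `gene_id`, `isoform_set`,
#' `read_count`) instead of files; used by the simulator and tests.
#'
#' @param ann Annotation tibble.
#' @param classes Long class tibble as above.
#' @param design Design tibble (`sample_id`, `condition`).
#' @param tol,max_iter EM settings.
#' @return An `iso_quant`.
#' @export
quantify_classes <- function(ann, classes, design, tol = 1e-6, max_iter = 1000) {
  design <- check_design(design)
  dir <- tempfile("quant_cls_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  design$path <- vapply(design$sample_id, function(sid) {
    p <- file.path(dir, paste0(sid, ".tsv"))
    readr::write_tsv(classes[classes$sample_id == sid,
                             c("gene_id", "isoform_set", "read_count")], p)
    p
  }, "")
  quantify_samples(ann, design, tol = tol, max_iter = max_iter)
}

#' @exportS3Method generics::tidy
tidy.iso_quant <- function(x, level = c("isoform", "gene"), ...) {
  level <- match.arg(level)
  if (level == "isoform") x$isoforms else x$genes
}

#' @exportS3Method generics::glance
glance.iso_quant <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_genes = dplyr::n_distinct(x$genes$gene_id),
         n_isoforms = dplyr::n_distinct(x$isoforms$transcript_id),
         total_reads = sum(x$samples$total_mapped))
}

#' @export
print.iso_quant <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Isoform quantification: %d genes / %d isoforms x %d samples (%s reads)\n",
              g$n_genes, g$n_isoforms, g$n_samples,
              format(g$total_reads, big.mark = ",")))
  invisible(x)
}

# condition means of RPKM (or any value column) per entity
condition_means <- function(tbl, value_col, id_cols) {
  tbl |>
    group_by(across(all_of(c(id_cols, "condition")))) |>
    summarise(m = mean(.data[[value_col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
}
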