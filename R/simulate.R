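#' Configuration for the synthetic splicing study generator
#'
#' The generator emulates a two-condition bulk RNA-seq study with three
#' replicates per condition and short single-end reads: genes with 1-5
#' isoforms built by skipping internal exons of a shared exon chain,
#' replicate-level isoform proportions drawn from a Dirichlet around each
#' condition's base proportions, planted major-minor switches that exchange
#' probability mass between the top two isoforms, log-normal gene expression
#' with planted fold changes, Poisson read counts, multinomial isoform
#' assignment with a tunable ambiguous-read fraction, and junction read
#' evidence including case-only novel junctions.
#'
#' @param seed Integer RNG seed (mandatory; recorded in every output file).
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer range `c(min, max)`.
#' @param exons_per_transcript Integer range for the gene's full exon chain
#'   (min 3 so internal exons exist).
#' @param exon_length,intron_length Ranges in bp.
#' @param n_replicates Replicates per condition.
#' @param switch_fraction Fraction of multi-isoform genes with a planted
#'   major-minor switch.
#' @param switch_magnitude Proportion points (0-100) moved between the top
#'   two isoforms from control to case.
#' @param replicate_noise Dirichlet concentration for replicate-level
#'   proportions around the condition base (larger = less noise; 800 keeps
#'   the replicate SD of a 50% isoform under ~1.8 points).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the per-gene
#'   expression level (RPKM-like units).
#' @param library_size Nominal per-sample library size used to scale
#'   expected read counts.
#' @param planted_de_fraction Fraction of genes with a planted expression
#'   fold change.
#' @param de_fold_change Range of planted fold changes (randomly inverted
#'   for down-regulation).
#' @param novel_junction_fraction Fraction of genes receiving a planted
#'   case-only novel junction.
#' @param novel_junction_support Mean read support of a planted novel
#'   junction per case sample.
#' @param junction_span_prob Probability that an isoform-assigned read
#'   supports any given junction of that isoform.
#' @param ambiguous_read_fraction Probability that a read is emitted as
#'   compatible with all of its gene's isoforms rather than unique.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 100,
                       isoforms_per_gene = c(1, 5),
                       exons_per_transcript = c(4, 8),
                       exon_length = c(150, 300),
                       intron_length = c(200, 1000),
                       n_replicates = 3,
                       switch_fraction = 0.1,
                       switch_magnitude = 50,
                       replicate_noise = 800,
                       expr_meanlog = log(50),
                       expr_sdlog = 1,
                       library_size = 2e6,
                       planted_de_fraction = 0.1,
                       de_fold_change = c(1.5, 3),
                       novel_junction_fraction = 0.05,
                       novel_junction_support = 15,
                       junction_span_prob = 0.05,
                       ambiguous_read_fraction = 0.2) {
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  stopifnot(seed == as.integer(seed), seed < 2^31 - 10,
            n_genes >= 1, isoforms_per_gene[1] >= 1,
            exons_per_transcript[1] >= 3,
            switch_fraction >= 0, switch_fraction <= 1,
            switch_magnitude >= 0, switch_magnitude <= 100,
            replicate_noise > 0, n_replicates >= 1,
            planted_de_fraction >= 0, planted_de_fraction <= 1,
            novel_junction_fraction >= 0, novel_junction_fraction <= 1,
            ambiguous_read_fraction >= 0, ambiguous_read_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# uniform integer draws safe against sample()'s scalar expansion
rint <- function(lo, hi, n = 1) {
  if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

# permutation / subset safe for length-1 vectors
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Simulate a transcript annotation
#'
#' Genes occupy non-overlapping loci on one chromosome. Each gene has a full
#' exon chain; additional isoforms skip one or two internal exons with
#' distinct skip patterns, so isoforms share exons and reads can be
#' ambiguous. Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return An annotation tibble.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  cursor <- 1000
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("SIMG%04d", g)
    E <- rint(cfg$exons_per_transcript[1], cfg$exons_per_transcript[2])
    ex_len <- rint(cfg$exon_length[1], cfg$exon_length[2], E)
    in_len <- rint(cfg$intron_length[1], cfg$intron_length[2], max(E - 1, 1))
    starts <- cursor + cumsum(c(0, head(ex_len, -1) + in_len))
    ends <- starts + ex_len
    cursor <- ends[E] + 10000
    K_want <- rint(cfg$isoforms_per_gene[1], cfg$isoforms_per_gene[2])
    internal <- seq(2, E - 1)
    # distinct skip patterns of 1-2 internal exons
    pats <- list(integer(0))
    cand <- c(lapply(internal, identity),
              if (length(internal) >= 2)
                unlist(lapply(seq_along(internal)[-length(internal)], function(i)
                  lapply(seq(i + 1, length(internal)), function(j)
                    internal[c(i, j)])), recursive = FALSE))
    if (K_want > 1 && length(cand)) {
      take <- resample(seq_along(cand), min(K_want - 1, length(cand)))
      pats <- c(pats, cand[take])
    }
    strand <- sample(c("+", "-"), 1)
    for (k in seq_along(pats)) {
      keep <- setdiff(seq_len(E), pats[[k]])
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = gid, transcript_id = sprintf("%s.t%d", gid, k),
        chrom = "chrS1", start = starts[keep], end = ends[keep],
        strand = strand, is_novel = FALSE, parent_id = NA_character_)
    }
  }
  validate_annotation(bind_rows(rows))
}

#' Simulate condition and replicate-level expression and proportions
#'
#' Condition base proportions are symmetric-Dirichlet; switch genes exchange
#' `switch_magnitude` proportion points between their top two isoforms from
#' control to case. Replicate proportions are Dirichlet centered on the
#' condition base with concentration `replicate_noise`. Gene expression is
#' log-normal, with planted fold changes for DE genes.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return List: `truth` (per gene: `switch`, `fold_change`, `expr_control`,
#'   base proportions as list-columns), `proportions` (per gene x isoform x
#'   sample replicate-level proportions), `design`.
#' @export
simulate_expression <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  design <- tibble(
    sample_id = c(paste0("ctrl", seq_len(cfg$n_replicates)),
                  paste0("case", seq_len(cfg$n_replicates))),
    condition = rep(c("control", "case"), each = cfg$n_replicates))
  iso <- distinct(ann, .data$gene_id, .data$transcript_id)
  genes <- split(iso$transcript_id, iso$gene_id)
  gids <- names(genes)
  multi <- gids[lengths(genes) >= 2]
  n_switch <- round(cfg$switch_fraction * length(multi))
  switch_genes <- if (n_switch > 0) resample(multi, n_switch) else character()
  n_de <- round(cfg$planted_de_fraction * length(gids))
  de_genes <- if (n_de > 0) resample(gids, n_de) else character()

  truth_rows <- list(); prop_rows <- list()
  for (gid in gids) {
    iso_ids <- genes[[gid]]
    K <- length(iso_ids)
    base_c <- sort(rdirichlet1(rep(1, K)), decreasing = TRUE)
    base_a <- base_c
    is_switch <- gid %in% switch_genes
    if (is_switch && K >= 2) {
      moved <- min(cfg$switch_magnitude / 100, base_c[1] - 0.02)
      base_a[1] <- base_c[1] - moved
      base_a[2] <- base_c[2] + moved
    }
    expr_c <- rlnorm(1, cfg$expr_meanlog, cfg$expr_sdlog)
    fc <- 1
    if (gid %in% de_genes) {
      fc <- runif(1, cfg$de_fold_change[1], cfg$de_fold_change[2])
      if (runif(1) < 0.5) fc <- 1 / fc
    }
    for (s in seq_len(nrow(design))) {
      base <- if (design$condition[s] == "control") base_c else base_a
      p <- if (K == 1) 1 else rdirichlet1(cfg$replicate_noise * base)
      prop_rows[[length(prop_rows) + 1L]] <- tibble(
        gene_id = gid, transcript_id = iso_ids,
        sample_id = design$sample_id[s], condition = design$condition[s],
        proportion = p)
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      gene_id = gid, n_isoforms = K, switch = is_switch && K >= 2,
      de = gid %in% de_genes, fold_change = fc, expr_control = expr_c,
      base_control = list(setNames(base_c, iso_ids)),
      base_case = list(setNames(base_a, iso_ids)))
  }
  list(truth = bind_rows(truth_rows), proportions = bind_rows(prop_rows),
       design = design)
}

#' Simulate read-class counts and junction evidence
#'
#' Per sample and gene the read count is Poisson with mean
#' `expression x fold-change (case) x union-length/1e3 x library_size/1e6`;
#' reads are assigned to isoforms multinomially by the replicate proportions
#' and emitted unique to their isoform with probability
#' `1 - ambiguous_read_fraction` (else compatible with all the gene's
#' isoforms). Junction support is binomial per isoform-assigned read;
#' planted novel junctions (a skip of one internal exon of the full isoform
#' not present in any annotated isoform) appear only in case samples.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation tibble.
#' @param expr Output of [simulate_expression()].
#' @return List: `classes` (sample_id, gene_id, isoform_set, read_count),
#'   `junctions` (observed junction tibble across samples), `novel_truth`
#'   (planted novel junctions with gene, parents and coordinates).
#' @export
simulate_counts_and_reads <- function(cfg, ann, expr) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  design <- expr$design
  g_len <- gene_union_lengths(ann)
  tx_junc <- transcript_junctions(ann)
  ann_junc <- extract_annotated_junctions(ann)
  ann_key <- paste(ann_junc$chrom, ann_junc$donor_end, ann_junc$acceptor_start,
                   sep = ":")

  # plant novel junctions on eligible genes (case-only evidence)
  gids <- unique(expr$truth$gene_id)
  n_novel <- round(cfg$novel_junction_fraction * length(gids))
  novel_rows <- list()
  if (n_novel > 0) {
    for (gid in resample(gids, n_novel)) {
      full_tx <- ann[ann$transcript_id == paste0(gid, ".t1"), ]
      E <- nrow(full_tx)
      if (E < 3) next
      cand_i <- resample(seq(2, E - 1))
      for (i in cand_i) {
        de_ <- full_tx$end[i - 1]; as_ <- full_tx$start[i + 1]
        key <- paste(full_tx$chrom[1], de_, as_, sep = ":")
        if (!(key %in% ann_key)) {
          parents <- ann |>
            group_by(.data$transcript_id) |>
            summarise(ok = .data$gene_id[1] == gid &&
                        any(.data$end == de_) && any(.data$start == as_) &&
                        any(.data$start >= de_ & .data$end <= as_),
                      .groups = "drop") |>
            filter(.data$ok) |> pull("transcript_id")
          novel_rows[[length(novel_rows) + 1L]] <- tibble(
            gene_id = gid, chrom = full_tx$chrom[1],
            donor_end = de_, acceptor_start = as_,
            strand = full_tx$strand[1],
            parents = paste(parents, collapse = ","))
          break
        }
      }
    }
  }
  novel_truth <- if (length(novel_rows)) bind_rows(novel_rows) else
    tibble(gene_id = character(), chrom = character(), donor_end = numeric(),
           acceptor_start = numeric(), strand = character(), parents = character())

  cls_rows <- list(); junc_rows <- list()
  truth <- expr$truth
  props <- expr$proportions
  for (s in seq_len(nrow(design))) {
    sid <- design$sample_id[s]
    is_case <- design$condition[s] == "case"
    pr_s <- props[props$sample_id == sid, ]
    pr_by_gene <- split(pr_s, pr_s$gene_id)
    for (g in seq_len(nrow(truth))) {
      gid <- truth$gene_id[g]
      L <- g_len$union_length[g_len$gene_id == gid]
      mu <- truth$expr_control[g] * (if (is_case) truth$fold_change[g] else 1) *
        (L / 1e3) * (cfg$library_size / 1e6)
      n_reads <- rpois(1, mu)
      if (n_reads == 0) next
      pr <- pr_by_gene[[gid]]
      iso_ids <- pr$transcript_id
      K <- length(iso_ids)
      iso_counts <- as.vector(rmultinom(1, n_reads, pr$proportion))
      amb <- if (K > 1 && cfg$ambiguous_read_fraction > 0)
        rbinom(K, iso_counts, cfg$ambiguous_read_fraction) else rep(0L, K)
      uniq <- iso_counts - amb
      sets <- character(); cnts <- numeric()
      if (any(uniq > 0)) {
        sets <- c(sets, iso_ids[uniq > 0]); cnts <- c(cnts, uniq[uniq > 0])
      }
      if (sum(amb) > 0) {
        sets <- c(sets, paste(iso_ids, collapse = ","))
        cnts <- c(cnts, sum(amb))
      }
      cls_rows[[length(cls_rows) + 1L]] <- tibble(
        sample_id = sid, gene_id = gid, isoform_set = sets, read_count = cnts)
      # junction evidence from isoform-assigned reads
      tj <- tx_junc[tx_junc$gene_id == gid, ]
      if (nrow(tj)) {
        for (k in seq_len(K)) {
          if (iso_counts[k] == 0) next
          jk <- tj[tj$transcript_id == iso_ids[k], ]
          if (!nrow(jk)) next
          sup <- rbinom(nrow(jk), iso_counts[k], cfg$junction_span_prob)
          keep <- sup > 0
          if (any(keep))
            junc_rows[[length(junc_rows) + 1L]] <- tibble(
              chrom = jk$chrom[keep], donor_end = jk$donor_end[keep],
              acceptor_start = jk$acceptor_start[keep],
              strand = jk$strand[keep], read_support = sup[keep],
              sample_id = sid)
        }
      }
      if (is_case && gid %in% novel_truth$gene_id) {
        nv <- novel_truth[novel_truth$gene_id == gid, ]
        sup <- 2 + rpois(nrow(nv), cfg$novel_junction_support)
        junc_rows[[length(junc_rows) + 1L]] <- tibble(
          chrom = nv$chrom, donor_end = nv$donor_end,
          acceptor_start = nv$acceptor_start, strand = nv$strand,
          read_support = sup, sample_id = sid)
      }
    }
  }
  junctions <- if (length(junc_rows)) {
    bind_rows(junc_rows) |>
      group_by(.data$chrom, .data$donor_end, .data$acceptor_start,
               .data$strand, .data$sample_id) |>
      summarise(read_support = sum(.data$read_support), .groups = "drop") |>
      select("chrom", "donor_end", "acceptor_start", "strand",
             "read_support", "sample_id")
  } else {
    tibble(chrom = character(), donor_end = numeric(),
           acceptor_start = numeric(), strand = character(),
           read_support = numeric(), sample_id = character())
  }
  list(classes = bind_rows(cls_rows), junctions = junctions,
       novel_truth = novel_truth)
}

#' Generate a complete synthetic splicing study
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_counts_and_reads()]; optionally writes the study to disk (GTF
#' annotation, per-sample compatibility TSVs and junction BED12 files,
#' design TSV, truth TSV), every file carrying the seed in a header comment.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `annotation`, `design` (with `path`/`junction_path`
#'   columns when written), `truth`, `proportions`, `classes`, `junctions`,
#'   `novel_truth`, and `paths`.
#' @export
simulate_splicing_study <- function(cfg, dir = NULL) {
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  reads <- simulate_counts_and_reads(cfg, ann, expr)
  design <- expr$design
  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    seed_line <- paste0("# seed: ", cfg$seed)
    gtf <- file.path(dir, "annotation.gtf")
    write_gtf(ann, gtf)
    txt <- readr::read_lines(gtf)
    readr::write_lines(c(seed_line, txt), gtf)
    design$path <- vapply(design$sample_id, function(sid) {
      p <- file.path(dir, paste0(sid, ".compat.tsv"))
      readr::write_lines(seed_line, p)
      readr::write_tsv(reads$classes[reads$classes$sample_id == sid,
                                     c("gene_id", "isoform_set", "read_count")],
                       p, append = TRUE, col_names = TRUE)
      p
    }, "")
    design$junction_path <- vapply(design$sample_id, function(sid) {
      p <- file.path(dir, paste0(sid, ".junctions.bed"))
      write_junction_bed(reads$junctions[reads$junctions$sample_id == sid, ], p)
      p
    }, "")
    dpath <- file.path(dir, "design.tsv")
    readr::write_lines(seed_line, dpath)
    readr::write_tsv(design, dpath, append = TRUE, col_names = TRUE)
    tpath <- file.path(dir, "truth.tsv")
    readr::write_lines(seed_line, tpath)
    readr::write_tsv(select(expr$truth, -"base_control", -"base_case"),
                     tpath, append = TRUE, col_names = TRUE)
    paths <- list(annotation = gtf, design = dpath, truth = tpath)
  }
  list(annotation = ann, design = design, truth = expr$truth,
       proportions = expr$proportions, classes = reads$classes,
       junctions = reads$junctions, novel_truth = reads$novel_truth,
       paths = paths)
}
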