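# Shared fixtures and independent oracles, built in code at test time.

# two genes / three transcripts; g1 has a skipped middle exon in t2
toy_annotation <- function() {
  dplyr::bind_rows(
    annotation_tbl("g1", "g1.t1", "chr1",
                   c(100, 300, 500), c(200, 400, 600), "+"),
    annotation_tbl("g1", "g1.t2", "chr1",
                   c(100, 500), c(200, 600), "+"),
    annotation_tbl("g2", "g2.t1", "chr2",
                   c(1000, 1500), c(1200, 1800), "-"))
}

toy_design <- function(n_rep = 3) {
  tibble::tibble(
    sample_id = c(paste0("ctrl", seq_len(n_rep)), paste0("case", seq_len(n_rep))),
    condition = rep(c("control", "case"), each = n_rep))
}

# iso_quant built from unique-read classes so proportions/RPKM are exact:
# counts is a list by sample_id of tibbles (gene_id, isoform_set, read_count)
quant_from_classes <- function(ann, counts, design) {
  cls <- dplyr::bind_rows(lapply(names(counts), function(sid)
    dplyr::mutate(counts[[sid]], sample_id = sid)))
  quantify_classes(ann, cls, design)
}

# per-isoform unique counts for one 2-isoform gene across 6 samples,
# chosen so sample proportions equal `props` exactly at `depth` reads
two_iso_classes <- function(gene, isoforms, props_control, props_case,
                            design, depth = 1000) {
  stopifnot(length(isoforms) == 2)
  props <- c(props_control, props_case)
  dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i) {
    p <- props[i]
    tibble::tibble(sample_id = design$sample_id[i], gene_id = gene,
                   isoform_set = isoforms,
                   read_count = c(round(depth * p), depth - round(depth * p)))
  }))
}

# independent BH step-up oracle (hand-coded; implementation uses p.adjust)
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force Pearson/Yates contingency statistic, coded independently
chisq_oracle <- function(O, yates) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  d <- abs(O - E)
  if (yates) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# observed-data log-likelihood of a 2-isoform mixture for the grid oracle
ll_2iso <- function(p, n1, n2, n12, l1, l2) {
  n1 * log(p / l1) + n2 * log((1 - p) / l2) +
    (if (n12 > 0) n12 * log(p / l1 + (1 - p) / l2) else 0)
}
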