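#' Build a read-isoform compatibility matrix for one gene
#'
#' A read is compatible with an isoform iff every aligned block lies within
#' the isoform's exon union and every junction the read spans (the gap
#' between consecutive blocks) is a junction of that isoform. Reads
#' compatible with no isoform of the gene are dropped and counted; reads on
#' another chromosome are excluded silently.
#'
#' @param alignments Tibble of single-end, uniquely mapped reads with columns
#'   `read_id`, `chrom` and a list-column `blocks`, each element a 2-column
#'   numeric matrix of sorted 0-based half-open `(start, end)` aligned blocks.
#' @param gene_ann Annotation tibble restricted to one gene.
#' @return A `compat_matrix` object: list with `gene_id`, `isoform_ids`,
#'   `classes` (tibble with list-column `iso_set` of isoform index vectors
#'   and `count`), `total_reads`, and `n_dropped`.
#' @export
build_compatibility <- function(alignments, gene_ann) {
  gene_ann <- validate_annotation(gene_ann)
  gene_id <- unique(gene_ann$gene_id)
  if (length(gene_id) != 1) abort("gene_ann must contain exactly one gene")
  iso_ids <- unique(gene_ann$transcript_id)
  chrom <- gene_ann$chrom[1]
  exon_sets <- lapply(iso_ids, function(tx) {
    ex <- gene_ann[gene_ann$transcript_id == tx, c("start", "end")]
    as.matrix(ex[order(ex$start), ])
  })
  junc_sets <- lapply(exon_sets, function(ex) {
    if (nrow(ex) < 2) return(character())
    paste(ex[-nrow(ex), "end"], ex[-1, "start"], sep = "-")
  })

  aln <- as_tibble(alignments)
  aln <- aln[aln$chrom == chrom, , drop = FALSE]
  n_dropped <- 0L
  keys <- character(nrow(aln))
  sets <- vector("list", nrow(aln))
  for (r in seq_len(nrow(aln))) {
    bl <- aln$blocks[[r]]
    gaps <- if (nrow(bl) > 1) paste(bl[-nrow(bl), 2], bl[-1, 1], sep = "-") else character()
    ok <- vapply(seq_along(iso_ids), function(i) {
      ex <- exon_sets[[i]]
      inside <- all(vapply(seq_len(nrow(bl)), function(b) {
        covered_by_union(bl[b, 1], bl[b, 2], ex)
      }, logical(1)))
      inside && all(gaps %in% junc_sets[[i]])
    }, logical(1))
    if (!any(ok)) { n_dropped <- n_dropped + 1L; keys[r] <- NA } else {
      sets[[r]] <- which(ok)
      keys[r] <- paste(which(ok), collapse = ",")
    }
  }
  keep <- !is.na(keys)
  tab <- table(keys[keep])
  classes <- tibble(
    iso_set = lapply(names(tab), function(k) as.integer(strsplit(k, ",")[[1]])),
    count = as.numeric(tab))
  structure(list(gene_id = gene_id, isoform_ids = iso_ids,
                 classes = classes, total_reads = sum(classes$count),
                 n_dropped = n_dropped),
            class = "compat_matrix")
}

# is [s, e) fully covered by the union of exon intervals (0-based half-open)?
covered_by_union <- function(s, e, exons) {
  ov <- exons[exons[, 2] > s & exons[, 1] < e, , drop = FALSE]
  if (!nrow(ov)) return(FALSE)
  ov <- ov[order(ov[, 1]), , drop = FALSE]
  if (ov[1, 1] > s) return(FALSE)
  reach <- ov[1, 2]
  for (i in seq_len(nrow(ov))[-1]) {
    if (ov[i, 1] > reach) return(FALSE)
    reach <- max(reach, ov[i, 2])
  }
  reach >= e
}

#' Assemble a compatibility matrix from pre-tabulated classes
#'
#' Convenience constructor used by the simulator and the compatibility-table
#' input path: equivalence classes arrive as comma-separated isoform id sets
#' with read multiplicities.
#'
#' @param gene_id Gene identifier.
#' @param isoform_ids Ordered character vector of the gene's isoform ids.
#' @param iso_sets Character vector, each a comma-separated subset of
#'   `isoform_ids`.
#' @param counts Numeric read multiplicities (>= 1).
#' @return A `compat_matrix`.
#' @export
compat_matrix <- function(gene_id, isoform_ids, iso_sets, counts) {
  stopifnot(length(iso_sets) == length(counts), all(counts >= 1))
  classes <- tibble(
    iso_set = lapply(iso_sets, function(s) {
      idx <- match(strsplit(s, ",")[[1]], isoform_ids)
      if (anyNA(idx)) abort(paste0("unknown isoform in set: ", s))
      sort(unique(idx))
    }),
    count = as.numeric(counts))
  structure(list(gene_id = gene_id, isoform_ids = isoform_ids,
                 classes = classes, total_reads = sum(classes$count),
                 n_dropped = 0L),
            class = "compat_matrix")
}

#' RAEM: EM estimation of isoform proportions from ambiguous read classes
#'
#' Reads-Assign-by-Expectation-Maximization. The E-step assigns each read
#' fractionally to its compatible isoforms with weight proportional to
#' `proportion / effective length`; the M-step sets each proportion
#' proportional to the summed fractional assignments. Iterates from a uniform
#' start until the maximum absolute proportion change drops below `tol` or
#' `max_iter` is reached. Effective length is the transcript length (no
#' fragment-length correction; the target regime is short single-end reads).
#'
#' @param compat A `compat_matrix`.
#' @param lengths Positive numeric effective lengths, one per isoform (same
#'   order as `compat$isoform_ids`).
#' @param tol Convergence threshold on the max absolute proportion change.
#' @param max_iter Iteration cap.
#' @return A `raem_fit`: list with `proportions`, `est_counts` (both named by
#'   isoform, counts summing to the total gene reads), `n_iter`, `converged`,
#'   `loglik` (per-iteration observed-data log-likelihood trace), and
#'   `zero_reads` flag (uniform proportions, zero counts).
#' @examples
#' cm <- compat_matrix("g", c("A", "B"), c("A", "B"), c(30, 10))
#' raem_em(cm, lengths = c(1000, 1000))$proportions
#' @export
raem_em <- function(compat, lengths, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(compat, "compat_matrix"))
  K <- length(compat$isoform_ids)
  if (length(lengths) != K) abort("need one length per isoform")
  if (any(lengths <= 0)) abort("isoform effective lengths must be positive")
  iso_ids <- compat$isoform_ids
  if (compat$total_reads == 0) {
    return(structure(list(
      proportions = setNames(rep(1 / K, K), iso_ids),
      est_counts = setNames(rep(0, K), iso_ids),
      n_iter = 0L, converged = TRUE, loglik = numeric(),
      zero_reads = TRUE, gene_id = compat$gene_id), class = "raem_fit"))
  }
  sets <- compat$classes$iso_set
  cnt <- compat$classes$count
  p <- rep(1 / K, K)
  ll <- numeric(0)
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    w <- p / lengths
    frac <- numeric(K)
    ll_i <- 0
    for (c in seq_along(sets)) {
      s <- sets[[c]]
      denom <- sum(w[s])
      frac[s] <- frac[s] + cnt[c] * w[s] / denom
      ll_i <- ll_i + cnt[c] * log(denom)
    }
    ll <- c(ll, ll_i)
    p_new <- frac / sum(frac)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  # final fractional assignment under the converged proportions
  w <- p / lengths
  counts <- numeric(K)
  for (c in seq_along(sets)) {
    s <- sets[[c]]
    counts[s] <- counts[s] + cnt[c] * w[s] / sum(w[s])
  }
  structure(list(
    proportions = setNames(p, iso_ids),
    est_counts = setNames(counts, iso_ids),
    n_iter = n_iter, converged = converged, loglik = ll,
    zero_reads = FALSE, gene_id = compat$gene_id), class = "raem_fit")
}

#' @exportS3Method generics::tidy
tidy.raem_fit <- function(x, ...) {
  tibble(transcript_id = names(x$proportions),
         proportion = unname(x$proportions),
         est_count = unname(x$est_counts))
}

#' @exportS3Method generics::glance
glance.raem_fit <- function(x, ...) {
  tibble(n_iter = x$n_iter, converged = x$converged,
         loglik = if (length(x$loglik)) tail(x$loglik, 1) else NA_real_,
         zero_reads = x$zero_reads)
}

#' @export
print.raem_fit <- function(x, ...) {
  cat("RAEM fit for gene", x$gene_id, "-", length(x$proportions), "isoforms,",
      x$n_iter, "iterations", if (x$converged) "(converged)" else "(not converged)", "\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Reads per kilobase of exon/transcript model per million mapped reads
#'
#' `rpkm = 1e9 * C / (N * L)` for `C` reads on a feature of length `L` bp in
#' a library of `N` mapped reads.
#'
#' @param count Read count(s) `C` (>= 0).
#' @param feature_length Feature length(s) `L` in bp (> 0).
#' @param total_mapped Library size `N` in reads (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(count, feature_length, total_mapped) {
  if (any(feature_length <= 0)) abort("feature_length must be positive")
  if (any(total_mapped <= 0)) abort("total_mapped must be positive")
  if (any(count < 0)) abort("count must be non-negative")
  1e9 * count / (total_mapped * feature_length)
}
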