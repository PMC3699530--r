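g1_ann <- function() toy_annotation() |> dplyr::filter(gene_id == "g1")

test_that("read compatibility follows exon-union and junction rules", {
  ann <- g1_ann()  # t1: exons (100,200),(300,400),(500,600); t2 skips the middle
  aln <- tibble::tibble(
    read_id = c("shared", "skip", "intronic", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    blocks = list(
      cbind(120, 160),                     # inside exon 1: both isoforms
      cbind(c(180, 500), c(200, 520)),     # spans skip junction 200-500: t2 only
      cbind(250, 280),                     # inside the intron: neither
      cbind(120, 160)))                    # wrong chromosome: silently excluded
  cm <- build_compatibility(aln, ann)
  expect_equal(cm$total_reads, 2)
  expect_equal(cm$n_dropped, 1)
  sets <- lapply(cm$classes$iso_set, function(s) sort(cm$isoform_ids[s]))
  expect_true(any(vapply(sets, identical, TRUE, c("g1.t1", "g1.t2"))))
  expect_true(any(vapply(sets, identical, TRUE, "g1.t2")))
  # a junction-spanning read also matches the isoform carrying that junction
  aln2 <- tibble::tibble(read_id = "j12", chrom = "chr1",
                         blocks = list(cbind(c(180, 300), c(200, 320))))
  cm2 <- build_compatibility(aln2, ann)
  expect_equal(cm2$isoform_ids[cm2$classes$iso_set[[1]]], "g1.t1")
})

test_that("EM fixed points match hand-derived solutions", {
  # single isoform
  cm1 <- compat_matrix("g", "A", "A", 17)
  expect_equal(unname(raem_em(cm1, 500)$proportions), 1)
  # all reads unique: proportions are the count fractions
  cm2 <- compat_matrix("g", c("A", "B"), c("A", "B"), c(30, 10))
  fit2 <- raem_em(cm2, c(1000, 1000))
  expect_equal(unname(fit2$proportions), c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(unname(fit2$est_counts), c(30, 10), tolerance = 1e-6)
  # full ambiguity with equal lengths: symmetric fixed point
  cm3 <- compat_matrix("g", c("A", "B"), "A,B", 40)
  expect_equal(unname(raem_em(cm3, c(800, 800))$proportions), c(0.5, 0.5))
})

test_that("EM handles degenerate inputs as specified", {
  cm0 <- structure(list(gene_id = "g", isoform_ids = c("A", "B"),
                        classes = tibble::tibble(iso_set = list(), count = numeric()),
                        total_reads = 0, n_dropped = 0L), class = "compat_matrix")
  fit <- raem_em(cm0, c(100, 100))
  expect_true(fit$zero_reads)
  expect_equal(unname(fit$proportions), c(0.5, 0.5))
  expect_equal(unname(fit$est_counts), c(0, 0))
  expect_error(raem_em(compat_matrix("g", "A", "A", 1), 0), "positive")
})

test_that("EM log-likelihood never decreases and counts are conserved", {
  set.seed(71)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    ids <- LETTERS[1:K]
    n_class <- sample(2:6, 1)
    sets <- vapply(seq_len(n_class), function(i)
      paste(sort(sample(ids, sample(1:K, 1))), collapse = ","), "")
    cnt <- sample(1:200, n_class, replace = TRUE)
    cm <- compat_matrix("g", ids, sets, cnt)
    fit <- raem_em(cm, sample(500:2000, K))
    expect_true(all(diff(fit$loglik) >= -1e-9))
    expect_equal(sum(fit$est_counts), cm$total_reads, tolerance = 1e-6)
  }
})

test_that("EM matches a grid search of the 2-isoform likelihood", {
  set.seed(72)
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  for (rep in 1:10) {
    n1 <- sample(5:300, 1); n2 <- sample(5:300, 1); n12 <- sample(0:300, 1)
    l1 <- sample(500:2000, 1); l2 <- sample(500:2000, 1)
    cm <- compat_matrix("g", c("A", "B"),
                        c("A", "B", "A,B"), pmax(c(n1, n2, n12), 1))
    if (n12 == 0) cm <- compat_matrix("g", c("A", "B"), c("A", "B"), c(n1, n2))
    fit <- raem_em(cm, c(l1, l2), tol = 1e-10)
    best <- grid[which.max(ll_2iso(grid, n1, n2, if (n12 == 0) 0 else n12, l1, l2))]
    expect_lt(abs(unname(fit$proportions[1]) - best), 1e-3)
  }
})

test_that("EM recovers proportions within 0.02 from 10,000 reads", {
  set.seed(73)
  truth <- c(0.5, 0.3, 0.2)
  ids <- c("A", "B", "C")
  iso_of_read <- sample(ids, 10000, replace = TRUE, prob = truth)
  unique_read <- runif(10000) < 0.8  # >= 20% uniquely assignable per isoform
  key <- ifelse(unique_read, iso_of_read, "A,B,C")
  tab <- table(key)
  cm <- compat_matrix("g", ids, names(tab), as.numeric(tab))
  fit <- raem_em(cm, c(1000, 1000, 1000))
  expect_lt(max(abs(fit$proportions[ids] - truth)), 0.02)
})

test_that("rpkm implements 1e9 C / (N L) with guards", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(50, 2000, 1e6), rpkm(50, 2000, 2e6) * 2)
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 100, 0), "positive")
  expect_error(rpkm(-1, 100, 10), "non-negative")
})

test_that("quantify_samples populates counts, RPKM and proportions per sample", {
  ann <- g1_ann()
  design <- toy_design(1)  # one replicate per condition suffices here
  cls <- dplyr::bind_rows(
    tibble::tibble(sample_id = "ctrl1", gene_id = "g1",
                   isoform_set = c("g1.t1", "g1.t2"), read_count = c(75, 25)),
    tibble::tibble(sample_id = "case1", gene_id = "g1",
                   isoform_set = c("g1.t1", "g1.t2"), read_count = c(75, 25)))
  q <- quantify_classes(ann, cls, design)
  iso <- q$isoforms
  expect_equal(iso$proportion[iso$transcript_id == "g1.t1"], c(0.75, 0.75),
               tolerance = 1e-9)
  expect_equal(q$genes$count, c(100, 100))
  # gene RPKM uses the union exon length (300 bp here)
  expect_equal(q$genes$rpkm, rep(1e9 * 100 / (100 * 300), 2), tolerance = 1e-9)
  # determinism: identical inputs give identical rows
  ctrl <- iso[iso$sample_id == "ctrl1", -1]
  case <- iso[iso$sample_id == "case1", -1]
  expect_equal(ctrl$rpkm, case$rpkm)
})

test_that("zero-read genes get RPKM 0 and undefined proportions", {
  ann <- toy_annotation()
  design <- toy_design(1)
  cls <- tibble::tibble(sample_id = c("ctrl1", "case1"), gene_id = "g1",
                        isoform_set = "g1.t1", read_count = 10)
  q <- quantify_classes(ann, cls, design)
  g2 <- q$genes[q$genes$gene_id == "g2", ]
  expect_equal(g2$rpkm, c(0, 0))
  expect_true(all(is.na(q$isoforms$proportion[q$isoforms$gene_id == "g2"])))
})

test_that("a design sample without an input file is reported by name", {
  ann <- g1_ann()
  design <- toy_design(1)
  design$path <- c("/nonexistent/a.tsv", "/nonexistent/b.tsv")
  expect_error(quantify_samples(ann, design), "ctrl1")
})

test_that("SAM alignments quantify through the compatibility builder", {
  ann <- g1_ann()
  sam <- withr::local_tempfile(fileext = ".sam")
  # 0-based exon blocks (100,200),(300,400),(500,600); SAM POS is 1-based
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t121\t60\t40M\t*\t0\t0\t*\t*\tNH:i:1",         # exon 1, both
    "r2\t0\tchr1\t181\t60\t20M300N20M\t*\t0\t0\t*\t*\tNH:i:1",  # skip junction
    "r3\t0\tchr1\t181\t60\t20M100N20M\t*\t0\t0\t*\t*\tNH:i:1",  # t1 junction
    "r4\t16\tchr1\t521\t60\t30M\t*\t0\t0\t*\t*\tNH:i:1",        # exon 3, both
    "r5\t0\tchr1\t121\t60\t40M\t*\t0\t0\t*\t*\tNH:i:2"),        # multi-mapped
    sam)
  design <- tibble::tibble(sample_id = c("ctrl1", "case1"),
                           condition = c("control", "case"),
                           path = c(sam, sam))
  q <- quantify_samples(ann, design)
  expect_equal(unique(q$samples$total_mapped), 4)  # NH:i:2 read skipped
  expect_equal(unique(q$genes$count), 4)
  iso <- q$isoforms[q$isoforms$sample_id == "ctrl1", ]
  expect_equal(sum(iso$est_count), 4, tolerance = 1e-6)
})
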