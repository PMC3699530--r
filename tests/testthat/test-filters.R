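# Abundance fixtures use unique-read classes with one filler gene padding
# each sample's total to exactly 1e8 reads; with 1000 bp isoforms a read
# count of 100*r then gives an RPKM of exactly r, making cutoff cases exact.

abundance_fixture <- function(gene_rpkm) {
  # gene_rpkm: tibble(gene_id, ctrl, case) target mean RPKM per condition
  ann <- dplyr::bind_rows(lapply(c(gene_rpkm$gene_id, "filler"), function(g)
    annotation_tbl(g, paste0(g, ".t1"), "chr1", 0, 1000, "+")))
  design <- toy_design(3)
  cls <- dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i) {
    level <- if (design$condition[i] == "control") gene_rpkm$ctrl else gene_rpkm$case
    counts <- round(level * 100)  # RPKM -> reads at L=1000, N=1e8
    rows <- tibble::tibble(sample_id = design$sample_id[i],
                           gene_id = gene_rpkm$gene_id,
                           isoform_set = paste0(gene_rpkm$gene_id, ".t1"),
                           read_count = pmax(counts, 0))
    rows <- rows[rows$read_count > 0, ]
    dplyr::bind_rows(rows, tibble::tibble(
      sample_id = design$sample_id[i], gene_id = "filler",
      isoform_set = "filler.t1",
      read_count = 1e8 - sum(rows$read_count)))
  }))
  quantify_classes(ann, cls, design)
}

test_that("gene abundance filter removes genes below 1 RPKM in both conditions", {
  q <- abundance_fixture(tibble::tibble(
    gene_id = c("low_both", "low_ctrl", "boundary"),
    ctrl = c(0.5, 0.5, 1.0), case = c(0.5, 2.0, 1.0)))
  rep <- abundance_filter_genes(q)
  expect_false(rep$pass[rep$entity_id == "low_both"])
  expect_true(rep$pass[rep$entity_id == "low_ctrl"])   # expressed in case only
  expect_true(rep$pass[rep$entity_id == "boundary"])   # < is strict
  # stricter reading available by switch
  thr2 <- analysis_thresholds(require_both_conditions = TRUE)
  rep2 <- abundance_filter_genes(q, thr2)
  expect_false(rep2$pass[rep2$entity_id == "low_ctrl"])
  expect_true(rep2$pass[rep2$entity_id == "boundary"])
  expect_true(all(table(rep$entity_id) == 1))
})

test_that("isoform abundance filter applies the same rule within surviving genes", {
  ann <- dplyr::bind_rows(
    annotation_tbl("gA", "gA.t1", "chr1", 0, 1000, "+"),
    annotation_tbl("gA", "gA.t2", "chr1", 0, 1000, "+"),
    annotation_tbl("gB", "gB.t1", "chr1", 2000, 3000, "+"),
    annotation_tbl("filler", "filler.t1", "chr1", 5000, 6000, "+"))
  design <- toy_design(2)
  mk <- function(sid, counts) {
    # counts of 100*r at L=1000, N=1e8 give RPKM exactly r
    rows <- tibble::tibble(sample_id = sid,
                           gene_id = c("gA", "gA", "gB"),
                           isoform_set = c("gA.t1", "gA.t2", "gB.t1"),
                           read_count = counts)
    dplyr::bind_rows(rows, tibble::tibble(
      sample_id = sid, gene_id = "filler", isoform_set = "filler.t1",
      read_count = 1e8 - sum(counts)))
  }
  cls <- dplyr::bind_rows(
    mk("ctrl1", c(500, 90, 40)), mk("ctrl2", c(500, 90, 40)),
    mk("case1", c(20, 90, 40)), mk("case2", c(20, 90, 40)))
  q <- quantify_classes(ann, cls, design)
  g <- abundance_filter_genes(q)
  i <- abundance_filter_isoforms(q, surviving_genes = g$entity_id[g$pass])
  expect_false(g$pass[g$entity_id == "gB"])            # 0.4/0.4 RPKM: removed
  expect_false("gB.t1" %in% i$entity_id)               # isoform of removed gene absent
  expect_true(i$pass[i$entity_id == "gA.t1"])          # 5 / 0.2: kept
  expect_false(i$pass[i$entity_id == "gA.t2"])         # 0.9 / 0.9: removed
})

test_that("variance filter enforces the enlarged-proportion variance cutoff", {
  ann <- dplyr::bind_rows(
    annotation_tbl("stable", "stable.t1", "chr1", 0, 1000, "+"),
    annotation_tbl("stable", "stable.t2", "chr1", 0, 1000, "+"),
    annotation_tbl("wobbly", "wobbly.t1", "chr1", 2000, 3000, "+"),
    annotation_tbl("wobbly", "wobbly.t2", "chr1", 2000, 3000, "+"))
  design <- toy_design(3)
  cls <- dplyr::bind_rows(
    two_iso_classes("stable", c("stable.t1", "stable.t2"),
                    c(0.9, 0.9, 0.9), c(0.9, 0.9, 0.9), design),
    two_iso_classes("wobbly", c("wobbly.t1", "wobbly.t2"),
                    c(0.9, 0.5, 0.7), c(0.7, 0.7, 0.7), design))
  q <- quantify_classes(ann, cls, design)
  rep <- variance_filter(q)
  expect_true(rep$pass[rep$entity_id == "stable"])     # variance 0
  expect_false(rep$pass[rep$entity_id == "wobbly"])    # ((20)^2+(-20)^2)/2 = 400
  expect_equal(rep$max_variance[rep$entity_id == "wobbly"], 400, tolerance = 1e-6)
})

test_that("the variance cutoff is strict: a gene at the cutoff fails", {
  ann <- dplyr::bind_rows(
    annotation_tbl("g", "g.t1", "chr1", 0, 1000, "+"),
    annotation_tbl("g", "g.t2", "chr1", 0, 1000, "+"))
  design <- toy_design(3)
  cls <- two_iso_classes("g", c("g.t1", "g.t2"),
                         c(0.4, 0.5, 0.6), c(0.5, 0.5, 0.5), design)
  q <- quantify_classes(ann, cls, design)
  # enlarged proportions (40, 50, 60): sample variance exactly 100
  at_cut <- variance_filter(q, analysis_thresholds(variance_cutoff = 100))
  above <- variance_filter(q, analysis_thresholds(variance_cutoff = 100.001))
  expect_false(at_cut$pass)
  expect_true(above$pass)
  # population-variance option uses the n denominator: 200/3
  pop <- variance_filter(q, analysis_thresholds(variance_denominator = "n"))
  expect_equal(pop$max_variance, 200 / 3, tolerance = 1e-6)
})

test_that("variance filter refuses single-replicate conditions", {
  ann <- dplyr::bind_rows(
    annotation_tbl("g", "g.t1", "chr1", 0, 1000, "+"),
    annotation_tbl("g", "g.t2", "chr1", 0, 1000, "+"))
  design <- toy_design(1)
  cls <- tibble::tibble(sample_id = rep(design$sample_id, each = 2),
                        gene_id = "g",
                        isoform_set = rep(c("g.t1", "g.t2"), 2),
                        read_count = 50)
  q <- quantify_classes(ann, cls, design)
  expect_error(variance_filter(q), ">= 2")
})

test_that("candidate selection needs >1 expressed isoform and all filters passed", {
  sim <- simulate_splicing_study(sim_config(seed = 21L, n_genes = 25))
  q <- quantify_classes(sim$annotation, sim$classes, sim$design)
  flt <- run_filters(q)
  # every candidate passes all three rules
  expect_true(all(flt$candidates %in% flt$genes$entity_id[flt$genes$pass]))
  expect_true(all(flt$candidates %in% flt$variance$entity_id[flt$variance$pass]))
  n_expr <- flt$isoforms |>
    dplyr::filter(pass) |> dplyr::count(gene_id)
  expect_true(all(n_expr$n[match(flt$candidates, n_expr$gene_id)] >= 2))
  # single-isoform genes can never be candidates
  one_iso <- sim$truth$gene_id[sim$truth$n_isoforms == 1]
  expect_length(intersect(flt$candidates, one_iso), 0)
})

test_that("filters are order-stable and monotone in their thresholds", {
  sim <- simulate_splicing_study(sim_config(seed = 22L, n_genes = 25))
  q1 <- quantify_classes(sim$annotation, sim$classes, sim$design)
  set.seed(1)
  shuffled <- sim$classes[sample(nrow(sim$classes)), ]
  q2 <- quantify_classes(sim$annotation, shuffled, sim$design)
  expect_equal(run_filters(q1)$candidates, run_filters(q2)$candidates)
  base <- run_filters(q1)$candidates
  tighter_var <- run_filters(q1, analysis_thresholds(variance_cutoff = 10))$candidates
  tighter_rpkm <- run_filters(q1, analysis_thresholds(min_avg_rpkm = 1e5))$candidates
  expect_true(all(tighter_var %in% base))
  expect_true(all(tighter_rpkm %in% base))
})
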