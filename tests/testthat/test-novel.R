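# toy gene: parent with exons (100,200),(300,400),(500,600); the skip
# junction 200->500 is unannotated while 200->300 and 400->500 are annotated
skip_gene <- function() {
  dplyr::bind_rows(
    annotation_tbl("g", "g.t1", "chr1", c(100, 300, 500), c(200, 400, 600), "+"),
    annotation_tbl("g", "g.t2", "chr1", c(100, 300), c(200, 400), "+"))
}

obs_junction <- function(donor, acceptor, support, sample_id, chrom = "chr1") {
  tibble::tibble(chrom = chrom, donor_end = donor, acceptor_start = acceptor,
                 strand = "*", read_support = support, sample_id = sample_id)
}

test_that("novel junctions require unannotated exon-boundary pairs of one gene", {
  ann <- skip_gene()
  design <- toy_design(1)
  obs <- dplyr::bind_rows(
    obs_junction(200, 500, 10, "case1"),   # novel skip: called
    obs_junction(200, 300, 50, "case1"),   # annotated: not called
    obs_junction(200, 450, 12, "case1"),   # acceptor off-boundary: not called
    obs_junction(150, 500, 12, "case1"))   # donor off-boundary: not called
  calls <- find_novel_junctions(obs, ann, design)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$donor_end, 200)
  expect_equal(calls$acceptor_start, 500)
  expect_equal(calls$gene_id, "g")
  expect_equal(calls$mechanism, "skipping_exon")
  expect_true(calls$condition_specific)
})

test_that("support threshold and condition specificity are honoured", {
  ann <- skip_gene()
  design <- toy_design(2)
  weak <- obs_junction(200, 500, 1, "case1")
  expect_equal(nrow(find_novel_junctions(weak, ann, design)), 0)
  both <- dplyr::bind_rows(obs_junction(200, 500, 5, "case1"),
                           obs_junction(200, 500, 4, "ctrl1"))
  calls <- find_novel_junctions(both, ann, design)
  expect_equal(calls$read_support, 9)
  expect_false(calls$condition_specific)   # seen in a control sample
  two_case <- dplyr::bind_rows(obs_junction(200, 500, 5, "case1"),
                               obs_junction(200, 500, 5, "case2"))
  strict <- find_novel_junctions(two_case, ann, design, min_case_samples = 2)
  expect_true(strict$condition_specific)
})

test_that("junctions matching two genes are excluded as ambiguous", {
  ann <- dplyr::bind_rows(
    skip_gene(),
    annotation_tbl("g2", "g2.t1", "chr1", c(150, 480, 700), c(200, 520, 800), "+"))
  # 200->700: donor boundary exists in g and g2, acceptor only in g2
  obs <- obs_junction(200, 700, 10, "case1")
  calls <- find_novel_junctions(obs, ann, toy_design(1))
  expect_equal(calls$gene_id, "g2")
  # make it truly ambiguous: both boundaries in both genes, junction unannotated
  ann2 <- dplyr::bind_rows(
    skip_gene(),
    annotation_tbl("g3", "g3.t1", "chr1", c(150, 350, 500), c(200, 450, 600), "+"))
  expect_message(
    calls2 <- find_novel_junctions(obs_junction(200, 500, 10, "case1"),
                                   ann2, toy_design(1)),
    "ambiguous")
  expect_equal(nrow(calls2), 0)
})

test_that("exon-skipping composition drops interior exons and suffixes _N", {
  ann <- skip_gene()
  novel <- compose_novel_transcript(ann, "g.t1", 200, 500)
  expect_equal(novel$transcript_id, rep("g.t1_N", 2))
  expect_equal(novel$start, c(100, 500))
  expect_equal(novel$end, c(200, 600))
  expect_true(all(novel$is_novel))
  expect_equal(unique(novel$parent_id), "g.t1")
  # composed transcript is shorter than its parent
  expect_lt(sum(novel$end - novel$start),
            sum(ann$end[ann$transcript_id == "g.t1"] -
                  ann$start[ann$transcript_id == "g.t1"]))
  # junction set = parent's minus removed-exon junctions plus the novel one
  pj <- transcript_junctions(ann) |> dplyr::filter(transcript_id == "g.t1")
  nj <- transcript_junctions(validate_annotation(novel))
  expect_equal(nrow(nj), 1)
  expect_equal(nj$donor_end, 200)
  expect_equal(nj$acceptor_start, 500)
  expect_false(any(paste(nj$donor_end, nj$acceptor_start) %in%
                     paste(pj$donor_end, pj$acceptor_start)))
})

test_that("multi-exon skips and degenerate junctions are handled", {
  ann <- annotation_tbl("g5", "g5.t1", "chr1",
                        c(0, 200, 400, 600, 800),
                        c(100, 300, 500, 700, 900), "+")
  novel <- compose_novel_transcript(ann, "g5.t1", 100, 800)
  expect_equal(nrow(novel), 2)  # exons 2-4 removed
  expect_error(compose_novel_transcript(ann, "g5.t1", 100, 200),
               "skips no exon")
  expect_error(compose_novel_transcript(ann, "missing", 100, 800), "not found")
})

test_that("two parents sharing a junction each get a novel transcript", {
  ann <- dplyr::bind_rows(
    annotation_tbl("g", "TXA", "chr1", c(100, 300, 500), c(200, 400, 600), "+"),
    annotation_tbl("g", "TXB", "chr1", c(100, 300, 500, 700),
                   c(200, 400, 600, 800), "+"))
  calls <- tibble::tibble(chrom = "chr1", donor_end = 200, acceptor_start = 500,
                          gene_id = "g", parents = "TXA,TXB")
  novel <- compose_novel_transcripts(ann, calls)
  expect_setequal(unique(novel$transcript_id), c("TXA_N", "TXB_N"))
})

test_that("augmentation validates, round-trips, and silences incorporated junctions", {
  ann <- skip_gene()
  novel <- compose_novel_transcript(ann, "g.t1", 200, 500)
  aug <- augment_annotation(ann, novel)
  expect_equal(dplyr::n_distinct(aug$transcript_id), 3)
  expect_error(augment_annotation(aug, novel), "duplicate")
  expect_equal(augment_annotation(ann, novel[0, ]), ann)
  # GTF round trip keeps the novel flag and parent linkage
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(aug, f)
  back <- read_gtf(f)
  nrec <- back[back$transcript_id == "g.t1_N", ]
  expect_true(all(nrec$is_novel))
  expect_equal(unique(nrec$parent_id), "g.t1")
  # the junction is annotated now: re-running detection returns nothing
  again <- find_novel_junctions(obs_junction(200, 500, 10, "case1"),
                                aug, toy_design(1))
  expect_equal(nrow(again), 0)
})

test_that("after augmentation the novel isoform absorbs junction-spanning reads", {
  ann <- skip_gene()
  aug <- augment_annotation(ann, compose_novel_transcript(ann, "g.t1", 200, 500))
  skip_read <- tibble::tibble(read_id = "r1", chrom = "chr1",
                              blocks = list(cbind(c(180, 500), c(200, 520))))
  before <- build_compatibility(skip_read, ann)
  expect_equal(before$total_reads, 0)  # no annotated isoform carries 200->500
  after <- build_compatibility(skip_read, aug)
  expect_equal(after$total_reads, 1)
  expect_equal(after$isoform_ids[after$classes$iso_set[[1]]], "g.t1_N")
})

test_that("mutually exclusive skipping junction pairs are labelled", {
  # exons A(0,100) B(200,300) C(400,500) D(600,700); isoforms use B xor C
  ann <- dplyr::bind_rows(
    annotation_tbl("g", "t1", "chr1", c(0, 200, 400, 600),
                   c(100, 300, 500, 700), "+"))
  design <- toy_design(1)
  obs <- dplyr::bind_rows(
    obs_junction(100, 400, 10, "case1"),  # skips B
    obs_junction(300, 600, 10, "case1"))  # skips C
  calls <- find_novel_junctions(obs, ann, design)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$mechanism, c("mutually_exclusive", "mutually_exclusive"))
})
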