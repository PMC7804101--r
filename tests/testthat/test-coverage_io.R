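test_that("coverage extraction from a synthetic BAM matches per-base truth", {
  skip_if_not_installed("GenomicAlignments")
  lay <- small_layout(L = 200L) # exons (100,300),(400,600); intron included
  bam <- file.path(tempdir(), "cov_fixture.bam")

  # 40 reads of 50M tiling exon 1 uniformly: depth 7 on its first 150 bases
  reads <- fixture_reads(pos = rep(seq(100, 240, by = 10), length.out = 105)[1:105],
                         cigar = rep("50M", 105))
  # build exact truth by pileup arithmetic
  truth <- integer(600)
  for (p in reads$pos) truth[(p + 1):(p + 50)] <- truth[(p + 1):(p + 50)] + 1L
  write_alignment_fixture(reads, bam, chrom = "chr1", chrom_len = 1000L)

  depth <- extract_coverage(bam, lay)
  expect_equal(depth, truth[lay$column_map + 1L])
})

test_that("empty region and boundary-spanning reads behave as specified", {
  skip_if_not_installed("GenomicAlignments")
  lay <- small_layout(L = 200L)
  bam <- file.path(tempdir(), "cov_empty.bam")
  # single read far away from the locus
  write_alignment_fixture(fixture_reads(900, "30M"), bam, chrom_len = 1000L)
  expect_equal(extract_coverage(bam, lay), rep(0L, length(lay$column_map)))

  # one read spanning the exon1/intron boundary: depth 1 on every covered column
  bam2 <- file.path(tempdir(), "cov_span.bam")
  write_alignment_fixture(fixture_reads(280, "40M"), bam2, chrom_len = 1000L)
  d2 <- extract_coverage(bam2, lay)
  covered <- lay$column_map >= 280 & lay$column_map < 320
  expect_equal(d2[covered], rep(1L, sum(covered)))
  expect_equal(sum(d2), 40L)
  expect_true(max(d2) <= 1L)
})

test_that("junction extraction counts distinct gapped-alignment skips", {
  skip_if_not_installed("GenomicAlignments")
  lay <- small_layout(L = 200L)
  bam <- file.path(tempdir(), "jx_fixture.bam")
  reads <- dplyr::bind_rows(
    fixture_reads(rep(250, 5), rep("50M100N50M", 5)), # skip (300,400) x5
    fixture_reads(rep(150, 3), rep("60M", 3)),        # no gap
    fixture_reads(rep(270, 2), rep("30M100N30M", 2))  # skip (300,400) too
  )
  write_alignment_fixture(reads, bam, chrom_len = 1000L)
  jx <- extract_junctions(bam, lay, sample_id = "sA")
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$donor, 300L)
  expect_equal(jx$acceptor, 400L)
  expect_equal(jx$count, 7L)

  # two distinct skips -> two records; gapless reads contribute none
  bam2 <- file.path(tempdir(), "jx_two.bam")
  write_alignment_fixture(dplyr::bind_rows(
    fixture_reads(250, "50M100N50M"),
    fixture_reads(240, "40M120N40M")
  ), bam2, chrom_len = 1000L)
  jx2 <- extract_junctions(bam2, lay, sample_id = "sB")
  expect_equal(nrow(jx2), 2L)
})

test_that("missing index and unknown contig produce explicit errors", {
  lay <- small_layout()
  fake <- tempfile(fileext = ".bam")
  file.create(fake)
  expect_error(extract_coverage(fake, lay), "index")

  skip_if_not_installed("GenomicAlignments")
  bam <- file.path(tempdir(), "contig_fixture.bam")
  write_alignment_fixture(fixture_reads(150, "50M"), bam, chrom = "chr9",
                          chrom_len = 1000L)
  expect_error(extract_coverage(bam, lay), "chr1")
})

test_that("coverage TSV round-trips losslessly and rejects malformed input", {
  withr::local_seed(11)
  lay <- small_layout(L = 200L)
  cov <- coverage_matrix(
    matrix(rpois(length(lay$column_map) * 4, 20), ncol = 4),
    paste0("s", 1:4), lay
  )
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(cov, path)
  back <- read_matrix_tsv(path, layout = lay)
  expect_equal(back$R, cov$R)
  expect_equal(back$sample_ids, cov$sample_ids)

  # without a layout a surrogate is built from the position runs
  back2 <- read_matrix_tsv(path)
  expect_equal(unname(back2$R), unname(cov$R))
  expect_equal(back2$layout$column_map, lay$column_map)

  # header/sample mismatch
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("pos\ts1\ts2", "100\t5"), bad)
  expect_error(read_matrix_tsv(bad), "match")
  empty <- tempfile(fileext = ".tsv")
  writeLines("pos\ts1", empty)
  expect_error(read_matrix_tsv(empty), "empty")
})

test_that("junction TSV round-trips", {
  jx <- tibble::tibble(donor = c(300L, 500L), acceptor = c(400L, 650L),
                       sample_id = c("a", "b"), count = c(5L, 2L))
  path <- tempfile(fileext = ".tsv")
  write_junctions_tsv(jx, path)
  expect_equal(read_junctions_tsv(path), jx)
})

test_that("coverage_matrix validates inputs", {
  lay <- small_layout()
  d <- length(lay$column_map)
  expect_error(coverage_matrix(matrix(-1, d, 2), c("a", "b"), lay), "non-negative")
  expect_error(coverage_matrix(matrix(0, d + 1, 2), c("a", "b"), lay), "layout dimension")
  expect_error(coverage_matrix(matrix(0, d, 2), c("a", "a"), lay), "unique")
})
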