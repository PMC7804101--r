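test_that("union gene model merges transcript exons and derives introns", {
  # identity case
  one <- build_union_gene_model(list(cbind(c(0, 200), c(100, 300))))
  expect_equal(one$exons$start, c(0L, 200L))
  expect_equal(one$exons$end, c(100L, 300L))
  expect_equal(one$introns$start, 100L)
  expect_equal(one$introns$end, 200L)

  # overlap merges, gap narrows
  two <- build_union_gene_model(list(
    cbind(c(0, 200), c(100, 300)),
    cbind(c(50, 200), c(150, 300))
  ))
  expect_equal(two$exons$start, c(0L, 200L))
  expect_equal(two$exons$end, c(150L, 300L))
  expect_equal(two$introns$start, 150L)

  # adjacency merges, no intron remains
  adj <- build_union_gene_model(list(cbind(0, 100), cbind(100, 200)))
  expect_equal(nrow(adj$exons), 1L)
  expect_equal(adj$exons$end, 200L)
  expect_equal(nrow(adj$introns), 0L)
})

test_that("malformed transcript input is rejected", {
  expect_error(build_union_gene_model(list()), "at least one")
  expect_error(build_union_gene_model(list(cbind(100, 50))), "malformed")
  expect_error(build_union_gene_model(list(cbind(c(0, 50), c(100, 150)))),
               "disjoint and sorted")
})

test_that("intron threshold balances exon and included-intron totals", {
  expect_identical(choose_intron_threshold(c(100, 200, 100), c(150, 700)), 250L)
  expect_identical(choose_intron_threshold(100, integer()), 0L)
  # objective is flat above the largest intron: smallest optimum returned
  expect_identical(choose_intron_threshold(500, c(100, 100)), 100L)
})

test_that("threshold choice matches brute-force enumeration on random genes", {
  withr::local_seed(421)
  for (rep in 1:25) {
    ex <- sample(50:400, sample(2:6, 1), replace = TRUE)
    ins <- sample(30:900, length(ex) - 1L, replace = TRUE)
    L <- choose_intron_threshold(ex, ins)
    grid <- 0:max(ins)
    obj <- vapply(grid, function(l) abs(sum(ex) - sum(pmin(ins, l))), numeric(1))
    expect_equal(obj[L + 1L], min(obj))
    expect_identical(L, as.integer(grid[which.min(obj)])) # smallest tie
  }
})

test_that("intron inclusion keeps short introns whole and splits long ones", {
  lay <- build_union_gene_model(list(cbind(c(0, 200), c(100, 300))))
  whole <- apply_intron_inclusion(lay, L = 250L)
  expect_equal(whole$included_intron_parts$side, "all")
  expect_equal(nrow(layout_columns(whole)), 300L)

  long <- build_union_gene_model(list(cbind(c(0, 1700), c(1000, 1800))))
  split <- apply_intron_inclusion(long, L = 250L)
  expect_equal(split$included_intron_parts$start, c(1000L, 1575L))
  expect_equal(split$included_intron_parts$end, c(1125L, 1700L))

  none <- apply_intron_inclusion(long, L = 0L)
  expect_equal(nrow(none$included_intron_parts), 0L)
  expect_equal(length(none$column_map), 1100L) # exon bases only
})

test_that("layout dimension and column map satisfy the structural invariants", {
  withr::local_seed(99)
  for (rep in 1:10) {
    ex <- sort(sample(50:300, sample(2:5, 1)))
    lens <- sample(40:200, length(ex), replace = TRUE)
    ins <- sample(30:600, length(ex) - 1L, replace = TRUE)
    pos <- 10L
    tx <- matrix(0L, length(ex), 2)
    for (k in seq_along(ex)) {
      tx[k, ] <- c(pos, pos + lens[k])
      pos <- pos + lens[k] + if (k < length(ex)) ins[k] else 0L
    }
    lay <- build_gene_model(list(tx))
    d <- length(lay$column_map)
    exp_d <- sum(lens) + sum(vapply(seq_len(nrow(lay$introns)), function(k) {
      il <- lay$introns$end[k] - lay$introns$start[k]
      if (il <= lay$L) il else 2L * (lay$L %/% 2L)
    }, numeric(1)))
    expect_equal(d, exp_d)
    expect_true(!is.unsorted(lay$column_map, strictly = TRUE))
    # round trip on included positions; excluded interiors have no column
    expect_equal(genomic_to_column(lay, column_to_genomic(lay, seq_len(d))),
                 seq_len(d))
    excluded <- setdiff(seq(min(lay$column_map), max(lay$column_map)),
                        lay$column_map)
    if (length(excluded)) {
      expect_true(all(is.na(genomic_to_column(lay, excluded))))
    }
  }
})

test_that("split intron flanks are labelled by strand-aware 5'/3' side", {
  plus <- build_gene_model(list(cbind(c(0, 1700), c(1000, 1800))),
                           strand = "+", L = 250L)
  minus <- build_gene_model(list(cbind(c(0, 1700), c(1000, 1800))),
                            strand = "-", L = 250L)
  expect_equal(plus$included_intron_parts$side, c("5p", "3p"))
  expect_equal(minus$included_intron_parts$side, c("3p", "5p"))
})

test_that("BED12 reader and layout writer round-trip a toy gene", {
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr7", 100, 900, "geneA", 0, "+", 100, 900, "0",
                     "3", "100,150,200", "0,300,600"), collapse = "\t"), bed)
  models <- read_gene_models_bed12(bed)
  expect_named(models, "geneA")
  lay <- models$geneA
  expect_equal(lay$exons$start, c(100L, 400L, 700L))
  expect_equal(lay$exons$end, c(200L, 550L, 900L))

  lay <- apply_intron_inclusion(lay)
  out_bed <- tempfile(fileext = ".bed")
  write_layout_bed(lay, out_bed)
  written <- read.table(out_bed, sep = "\t")
  expect_true(all(grepl("^(exon|intron)", written$V4)))
  meta <- jsonlite::read_json(paste0(out_bed, ".json"))
  expect_equal(meta$L, lay$L)
  expect_equal(meta$d, length(lay$column_map))
})

test_that("GTF reader builds union models grouped by gene", {
  gtf <- tempfile(fileext = ".gtf")
  rows <- c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gX"; transcript_id "t1";',
    'chr1\ttest\texon\t401\t600\t.\t+\t.\tgene_id "gX"; transcript_id "t1";',
    'chr1\ttest\texon\t151\t250\t.\t+\t.\tgene_id "gX"; transcript_id "t2";',
    'chr1\ttest\texon\t401\t600\t.\t+\t.\tgene_id "gX"; transcript_id "t2";'
  )
  writeLines(rows, gtf)
  models <- read_gene_models_gtf(gtf)
  lay <- models$gX
  expect_equal(lay$exons$start, c(100L, 400L)) # 1-based closed -> 0-based
  expect_equal(lay$exons$end, c(250L, 600L))
  expect_equal(lay$introns$start, 250L)
})
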