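#' Per-gene coverage matrix container
#'
#' A coverage matrix holds base-level read depth over one gene layout:
#' a `d x n` non-negative matrix `R` (rows = layout columns in ascending
#' genomic order, columns = samples), the sample ids, the `gene_layout`, and
#' an optional splice-junction table.
#'
#' @param R `d x n` numeric matrix of non-negative read depths.
#' @param sample_ids unique character vector of length `n`.
#' @param layout `gene_layout` with intron inclusion applied; its dimension
#'   must equal `nrow(R)`.
#' @param junctions optional tibble of junction records
#'   (`donor`, `acceptor`, `sample_id`, `count`), 0-based half-open skipped
#'   interval with `donor < acceptor` and `count >= 0`.
#' @return object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(R, sample_ids, layout, junctions = NULL) {
  stopifnot(inherits(layout, "gene_layout"), !is.null(layout$column_map))
  R <- as.matrix(R)
  if (!is_count_matrix(R)) stop("R must be a finite non-negative numeric matrix")
  if (nrow(R) != length(layout$column_map)) {
    stop("nrow(R) must equal the layout dimension d = ", length(layout$column_map))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(R) || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and match ncol(R)")
  }
  colnames(R) <- sample_ids
  junctions <- junctions %||% empty_junction_table()
  stopifnot(all(junctions$donor < junctions$acceptor), all(junctions$count >= 0))
  structure(
    list(R = R, sample_ids = sample_ids, layout = layout,
         junctions = tibble::as_tibble(junctions)),
    class = "coverage_matrix"
  )
}

empty_junction_table <- function() {
  tibble::tibble(donor = integer(), acceptor = integer(),
                 sample_id = character(), count = integer())
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %s: d = %d positions x n = %d samples, %d junction record(s)\n",
              x$layout$gene_id, nrow(x$R), ncol(x$R), nrow(x$junctions)))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$R)

default_bam_flags <- function(include_duplicates = FALSE) {
  Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE,
    isNotPassingQualityControls = FALSE,
    isUnmappedQuery = FALSE
  )
}

layout_granges <- function(layout) {
  cols <- layout_columns(layout)
  runs <- rle(cols$label)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  GenomicRanges::GRanges(
    seqnames = layout$chrom,
    ranges = IRanges::IRanges(start = cols$pos[starts] + 1L, end = cols$pos[ends] + 1L)
  )
}

check_bam_contig <- function(bam, chrom) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    stop("contig '", chrom, "' not present in BAM ", bam,
         " (contigs: ", paste(names(hdr), collapse = ", "), ")")
  }
}

#' Extract one sample's base-level coverage from an indexed BAM
#'
#' Pileup depth at every layout column; positions with no aligned reads are 0.
#' Depth follows conventional pileup semantics (alignment match/mismatch and
#' deletion operations consume depth; skips and soft clips do not). Secondary
#' and QC-failed alignments are always excluded; duplicates are excluded by
#' default.
#'
#' @param bam path to an indexed BAM file.
#' @param layout `gene_layout` with intron inclusion applied.
#' @param min_mapq minimum mapping quality (default 0: no filter).
#' @param include_duplicates count duplicate-flagged reads (default `FALSE`).
#' @return integer vector of length `d` (one depth per layout column).
#' @export
extract_coverage <- function(bam, layout, min_mapq = 0, include_duplicates = FALSE) {
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("missing BAM index for ", bam)
  }
  check_bam_contig(bam, layout$chrom)
  gr <- layout_granges(layout)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = gr, flag = default_bam_flags(include_duplicates)),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = 0L, min_mapq = as.integer(min_mapq),
      distinguish_strands = FALSE, distinguish_nucleotides = FALSE,
      include_deletions = TRUE, include_insertions = FALSE
    )
  )
  depth <- integer(length(layout$column_map))
  if (nrow(p) > 0L) {
    agg <- stats::aggregate(count ~ pos, data = p, FUN = sum)
    idx <- genomic_to_column(layout, agg$pos - 1L)
    keep <- !is.na(idx)
    depth[idx[keep]] <- agg$count[keep]
  }
  depth
}

#' Extract splice junctions from an indexed BAM
#'
#' One record per distinct gapped-alignment skip (CIGAR `N` span) overlapping
#' the locus, with its supporting read count. Junction intervals are 0-based
#' half-open over the skipped bases.
#'
#' @inheritParams extract_coverage
#' @param sample_id sample label attached to the records.
#' @return tibble with `donor`, `acceptor`, `sample_id`, `count`.
#' @export
extract_junctions <- function(bam, layout, sample_id = basename(bam),
                              min_mapq = 0, include_duplicates = FALSE) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("GenomicAlignments is required for junction extraction from BAM")
  }
  check_bam_contig(bam, layout$chrom)
  span <- GenomicRanges::GRanges(
    seqnames = layout$chrom,
    ranges = IRanges::IRanges(min(layout$column_map) + 1L, max(layout$column_map) + 1L)
  )
  gal <- GenomicAlignments::readGAlignments(
    bam,
    param = Rsamtools::ScanBamParam(
      which = span, flag = default_bam_flags(include_duplicates),
      mapqFilter = as.integer(min_mapq)
    )
  )
  j <- unlist(GenomicAlignments::junctions(gal))
  if (length(j) == 0L) return(empty_junction_table())
  key <- paste(GenomicRanges::start(j) - 1L, GenomicRanges::end(j), sep = ":")
  tab <- table(key)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  out <- tibble::tibble(
    donor = vapply(parts, function(x) as.integer(x[1]), integer(1)),
    acceptor = vapply(parts, function(x) as.integer(x[2]), integer(1)),
    sample_id = sample_id,
    count = as.integer(tab)
  )
  dplyr::arrange(out, .data$donor, .data$acceptor)
}

#' Assemble a coverage matrix for a cohort of BAM files
#'
#' @param bams named character vector of BAM paths (names become sample ids).
#' @inheritParams extract_coverage
#' @param with_junctions also extract splice junctions per sample.
#' @return a [coverage_matrix()].
#' @export
build_coverage_matrix <- function(bams, layout, min_mapq = 0,
                                  include_duplicates = FALSE, with_junctions = TRUE) {
  ids <- names(bams) %||% basename(bams)
  R <- vapply(bams, extract_coverage, integer(length(layout$column_map)),
              layout = layout, min_mapq = min_mapq,
              include_duplicates = include_duplicates)
  jx <- if (with_junctions) {
    dplyr::bind_rows(Map(function(b, id) {
      extract_junctions(b, layout, sample_id = id, min_mapq = min_mapq,
                        include_duplicates = include_duplicates)
    }, bams, ids))
  } else NULL
  coverage_matrix(R, ids, layout, junctions = jx)
}

#' Read and write coverage matrices as TSV
#'
#' Tab-separated dialect: optional `#`-prefixed metadata lines, a header row
#' with `pos` followed by sample ids, then one row per layout column with the
#' 0-based genomic position and per-sample depths. The round trip
#' `write_matrix_tsv()` / `read_matrix_tsv()` is lossless for `R`,
#' `sample_ids` and the position column.
#'
#' @param x a `coverage_matrix`.
#' @param path TSV file path.
#' @param layout layout to attach on read; when `NULL` a single-exon
#'   surrogate layout covering the file's positions is constructed (positions
#'   must then be contiguous runs; region structure is unavailable).
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "coverage_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gene_id=%s chrom=%s strand=%s L=%d",
                     x$layout$gene_id, x$layout$chrom, x$layout$strand, x$layout$L), con)
  writeLines(paste(c("pos", x$sample_ids), collapse = "\t"), con)
  df <- cbind(pos = x$layout$column_map, x$R)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, layout = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L) stop("empty coverage matrix in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "pos" || length(header) < 2L) {
    stop("malformed coverage TSV header (expected 'pos' then sample ids)")
  }
  dat <- utils::read.table(text = body[-1], sep = "\t")
  if (ncol(dat) != length(header)) {
    stop("coverage TSV row width does not match header sample count")
  }
  pos <- as.integer(dat[[1]])
  R <- as.matrix(dat[, -1, drop = FALSE])
  colnames(R) <- header[-1]
  if (is.null(layout)) {
    layout <- surrogate_layout_from_positions(pos, meta)
  }
  if (!identical(as.integer(layout$column_map), pos)) {
    stop("positions in ", path, " do not match the supplied layout")
  }
  coverage_matrix(R, header[-1], layout)
}

surrogate_layout_from_positions <- function(pos, meta = character()) {
  gene_id <- "unknown"; chrom <- "chr1"; strand <- "+"
  if (length(meta)) {
    kv <- regmatches(meta[1], gregexpr("[a-zA-Z_]+=[^ ]+", meta[1]))[[1]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (p[1] == "gene_id") gene_id <- p[2]
      if (p[1] == "chrom") chrom <- p[2]
      if (p[1] == "strand" && p[2] %in% c("+", "-")) strand <- p[2]
    }
  }
  brk <- which(diff(pos) != 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))] + 1L
  # one surrogate transcript whose "exons" are the contiguous position runs
  build_gene_model(list(cbind(starts, ends)), gene_id = gene_id,
                   chrom = chrom, strand = strand, L = 0L)
}

#' Read and write junction tables as TSV
#'
#' Columns: `chrom`, `donor`, `acceptor`, `sample_id`, `count` (0-based
#' half-open skipped interval).
#' @param junctions junction tibble.
#' @param chrom chromosome written with each record.
#' @param path TSV file path.
#' @export
write_junctions_tsv <- function(junctions, path, chrom = "chr1") {
  df <- as.data.frame(junctions)
  df <- cbind(chrom = rep(chrom, nrow(df)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junctions_tsv
#' @export
read_junctions_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  tibble::tibble(donor = as.integer(df$donor), acceptor = as.integer(df$acceptor),
                 sample_id = as.character(df$sample_id), count = as.integer(df$count))
}

#' Write a synthetic alignment fixture as an indexed BAM
#'
#' Builds a small synthetic BAM (via an intermediate SAM) from a read table;
#' intended for exercising the coverage and junction extractors against known
#' truth, not for real data.
#'
#' @param reads tibble with `pos` (0-based leftmost aligned base) and `cigar`;
#'   optional `qname`, `seq`.
#' @param bam_path output BAM path (index written alongside).
#' @param chrom,chrom_len reference name and length for the header.
#' @return the BAM path, invisibly.
#' @export
write_alignment_fixture <- function(reads, bam_path, chrom = "chr1",
                                    chrom_len = 100000L) {
  stopifnot(all(c("pos", "cigar") %in% names(reads)))
  sam_path <- tempfile(fileext = ".sam")
  qlen <- function(cig) {
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.integer(sub("[A-Z=]$", "", o))
      if (grepl("[MIS=X]$", o)) n else 0L
    }, integer(1)))
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    vapply(seq_len(nrow(reads)), function(i) {
      n <- qlen(reads$cigar[i])
      sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
              reads$qname[i] %||% paste0("r", i), chrom, reads$pos[i] + 1L,
              reads$cigar[i], strrep("A", n), strrep("I", n))
    }, character(1))
  )
  # SAM requires coordinate sorting for direct conversion
  ord <- order(reads$pos)
  lines <- c(lines[1:2], lines[-(1:2)][ord])
  writeLines(lines, sam_path)
  out <- Rsamtools::asBam(sam_path, sub("\\.bam$", "", bam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(out)
}
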