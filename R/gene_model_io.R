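# Annotation readers and layout writers.

#' Read gene models from annotation files
#'
#' `read_gene_models_gtf()` groups `exon` features by `transcript_id` within
#' `gene_id` (GTF/GFF via rtracklayer; 1-based closed coordinates converted to
#' 0-based half-open). `read_gene_models_bed12()` treats each BED12 record as
#' one transcript whose blocks are exons, grouped by the `name` field.
#'
#' @param path annotation file path.
#' @param genes optional character vector restricting to these gene ids.
#' @return named list of `gene_layout` objects (intron inclusion not applied;
#'   see [apply_intron_inclusion()]).
#' @export
read_gene_models_gtf <- function(path, genes = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GTF/GFF annotation")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features found in ", path)
  df <- tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(genes)) df <- df[df$gene_id %in% genes, ]
  if (nrow(df) == 0L) stop("no exon features left after gene filtering")
  models_from_exon_table(df)
}

#' @rdname read_gene_models_gtf
#' @export
read_gene_models_bed12 <- function(path, genes = NULL) {
  bed <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 12L) stop("BED12 input requires 12 columns")
  recs <- lapply(seq_len(nrow(bed)), function(i) {
    sizes <- as.integer(strsplit(as.character(bed[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(as.character(bed[i, 12]), ",")[[1]])
    tibble::tibble(
      gene_id = as.character(bed[i, 4]),
      transcript_id = paste0(bed[i, 4], ".", i),
      chrom = as.character(bed[i, 1]),
      strand = as.character(bed[i, 6]),
      start = as.integer(bed[i, 2]) + offs,
      end = as.integer(bed[i, 2]) + offs + sizes
    )
  })
  df <- dplyr::bind_rows(recs)
  if (!is.null(genes)) df <- df[df$gene_id %in% genes, ]
  if (nrow(df) == 0L) stop("no records left after gene filtering")
  models_from_exon_table(df)
}

models_from_exon_table <- function(df) {
  out <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(t) {
      t <- t[order(t$start), ]
      cbind(t$start, t$end)
    })
    strand <- g$strand[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    build_union_gene_model(txs, gene_id = g$gene_id[1],
                           chrom = g$chrom[1], strand = strand)
  })
  out[order(names(out))]
}

#' Write a layout as BED intervals plus a JSON sidecar
#'
#' One BED line per contiguous labelled piece (exon or included intron part),
#' label in the name field; the sidecar records `gene_id`, `strand`, `L`, `d`
#' and the piece table.
#' @param layout a `gene_layout` with intron inclusion applied.
#' @param bed_path,json_path output paths; `json_path` defaults to
#'   `bed_path` with a `.json` extension appended.
#' @export
write_layout_bed <- function(layout, bed_path, json_path = paste0(bed_path, ".json")) {
  cols <- layout_columns(layout)
  runs <- rle(cols$label)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  pieces <- tibble::tibble(
    chrom = layout$chrom,
    start = cols$pos[starts],
    end = cols$pos[ends] + 1L,
    name = runs$values,
    score = 0L,
    strand = layout$strand
  )
  utils::write.table(pieces, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(gene_id = layout$gene_id, chrom = layout$chrom, strand = layout$strand,
         L = layout$L, d = nrow(cols),
         pieces = pieces[, c("start", "end", "name")]),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(bed_path)
}
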