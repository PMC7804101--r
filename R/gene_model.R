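#' Gene coordinate systems for base-level coverage analysis
#'
#' A gene layout is the union-of-transcripts exon model plus the parts of the
#' intervening introns that are carried into the coverage matrix. Introns are
#' included up to a threshold `L` chosen so that total included intronic length
#' approximately balances total exonic length: an intron of length `<= L` is
#' included whole; a longer intron contributes two flanks of `floor(L/2)` bp,
#' one abutting each bounding exon. All coordinates are 0-based half-open;
#' 1-based formats (GTF) are converted at the reader boundary.
#'
#' @param transcripts list with one element per transcript; each element a
#'   two-column matrix or data frame of exon `start`/`end` (0-based half-open),
#'   disjoint and sorted.
#' @param gene_id,chrom,strand gene metadata; `strand` is `"+"` or `"-"` and is
#'   used only for 5'/3' labelling and degradation orientation.
#' @return An object of class `gene_layout`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons` and `introns` (tibbles of `start`,`end`),
#'   `included_intron_parts`, threshold `L`, the genomic `column_map`
#'   (positions of matrix rows), per-column `region_labels` (side-annotated)
#'   and `region_ids` (basis regions).
#' @examples
#' layout <- build_union_gene_model(
#'   list(cbind(c(0, 200), c(100, 300)), cbind(c(50, 200), c(150, 300))),
#'   gene_id = "toy"
#' )
#' layout$exons
#' @export
build_union_gene_model <- function(transcripts, gene_id = "gene", chrom = "chr1",
                                   strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (length(transcripts) == 0L) {
    stop("at least one transcript is required to build a gene model")
  }
  ivs <- lapply(transcripts, function(tx) {
    tx <- as.matrix(as.data.frame(tx)[, 1:2])
    storage.mode(tx) <- "double"
    if (nrow(tx) == 0L || any(!is.finite(tx)) || any(tx[, 2] <= tx[, 1])) {
      stop("malformed transcript exons: need finite intervals with end > start")
    }
    if (is.unsorted(tx[, 1], strictly = TRUE) ||
        any(tx[-1L, 1] < tx[-nrow(tx), 2])) {
      stop("transcript exons must be disjoint and sorted")
    }
    tx
  })
  all_iv <- do.call(rbind, ivs)
  # interval union (merging overlap and adjacency) via IRanges on 1-based closed
  ir <- IRanges::reduce(IRanges::IRanges(start = all_iv[, 1] + 1L, end = all_iv[, 2]))
  exons <- tibble::tibble(
    start = as.integer(IRanges::start(ir)) - 1L,
    end = as.integer(IRanges::end(ir))
  )
  introns <- if (nrow(exons) > 1L) {
    tibble::tibble(start = exons$end[-nrow(exons)], end = exons$start[-1L])
  } else {
    tibble::tibble(start = integer(), end = integer())
  }
  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exons = exons, introns = introns,
      included_intron_parts = NULL, L = NA_integer_,
      column_map = NULL, region_labels = NULL, region_ids = NULL
    ),
    class = "gene_layout"
  )
}

#' @export
print.gene_layout <- function(x, ...) {
  cat(sprintf(
    "<gene_layout> %s (%s%s): %d exon(s), %d intron(s)%s\n",
    x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
    if (is.null(x$column_map)) " [intron inclusion not applied]"
    else sprintf(", L = %d, d = %d", x$L, length(x$column_map))
  ))
  invisible(x)
}

#' Balance included intronic length against exonic length
#'
#' Finds the integer threshold `L >= 0` minimising
#' `|sum(exon_lengths) - sum(pmin(intron_lengths, L))|`, i.e. the capped
#' included intronic total closest to the exonic total. Ties are broken toward
#' the smallest `L`. The objective is piecewise linear in `L`, so only segment
#' endpoints and the per-segment exact solutions need to be evaluated.
#'
#' @param exon_lengths,intron_lengths integer vectors of region lengths (bp).
#' @return integer threshold `L` (0 when there are no introns).
#' @examples
#' choose_intron_threshold(c(100, 200, 100), c(150, 700)) # 250
#' @export
choose_intron_threshold <- function(exon_lengths, intron_lengths) {
  stopifnot(length(exon_lengths) > 0L, all(exon_lengths > 0))
  if (length(intron_lengths) == 0L) return(0L)
  stopifnot(all(intron_lengths > 0))
  e_tot <- sum(exon_lengths)
  len <- sort(as.numeric(intron_lengths))
  included <- function(L) sum(pmin(len, L))
  # candidate Ls: 0, each distinct intron length, and the exact crossing point
  # within each linear segment (rounded both ways)
  brk <- unique(c(0, len))
  cand <- brk
  for (k in seq_along(brk)) {
    lo <- brk[k]
    n_above <- sum(len > lo)
    if (n_above == 0L) break
    base <- sum(len[len <= lo])
    L_star <- (e_tot - base) / n_above
    hi <- if (k < length(brk)) brk[k + 1L] else max(len)
    if (L_star >= lo && L_star <= hi) {
      cand <- c(cand, floor(L_star), ceiling(L_star))
    }
  }
  cand <- sort(unique(pmax(0, pmin(cand, max(len)))))
  obj <- vapply(cand, function(L) abs(e_tot - included(L)), numeric(1))
  as.integer(cand[which.min(obj)]) # which.min takes the first (smallest) tie
}

#' Apply intron inclusion and build the column coordinate system
#'
#' Populates `included_intron_parts`, the genomic `column_map` and per-column
#' region labels for a layout. Introns of length `<= L` are included whole;
#' longer introns contribute two `floor(L/2)` bp flanks abutting the bounding
#' exons (their columns are labelled with the 5'/3' side, strand-aware).
#'
#' @param layout a `gene_layout` from [build_union_gene_model()].
#' @param L non-negative integer threshold; defaults to
#'   [choose_intron_threshold()] on the layout's own region lengths.
#' @return the layout with `L`, `included_intron_parts`, `column_map`,
#'   `region_labels` and `region_ids` populated.
#' @export
apply_intron_inclusion <- function(layout, L = NULL) {
  stopifnot(inherits(layout, "gene_layout"))
  exon_len <- layout$exons$end - layout$exons$start
  intron_len <- layout$introns$end - layout$introns$start
  if (is.null(L)) L <- choose_intron_threshold(exon_len, intron_len)
  stopifnot(length(L) == 1L, L >= 0)
  L <- as.integer(L)

  parts <- list()
  if (nrow(layout$introns) > 0L && L > 0L) {
    half <- L %/% 2L
    for (k in seq_len(nrow(layout$introns))) {
      s <- layout$introns$start[k]; e <- layout$introns$end[k]
      if (e - s <= L) {
        parts[[length(parts) + 1L]] <- tibble::tibble(
          intron = k, side = "all", start = s, end = e
        )
      } else if (half > 0L) {
        left_side <- if (layout$strand == "+") "5p" else "3p"
        right_side <- if (layout$strand == "+") "3p" else "5p"
        parts[[length(parts) + 1L]] <- tibble::tibble(
          intron = c(k, k), side = c(left_side, right_side),
          start = c(s, e - half), end = c(s + half, e)
        )
      }
    }
  }
  parts <- if (length(parts)) dplyr::bind_rows(parts) else
    tibble::tibble(intron = integer(), side = character(),
                   start = integer(), end = integer())

  pieces <- dplyr::bind_rows(
    tibble::tibble(
      start = layout$exons$start, end = layout$exons$end,
      region = paste0("exon", seq_len(nrow(layout$exons))),
      label = paste0("exon", seq_len(nrow(layout$exons)))
    ),
    tibble::tibble(
      start = as.integer(parts$start), end = as.integer(parts$end),
      region = paste0("intron", parts$intron),
      label = paste0("intron", parts$intron,
                     ifelse(parts$side == "all", "", paste0("_", parts$side)))
    )
  )
  pieces <- dplyr::arrange(pieces, .data$start)
  layout$L <- L
  layout$included_intron_parts <- parts
  layout$column_map <- unlist(Map(seq.int, pieces$start, pieces$end - 1L),
                              use.names = FALSE)
  layout$region_labels <- rep(pieces$label, pieces$end - pieces$start)
  layout$region_ids <- rep(pieces$region, pieces$end - pieces$start)
  stopifnot(!is.unsorted(layout$column_map, strictly = TRUE))
  layout
}

#' Build a complete gene layout in one call
#'
#' Convenience wrapper: interval union, threshold selection, intron inclusion.
#' @inheritParams build_union_gene_model
#' @inheritParams apply_intron_inclusion
#' @export
build_gene_model <- function(transcripts, gene_id = "gene", chrom = "chr1",
                             strand = "+", L = NULL) {
  apply_intron_inclusion(
    build_union_gene_model(transcripts, gene_id, chrom, strand), L = L
  )
}

#' Map genomic positions to matrix columns and back
#'
#' `genomic_to_column()` returns the matrix row index of each genomic position
#' (`NA` for positions outside the included layout); `column_to_genomic()` is
#' its inverse on included positions.
#' @param layout a `gene_layout` with intron inclusion applied.
#' @param pos genomic positions (0-based).
#' @param column matrix row indices in `1..d`.
#' @export
genomic_to_column <- function(layout, pos) {
  stopifnot(!is.null(layout$column_map))
  match(pos, layout$column_map)
}

#' @rdname genomic_to_column
#' @export
column_to_genomic <- function(layout, column) {
  stopifnot(!is.null(layout$column_map))
  layout$column_map[column]
}

#' Per-column layout table
#'
#' @param layout a `gene_layout` with intron inclusion applied.
#' @return tibble with one row per matrix column: `column`, genomic `pos`,
#'   side-annotated `label` and basis `region`.
#' @export
layout_columns <- function(layout) {
  stopifnot(!is.null(layout$column_map))
  tibble::tibble(
    column = seq_along(layout$column_map),
    pos = layout$column_map,
    label = layout$region_labels,
    region = layout$region_ids
  )
}

#' Basis region summary
#'
#' One row per exon / included intron, with its column support.
#' @param layout a `gene_layout` with intron inclusion applied.
#' @return tibble with `region`, `type`, `n_columns`, and the 5'-to-3' rank
#'   of the region in transcript orientation (`rank5p`).
#' @export
layout_regions <- function(layout) {
  cols <- layout_columns(layout)
  out <- dplyr::summarise(
    dplyr::group_by(cols, .data$region),
    type = ifelse(startsWith(.data$region[1], "exon"), "exon", "intron"),
    n_columns = dplyr::n(),
    first_column = min(.data$column),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$first_column)
  out$rank5p <- if (layout$strand == "+") seq_len(nrow(out)) else rev(seq_len(nrow(out)))
  out
}
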