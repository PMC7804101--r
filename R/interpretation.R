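#' Summarise a most outlying direction by layout region
#'
#' Decomposes a unit direction into per-region signed shares of its squared
#' mass. The sign is the direction of coverage change for the flagged sample
#' (directions returned by the detectors are already oriented toward the
#' sample's deviation). `support_frac` measures how uniformly the direction
#' covers the region: `(sum |u_i|)^2 / (len * sum u_i^2)` over the region's
#' columns — 1 for a constant (whole-region) direction, ~`k/len` for a
#' direction concentrated on `k` columns.
#'
#' @param mod length-`d` direction vector (oriented).
#' @param layout the matching `gene_layout`.
#' @return tibble with one row per basis region: `region`, `type`, `rank5p`,
#'   signed `share`, unsigned `mass`, `support_frac`, `n_columns`.
#' @export
summarize_mod <- function(mod, layout) {
  cols <- layout_columns(layout)
  regions <- layout_regions(layout)
  tot <- sum(mod^2)
  if (tot <= 0) stop("most outlying direction is identically zero")
  out <- lapply(seq_len(nrow(regions)), function(k) {
    sup <- cols$column[cols$region == regions$region[k]]
    u <- mod[sup]
    mass <- sum(u^2) / tot
    sgn <- sign(sum(u))
    sf <- if (sum(u^2) > 0) sum(abs(u))^2 / (length(u) * sum(u^2)) else 0
    tibble::tibble(
      region = regions$region[k], type = regions$type[k],
      rank5p = regions$rank5p[k],
      share = ifelse(sgn == 0, mass, sgn * mass), mass = mass,
      support_frac = sf, n_columns = length(u)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$rank5p)
}

#' Type a shape-change call from its region summary and junction evidence
#'
#' Deterministic rule cascade over the signed region shares of the most
#' outlying direction (regions with squared-mass share below `min_mass` are
#' ignored; `full` means `support_frac >= 0.5`, i.e. the direction covers the
#' region broadly rather than a sub-interval):
#'
#' 1. loss on one or more full internal exons (never the 5'- or 3'-most) ->
#'    `exon_skipping`; a partial-exon loss with junction support ->
#'    `cryptic_exon_skipping`;
#' 2. gain on intron(s) -> `intron_retention` (partial -> `cryptic_intron_retention`);
#' 3. loss of whole regions confined to a 5' prefix of the layout
#'    (transcript orientation) -> `ATS`; to a 3' suffix -> `ATT`;
#' 4. sub-exonic loss without junction support -> `deletion`
#'    (`small_deletion` when the effective width is < `small_bp`);
#' 5. a common sign across all informative regions -> `overexpression` /
#'    `underexpression`;
#' otherwise `unclassified`.
#'
#' @param mod_regions region summary from [summarize_mod()].
#' @param junction_support logical: does the flagged sample carry novel
#'   junction reads (>= 2) spanning the dominant loss region?
#' @param strand gene strand (orientation is already encoded in `rank5p`;
#'   kept for interface completeness).
#' @param min_mass region squared-mass share below which a region is ignored.
#' @param full_support `support_frac` at or above which a region counts as
#'   fully covered.
#' @param small_bp effective width below which a deletion is "small".
#' @return event type string.
#' @export
classify_event <- function(mod_regions, junction_support = FALSE, strand = "+",
                           min_mass = 0.1, full_support = 0.6, small_bp = 100) {
  stopifnot(nrow(mod_regions) > 0L)
  mr <- dplyr::arrange(mod_regions, .data$rank5p)
  dom <- mr[mr$mass >= min_mass, , drop = FALSE]
  if (nrow(dom) == 0L) dom <- mr[which.max(mr$mass), , drop = FALSE]

  exons <- mr[mr$type == "exon", ]
  first_exon <- exons$region[which.min(exons$rank5p)]
  last_exon <- exons$region[which.max(exons$rank5p)]

  neg <- dom[dom$share < 0, , drop = FALSE]
  pos <- dom[dom$share > 0, , drop = FALSE]
  neg_exons <- neg[neg$type == "exon", , drop = FALSE]
  pos_introns <- pos[pos$type == "intron", , drop = FALSE]

  # 1. exon skipping: loss on internal exon(s) only
  if (nrow(neg_exons) > 0L &&
      !any(neg_exons$region %in% c(first_exon, last_exon))) {
    full <- neg_exons$support_frac >= full_support
    if (all(full)) return("exon_skipping")
    if (junction_support) return("cryptic_exon_skipping")
    # partial internal-exon loss without junctions falls through to deletion
  }

  # 2. intron retention: gain on intron(s) dominates while exons stay normal
  if (nrow(pos_introns) > 0L &&
      sum(pos_introns$mass) >= sum(pos$mass) * 0.5 &&
      sum(pos$mass) >= sum(dom$mass) * 0.5 &&
      sum(pos$mass[pos$type == "exon"]) <= 0.5 * sum(pos_introns$mass)) {
    if (all(pos_introns$support_frac >= full_support)) return("intron_retention")
    return("cryptic_intron_retention")
  }

  # 3. ATS / ATT: loss of whole regions confined to a strict 5' prefix
  # (or 3' suffix) of the layout, the rest of the gene staying expressed.
  # The silenced exons must be lost wholesale: a sub-exonic dip in a
  # terminal exon is a deletion, not an alternative start.
  if (nrow(neg_exons) > 0L &&
      all(neg_exons$support_frac >= full_support)) {
    neg_max <- max(neg$rank5p); neg_min <- min(neg$rank5p)
    ranks_all <- range(mr$rank5p)
    # regions inside the candidate lost block are negative or negligible
    block_ok <- function(lo, hi) {
      inside <- mr[mr$rank5p >= lo & mr$rank5p <= hi, , drop = FALSE]
      all(inside$share < 0 | inside$mass < min_mass)
    }
    # no dominantly lost exon beyond the block (that would be a gene-wide
    # loss, not an alternative start/termination)
    beyond_ok <- function(lo, hi) {
      outside <- mr[mr$rank5p < lo | mr$rank5p > hi, , drop = FALSE]
      nrow(outside) > 0L &&
        !any(outside$type == "exon" & outside$share < 0 &
               outside$mass >= min_mass)
    }
    if (neg_min == ranks_all[1] && neg_max < ranks_all[2] &&
        block_ok(ranks_all[1], neg_max) && beyond_ok(ranks_all[1], neg_max)) {
      return("ATS")
    }
    if (neg_max == ranks_all[2] && neg_min > ranks_all[1] &&
        block_ok(neg_min, ranks_all[2]) && beyond_ok(neg_min, ranks_all[2])) {
      return("ATT")
    }
  }

  # 4. sub-exonic loss, no junction evidence: deletion
  if (nrow(neg_exons) > 0L && !junction_support &&
      all(neg_exons$support_frac < full_support)) {
    eff_width <- sum(neg_exons$support_frac * neg_exons$n_columns)
    return(if (eff_width < small_bp) "small_deletion" else "deletion")
  }

  # 5. uniform sign across informative regions
  informative <- mr[mr$mass >= 0.02, , drop = FALSE]
  if (nrow(informative) >= 2L) {
    if (all(informative$share > 0)) return("overexpression")
    if (all(informative$share < 0)) return("underexpression")
  }

  "unclassified"
}

#' Interpret detection results into typed outlier calls
#'
#' Combines global and local detection results with the sample junction table
#' into one tidy table of typed calls. Junction support for a call means the
#' flagged sample has at least `min_junction_reads` reads on a junction whose
#' skipped interval overlaps the call's dominant loss region.
#'
#' A global call is typed from the flagged sample's own oriented latent
#' deviation profile (its latent column minus the per-position cohort
#' median) rather than from the single bank direction achieving its maximum:
#' the deviation profile is the full-resolution realisation of the "linear
#' combination of bases" that describes the sample's abnormality, and its
#' per-region concentration is what distinguishes a sub-exonic deletion from
#' a whole-exon loss. Local calls are typed from their window direction.
#'
#' @param coverage the [coverage_matrix()] that was analysed (provides
#'   junctions and the layout).
#' @param global a `global_result` (or `NULL`).
#' @param local a `local_result` (or `NULL`).
#' @param X the normalised latent matrix the detectors ran on; required for
#'   deviation-profile typing of global calls (falls back to the bank MOD
#'   when `NULL`).
#' @param min_junction_reads junction read support threshold.
#' @return tibble of class `outlier_calls`: one row per call with `sample_id`,
#'   `gene_id`, `step`, `score`, `df`, `p_value`, `event_type`, `top_region`,
#'   `junction_support`; the per-call MOD vectors are attached as the
#'   `"mod"` attribute (a named list).
#' @export
interpret_calls <- function(coverage, global = NULL, local = NULL, X = NULL,
                            min_junction_reads = 2L) {
  layout <- coverage$layout
  jx <- coverage$junctions
  rows <- list()
  mods <- list()
  med_profile <- if (!is.null(X)) apply(X, 1L, median) else NULL

  add_call <- function(sample_id, step, score, df, mod) {
    ms <- summarize_mod(mod, layout)
    jsup <- has_junction_support(jx, layout, ms, sample_id, min_junction_reads)
    ev <- classify_event(ms, junction_support = jsup, strand = layout$strand)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, gene_id = layout$gene_id, step = step,
      score = score, df = df,
      p_value = max(pchisq(score^2, df = df, lower.tail = FALSE),
                    .Machine$double.xmin),
      event_type = ev,
      top_region = ms$region[which.max(ms$mass)],
      junction_support = jsup
    )
    mods[[paste(sample_id, step, sep = ":")]] <<- mod
  }

  if (!is.null(global) && length(global$calls)) {
    for (j in global$calls) {
      typing_vec <- if (!is.null(med_profile)) {
        dev <- X[, j] - med_profile
        if (sum(dev^2) > 0) unit_vector(dev) else global$MOD[, j]
      } else {
        global$MOD[, j]
      }
      add_call(global$sample_ids[j], "global", global$GO[j], global$df,
               typing_vec)
    }
  }
  if (!is.null(local) && length(local$calls)) {
    for (i in seq_along(local$calls_local)) {
      jl <- local$calls_local[i]
      add_call(local$sample_ids[jl], "local", local$LO[jl], local$df,
               local$MOD[, jl])
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    sample_id = character(), gene_id = character(), step = character(),
    score = numeric(), df = integer(), p_value = numeric(),
    event_type = character(), top_region = character(),
    junction_support = logical()
  )
  attr(out, "mod") <- mods
  class(out) <- c("outlier_calls", class(out))
  out
}

has_junction_support <- function(jx, layout, mod_regions, sample_id,
                                 min_junction_reads = 2L) {
  if (is.null(jx) || nrow(jx) == 0L) return(FALSE)
  jx <- jx[jx$sample_id == sample_id & jx$count >= min_junction_reads, ,
           drop = FALSE]
  if (nrow(jx) == 0L) return(FALSE)
  loss <- mod_regions[mod_regions$share < 0 & mod_regions$mass >= 0.1, ,
                      drop = FALSE]
  if (nrow(loss) == 0L) return(FALSE)
  cols <- layout_columns(layout)
  for (r in loss$region) {
    pos <- cols$pos[cols$region == r]
    lo <- min(pos); hi <- max(pos)
    if (any(jx$donor <= lo & jx$acceptor >= hi + 1L)) return(TRUE)
  }
  FALSE
}

#' Write typed outlier calls
#'
#' `write_calls_tsv()` writes the tidy call table; `write_calls_json()` writes
#' per-call JSON records including the region decomposition of each MOD.
#' @param calls an `outlier_calls` table from [interpret_calls()].
#' @param path output path.
#' @param layout layout used for the JSON region decomposition.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_json <- function(calls, layout, path) {
  mods <- attr(calls, "mod")
  recs <- lapply(seq_len(nrow(calls)), function(i) {
    key <- paste(calls$sample_id[i], calls$step[i], sep = ":")
    c(as.list(calls[i, ]),
      list(mod_regions = summarize_mod(mods[[key]], layout)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
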