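#' Default toy gene layout for simulations
#'
#' Four exons separated by three introns, with the intron-inclusion threshold
#' balanced automatically — geometry in the range of a compact human gene.
#'
#' @param exon_lengths,intron_lengths region lengths in bp.
#' @param strand gene strand.
#' @export
toy_layout <- function(exon_lengths = c(300L, 250L, 350L, 200L),
                       intron_lengths = c(500L, 800L, 600L),
                       strand = "+") {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L)
  starts <- integer(length(exon_lengths))
  pos <- 1000L
  ex <- matrix(0L, nrow = length(exon_lengths), ncol = 2L)
  for (k in seq_along(exon_lengths)) {
    ex[k, ] <- c(pos, pos + exon_lengths[k])
    pos <- pos + exon_lengths[k] +
      if (k < length(exon_lengths)) intron_lengths[k] else 0L
  }
  build_gene_model(list(ex), gene_id = "toy", chrom = "chr1", strand = strand)
}

#' Specification of a synthetic coverage cohort
#'
#' Defines the cohort generated by [simulate_cohort()] under the multiplicative
#' coverage model: `R_ij = max(0, round(exp(a_j * mu_i + g(a_j) * x_ij) - c))`
#' with baseline log profile `mu`, per-sample depth factor `a_j`, nonlinear
#' scale curve `g` (`g(1) = 1`) and latent noise `x`. Events are injected
#' coherently on the count scale (an exon skip reduces exon depth by the skip
#' fraction and emits matching junction reads; intron retention raises intron
#' depth with no junctions; an alternative transcription start silences the
#' upstream exons and adds signal at the start of the preceding intron), and
#' 3'-biased degradation tilts the log profile linearly along the transcript.
#'
#' @param layout a `gene_layout` (default [toy_layout()]).
#' @param n cohort size.
#' @param depth_exon,depth_intron baseline read depth on exons / included introns.
#' @param sd_a standard deviation of the depth factor `a_j` around 1.
#' @param g nonlinear scale curve (vectorised, `g(1) = 1`).
#' @param sigma_x latent noise standard deviation.
#' @param noise `"gaussian"` (default) or `"t"` (df 5, rescaled to unit
#'   variance) for the latent noise law.
#' @param c pseudo-count of the generative transform.
#' @param events list of event descriptors: each a list with `type` in
#'   `exon_skipping`, `intron_retention`, `deletion`, `ATS`, `ATT`,
#'   `overexpression`; `region` (a region id such as `"exon2"`, or a genomic
#'   `c(start, end)` for deletions); `frac` effect size in `(0, 1]` (count
#'   multiplier for overexpression); and either explicit `samples` indices or
#'   an outlier proportion `w` in `[0, 0.5)`.
#' @param degradation `NULL` or list with `samples` (indices or proportion `w`)
#'   and `beta` (decay slope in log-coverage per unit of transcript fraction).
#' @param seed RNG seed; a fixed seed makes the generated cohort byte-identical.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(layout = toy_layout(), n = 100L,
                            depth_exon = 50, depth_intron = 2, sd_a = 0.1,
                            g = function(a) pmax(a, 0.1)^0.7,
                            sigma_x = 0.2, noise = c("gaussian", "t"),
                            c = 1, events = list(), degradation = NULL,
                            seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(layout, "gene_layout"), !is.null(layout$column_map),
            n >= 4L, depth_exon > 0, depth_intron >= 0, sd_a >= 0,
            sigma_x >= 0, c > 0, abs(g(1) - 1) < 1e-8)
  for (ev in events) {
    stopifnot(is.list(ev), !is.null(ev$type))
    if (!ev$type %in% c("exon_skipping", "intron_retention", "deletion",
                        "ATS", "ATT", "overexpression")) {
      stop("unknown event type: ", ev$type)
    }
    if (!is.null(ev$w)) stopifnot(ev$w >= 0, ev$w < 0.5)
    if (ev$type != "overexpression") {
      resolve_event_columns(layout, ev$region) # errors if outside the layout
    }
  }
  structure(
    list(layout = layout, n = as.integer(n), depth_exon = depth_exon,
         depth_intron = depth_intron, sd_a = sd_a, g = g, sigma_x = sigma_x,
         noise = noise, c = c, events = events, degradation = degradation,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

resolve_event_columns <- function(layout, region) {
  cols <- layout_columns(layout)
  if (is.character(region)) {
    idx <- cols$column[cols$region == region]
    if (length(idx) == 0L) stop("event region '", region, "' not in the layout")
    return(idx)
  }
  region <- as.numeric(region)
  stopifnot(length(region) == 2L, region[1] < region[2])
  idx <- cols$column[cols$pos >= region[1] & cols$pos < region[2]]
  if (length(idx) == 0L) {
    stop("event region [", region[1], ",", region[2], ") has no layout columns")
  }
  idx
}

pick_event_samples <- function(ev, n) {
  if (!is.null(ev$samples)) return(as.integer(ev$samples))
  w <- ev$w %||% 0.03
  if (w == 0) return(integer())
  sample.int(n, max(1L, round(w * n)))
}

#' Simulate a coverage cohort with injected events and truth labels
#'
#' @param spec a [simulation_spec()].
#' @return object of class `synthetic_cohort`: list with `coverage` (a
#'   [coverage_matrix()] including the junction table), `truth` (tibble of
#'   `sample_id`, `event_type`, `region`, `frac`), `a` (true depth factors)
#'   and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  layout <- spec$layout
  cols <- layout_columns(layout)
  d <- nrow(cols)
  n <- spec$n
  ids <- sprintf("s%03d", seq_len(n))

  is_exon <- startsWith(cols$region, "exon")
  mu <- ifelse(is_exon, log(spec$depth_exon + spec$c),
               log(spec$depth_intron + spec$c))
  # mild fixed per-position texture so the baseline is not exactly piecewise flat
  mu <- mu + rnorm(d, 0, 0.03)

  a <- pmax(rnorm(n, 1, spec$sd_a), 0.2)
  x <- if (spec$noise == "gaussian") {
    matrix(rnorm(d * n, 0, spec$sigma_x), d, n)
  } else {
    matrix(stats::rt(d * n, df = 5) / sqrt(5 / 3) * spec$sigma_x, d, n)
  }

  log_lambda <- outer(mu, a) + sweep(x, 2L, spec$g(a), "*")

  if (!is.null(spec$degradation)) {
    deg <- spec$degradation
    ds <- if (!is.null(deg$samples)) {
      as.integer(deg$samples)
    } else {
      sample.int(n, max(1L, round((deg$w %||% 0.1) * n)))
    }
    t5 <- seq_len(d) / d
    if (layout$strand == "-") t5 <- rev(t5)
    log_lambda[, ds] <- log_lambda[, ds] + deg$beta * (t5 - mean(t5))
  } else {
    ds <- integer()
  }

  R <- pmax(round(exp(log_lambda) - spec$c), 0)

  truth <- list()
  junctions <- list()
  if (length(ds)) {
    truth[[length(truth) + 1L]] <- tibble::tibble(
      sample_id = ids[ds], event_type = "degradation", region = "gene",
      frac = spec$degradation$beta
    )
  }

  regions <- layout_regions(layout)
  exon_regions <- regions$region[regions$type == "exon"]

  for (ev in spec$events) {
    samples <- pick_event_samples(ev, n)
    if (length(samples) == 0L) next
    frac <- ev$frac %||% 0.5
    if (ev$type == "overexpression") {
      R[, samples] <- round(R[, samples, drop = FALSE] * frac)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = ids[samples], event_type = ev$type, region = "gene",
        frac = frac
      )
      next
    }
    idx <- resolve_event_columns(layout, ev$region)
    for (s in samples) {
      if (ev$type == "exon_skipping") {
        stopifnot(is.character(ev$region), ev$region %in% exon_regions)
        k <- match(ev$region, exon_regions)
        if (k == 1L || k == length(exon_regions)) {
          stop("exon_skipping requires an internal exon")
        }
        flank_cols <- cols$column[cols$region %in% exon_regions[c(k - 1L, k + 1L)]]
        flank_depth <- mean(R[flank_cols, s])
        R[idx, s] <- round(R[idx, s] * (1 - frac))
        donor <- layout$exons$end[k - 1L]
        acceptor <- layout$exons$start[k + 1L]
        junctions[[length(junctions) + 1L]] <- tibble::tibble(
          donor = donor, acceptor = acceptor, sample_id = ids[s],
          count = as.integer(round(frac * flank_depth))
        )
      } else if (ev$type == "intron_retention") {
        k <- as.integer(sub("intron", "", ev$region))
        flank_cols <- cols$column[cols$region %in% exon_regions[c(k, k + 1L)]]
        add <- round(frac * mean(R[flank_cols, s]))
        R[idx, s] <- R[idx, s] + add
      } else if (ev$type == "deletion") {
        R[idx, s] <- round(R[idx, s] * (1 - frac))
      } else if (ev$type %in% c("ATS", "ATT")) {
        stopifnot(is.character(ev$region), ev$region %in% exon_regions)
        k <- match(ev$region, exon_regions)
        silence_5p <- ev$type == "ATS"
        ranks <- regions$rank5p[match(exon_regions, regions$region)]
        kr <- ranks[k]
        silenced_exons <- exon_regions[if (silence_5p) ranks < kr else ranks > kr]
        if (length(silenced_exons) == 0L) {
          stop(ev$type, " requires at least one exon to silence")
        }
        sil_cols <- cols$column[cols$region %in% silenced_exons]
        R[sil_cols, s] <- round(R[sil_cols, s] * 0.02)
        # silence the intervening introns too, and add run-in signal in the
        # intron flank abutting the new terminal exon
        ev_cols <- cols$column[cols$region == ev$region]
        boundary <- if (silence_5p == (layout$strand == "+")) min(ev_cols) else max(ev_cols)
        gene_dir <- if (silence_5p == (layout$strand == "+")) -1L else 1L
        intron_cols <- cols$column[!is_exon]
        sil_introns <- intron_cols[if (gene_dir < 0) intron_cols < boundary - 300L
                                   else intron_cols > boundary + 300L]
        R[sil_introns, s] <- round(R[sil_introns, s] * 0.02)
        runin <- intron_cols[if (gene_dir < 0) {
          intron_cols >= boundary - 300L & intron_cols < boundary
        } else {
          intron_cols <= boundary + 300L & intron_cols > boundary
        }]
        if (length(runin)) {
          R[runin, s] <- round(frac * mean(R[ev_cols, s]))
        }
      }
    }
    truth[[length(truth) + 1L]] <- tibble::tibble(
      sample_id = ids[samples], event_type = ev$type,
      region = if (is.character(ev$region)) ev$region else
        paste0(ev$region, collapse = "-"),
      frac = frac
    )
  }

  jx <- if (length(junctions)) dplyr::bind_rows(junctions) else NULL
  cov <- coverage_matrix(R, ids, layout, junctions = jx)
  structure(
    list(coverage = cov,
         truth = if (length(truth)) dplyr::bind_rows(truth) else
           tibble::tibble(sample_id = character(), event_type = character(),
                          region = character(), frac = numeric()),
         a = a, spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d x %d, %d truth record(s), seed %d\n",
              nrow(x$coverage$R), ncol(x$coverage$R), nrow(x$truth),
              x$spec$seed))
  invisible(x)
}
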