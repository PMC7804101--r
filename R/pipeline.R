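#' Pipeline configuration
#'
#' Collects the tunable parameters of the per-gene and cohort pipelines with
#' their defaults: per-sample significance level `alpha = 1e-4`, normality
#' cutoff `rho = 3`, window sizes 50/100/200 bp, a 20-point logarithmic
#' log-shift grid over `[0.01, 100]`, 10% trimming per tail, on/off angle
#' cutoff 60 degrees, and a minimum recommended cohort size of 30.
#'
#' @param alpha per-sample significance level.
#' @param rho normality-screen cutoff.
#' @param window_sizes local-detection window sizes (bp).
#' @param shift_grid candidate pseudo-counts for the log-shift search.
#' @param shift fixed pseudo-count; `NULL` selects it per gene from the grid.
#' @param trim trimmed-mean fraction per tail.
#' @param theta_star on/off angle cutoff (degrees).
#' @param margin degradation-cluster separation margin (pooled-MAD units).
#' @param n_random random directions in the global bank.
#' @param min_n cohort-size warning threshold.
#' @param seed integer seed driving every stochastic choice.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alpha = 1e-4, rho = 3, window_sizes = c(50L, 100L, 200L),
                        shift_grid = log_grid(), shift = NULL, trim = 0.1,
                        theta_star = 60, margin = 2, n_random = 100L,
                        min_n = 30L, seed = 1L) {
  cfg <- list(alpha = alpha, rho = rho, window_sizes = window_sizes,
              shift_grid = shift_grid, shift = shift, trim = trim,
              theta_star = theta_star, margin = margin, n_random = n_random,
              min_n = min_n, seed = as.integer(seed))
  stopifnot(alpha > 0, alpha < 1, rho > 0, all(window_sizes > 0), trim >= 0,
            theta_star > 0, margin > 0, min_n > 0)
  structure(cfg, class = "scan_config")
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                    character(1)), collapse = ";")
  # small stable FNV-1a style hash (32-bit arithmetic split to stay exact in
  # doubles); provenance marker only
  mul32 <- function(a, b) {
    ((a %/% 65536 * b) %% 65536 * 65536 + (a %% 65536) * b) %% 4294967296
  }
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- mul32(bitwXor(as.integer(h %% 2147483648), ch) +
                 (if (h >= 2147483648) 2147483648 else 0), 16777619)
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the shape-change pipeline on one gene
#'
#' Pipeline order: transform and normalise (log-shift selection, mean scale
#' correction), global detection on the exon/intron basis, local detection on
#' the residuals of the remaining samples with window and junction-derived
#' directions, then event typing of every call.
#'
#' @param coverage a [coverage_matrix()] for the gene.
#' @param config a [scan_config()].
#' @return object of class `gene_scan`: list with `normalization`, `global`,
#'   `local`, `calls` (typed [interpret_calls()] table), `config_hash`.
#' @export
run_gene <- function(coverage, config = scan_config()) {
  stopifnot(inherits(coverage, "coverage_matrix"))
  layout <- coverage$layout
  n <- ncol(coverage$R)
  if (n < config$min_n) {
    warning("cohort size ", n, " is below the recommended minimum of ",
            config$min_n, "; proceeding")
  }
  c_sel <- config$shift %||% select_log_shift(coverage$R, grid = config$shift_grid,
                                              trim = config$trim)$c
  norm <- fit_mean_scale_correction(coverage, c = c_sel, trim = config$trim,
                                    min_n = 1L)
  norm$sample_ids <- coverage$sample_ids
  colnames(norm$X) <- coverage$sample_ids

  global <- detect_global(norm$X, layout, alpha = config$alpha,
                          rho = config$rho, n_random = config$n_random,
                          seed = config$seed)

  basis <- global$basis
  retained <- setdiff(seq_len(n), global$calls)
  resid <- compute_residuals(norm$X, basis)[, retained, drop = FALSE]
  bank <- build_window_bank(layout, junctions = coverage$junctions,
                            sizes = config$window_sizes)
  local <- detect_local(resid, bank, alpha = config$alpha, rho = config$rho,
                        retained = retained)

  calls <- interpret_calls(coverage, global = global, local = local,
                           X = norm$X)
  structure(
    list(gene_id = layout$gene_id, normalization = norm, global = global,
         local = local, calls = calls, config = config,
         config_hash = config_hash(config)),
    class = "gene_scan"
  )
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf("<gene_scan> %s: %d global + %d local call(s) [config %s]\n",
              x$gene_id, length(x$global$calls), length(x$local$calls),
              x$config_hash))
  invisible(x)
}

#' @describeIn run_gene per-sample scores from both steps, one row per
#'   sample and step.
#' @param x a `gene_scan`.
#' @param ... unused.
#' @export
tidy.gene_scan <- function(x, ...) {
  out <- dplyr::bind_rows(tidy(x$global), tidy(x$local))
  out$gene_id <- x$gene_id
  dplyr::relocate(out, "gene_id")
}

#' @describeIn run_gene one-row gene summary.
#' @export
glance.gene_scan <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, n = length(x$global$GO), K = x$global$K,
    df_global = x$global$df, df_local = x$local$df,
    n_global_calls = length(x$global$calls),
    n_local_calls = length(x$local$calls),
    shift = x$normalization$c, config_hash = x$config_hash
  )
}

#' Run the pipeline across a cohort of genes
#'
#' Applies the quality-control filters first — degraded samples are removed
#' from every gene, on/off genes are excluded — then runs [run_gene()] on each
#' retained gene. Genes are independent units; the outputs are identical to
#' serial execution by construction.
#'
#' @param coverages named list of [coverage_matrix()] objects.
#' @param config a [scan_config()].
#' @return object of class `cohort_scan`: list with `qc` ([qc_report()]),
#'   `genes` (list of `gene_scan`), `calls` (combined table), `scores`
#'   (gene x sample global-score matrix for prioritisation), `log` (tibble of
#'   per-gene processing records).
#' @export
run_cohort <- function(coverages, config = scan_config()) {
  stopifnot(length(coverages) >= 1L)
  gene_ids <- names(coverages) %||%
    vapply(coverages, function(x) x$layout$gene_id, character(1))
  stopifnot(!anyDuplicated(gene_ids))
  qc <- qc_report(coverages, margin = config$margin,
                  theta_star = config$theta_star)
  keep_samples <- setdiff(coverages[[1]]$sample_ids, qc$degraded)
  log_rows <- list()
  scans <- list()
  for (g in seq_along(coverages)) {
    cov <- coverages[[g]]
    gid <- gene_ids[g]
    if (qc$genes$excluded[g]) {
      log_rows[[g]] <- tibble::tibble(
        gene_id = gid, status = "excluded_onoff",
        off_fraction = qc$genes$off_fraction[g],
        n_samples = NA_integer_, n_global = NA_integer_, n_local = NA_integer_
      )
      next
    }
    idx <- match(keep_samples, cov$sample_ids)
    sub <- coverage_matrix(cov$R[, idx, drop = FALSE], keep_samples, cov$layout,
                           junctions = cov$junctions[cov$junctions$sample_id %in%
                                                       keep_samples, , drop = FALSE])
    scan <- run_gene(sub, config)
    scans[[gid]] <- scan
    log_rows[[g]] <- tibble::tibble(
      gene_id = gid, status = "analysed",
      off_fraction = qc$genes$off_fraction[g],
      n_samples = length(keep_samples),
      n_global = length(scan$global$calls), n_local = length(scan$local$calls)
    )
  }
  calls <- if (length(scans)) {
    dplyr::bind_rows(lapply(scans, function(s) tibble::as_tibble(s$calls)))
  } else tibble::tibble()
  scores <- if (length(scans)) {
    do.call(rbind, lapply(scans, function(s) setNames(s$global$GO, s$global$sample_ids)))
  } else NULL
  structure(
    list(qc = qc, genes = scans, calls = calls, scores = scores,
         log = dplyr::bind_rows(log_rows), config = config,
         config_hash = config_hash(config)),
    class = "cohort_scan"
  )
}

#' @export
print.cohort_scan <- function(x, ...) {
  cat(sprintf("<cohort_scan> %d gene(s) analysed, %d excluded; %d degraded sample(s) removed; %d call(s) [config %s]\n",
              length(x$genes), sum(x$log$status != "analysed"),
              length(x$qc$degraded), nrow(x$calls), x$config_hash))
  invisible(x)
}

#' @describeIn run_cohort combined typed calls across genes.
#' @param x a `cohort_scan`.
#' @param ... unused.
#' @export
tidy.cohort_scan <- function(x, ...) x$calls

#' @describeIn run_cohort one-row cohort summary.
#' @export
glance.cohort_scan <- function(x, ...) {
  tibble::tibble(
    n_genes_in = nrow(x$log), n_genes_analysed = length(x$genes),
    n_degraded = length(x$qc$degraded), n_calls = nrow(x$calls),
    config_hash = x$config_hash
  )
}
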