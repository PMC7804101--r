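# Shared fixtures, built in code at test time.

# Small two-exon layout with one fully included intron.
small_layout <- function(L = NULL) {
  build_gene_model(list(cbind(c(100, 400), c(300, 600))), gene_id = "g1",
                   L = L %||% 200L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic coverage matrix on a layout: given per-region depths.
flat_coverage <- function(layout, depths, n = 6, jitter = 0) {
  cols <- layout_columns(layout)
  base <- depths[cols$region]
  R <- matrix(rep(base, n), ncol = n)
  if (jitter > 0) {
    R <- R + matrix(rpois(length(R), jitter), nrow = nrow(R))
  }
  coverage_matrix(R, sprintf("s%02d", seq_len(n)), layout)
}

# Model-exact count-free matrix: R_ij = exp(a_j * mu_i) - c (real-valued).
model_exact_matrix <- function(mu_log, a, c) {
  R <- exp(outer(mu_log, a)) - c
  stopifnot(all(R >= 0))
  R
}

# Reads tibble for the SAM/BAM fixture writer.
fixture_reads <- function(pos, cigar) {
  tibble::tibble(qname = sprintf("r%03d", seq_along(pos)), pos = pos,
                 cigar = cigar)
}
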