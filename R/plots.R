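# ggplot2 displays for the main result types.

#' Plot a cohort's coverage profiles
#'
#' Per-base coverage curves over the layout columns, optionally log-scaled,
#' with exon/intron regions shaded and selected samples highlighted.
#'
#' @param object a [coverage_matrix()].
#' @param highlight sample ids drawn in colour on top of the cohort.
#' @param log_scale show `log(depth + 1)`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coverage_matrix <- function(object, highlight = character(),
                                     log_scale = FALSE, ...) {
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(layout_columns(object$layout),
                     tibble::as_tibble(object$R)),
    cols = dplyr::all_of(object$sample_ids),
    names_to = "sample_id", values_to = "depth"
  )
  if (log_scale) df$depth <- log(df$depth + 1)
  regions <- dplyr::summarise(
    dplyr::group_by(layout_columns(object$layout), .data$region),
    xmin = min(.data$column), xmax = max(.data$column),
    type = ifelse(startsWith(.data$region[1], "exon"), "exon", "intron"),
    .groups = "drop"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$depth,
                                        group = .data$sample_id)) +
    ggplot2::geom_rect(
      data = regions[regions$type == "exon", ],
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "grey92", inherit.aes = FALSE
    ) +
    ggplot2::geom_line(colour = "grey55", linewidth = 0.2, alpha = 0.6) +
    ggplot2::labs(x = "layout column", y = if (log_scale) "log(depth + 1)" else "depth",
                  title = object$layout$gene_id) +
    ggplot2::theme_minimal()
  if (length(highlight)) {
    p <- p + ggplot2::geom_line(
      data = df[df$sample_id %in% highlight, ],
      ggplot2::aes(colour = .data$sample_id), linewidth = 0.5
    )
  }
  p
}

score_plot <- function(scores, cutoff, step) {
  df <- tibble::tibble(sample = seq_along(scores), score = scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$score)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = sqrt(cutoff), linetype = 2, colour = "red") +
    ggplot2::labs(x = "sample", y = paste0(step, " outlyingness"),
                  title = paste0(step, " shape-change scores")) +
    ggplot2::theme_minimal()
}

#' Plot global outlyingness scores with the chi-squared cutoff
#'
#' @param object a `global_result`.
#' @param ... unused.
#' @export
autoplot.global_result <- function(object, ...) {
  score_plot(object$GO, object$cutoff, "global")
}

#' Plot local outlyingness scores with the chi-squared cutoff
#'
#' @param object a `local_result`.
#' @param ... unused.
#' @export
autoplot.local_result <- function(object, ...) {
  score_plot(object$LO, object$cutoff, "local")
}

#' Plot a gene scan: scores from both steps
#'
#' @param object a `gene_scan`.
#' @param ... unused.
#' @export
autoplot.gene_scan <- function(object, ...) {
  df <- tidy(object)
  cut <- tibble::tibble(
    step = c("global", "local"),
    cutoff = sqrt(c(object$global$cutoff, object$local$cutoff))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), size = 1) +
    ggplot2::geom_hline(data = cut, ggplot2::aes(yintercept = .data$cutoff),
                        linetype = 2) +
    ggplot2::facet_wrap(~step, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = "outlyingness", title = object$gene_id)
}

#' Plot a most outlying direction over the gene layout
#'
#' @param scan a `gene_scan`.
#' @param sample_id flagged sample.
#' @param step `"global"` or `"local"`.
#' @return a ggplot object.
#' @export
plot_mod <- function(scan, sample_id, step = c("global", "local")) {
  step <- match.arg(step)
  res <- if (step == "global") scan$global else scan$local
  j <- match(sample_id, res$sample_ids)
  if (is.na(j)) stop("sample ", sample_id, " not in the ", step, " result")
  df <- tibble::tibble(column = seq_len(nrow(res$MOD)), mod = res$MOD[, j])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$mod)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "layout column", y = "MOD loading",
                  title = sprintf("%s MOD: %s", step, sample_id)) +
    ggplot2::theme_minimal()
}
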