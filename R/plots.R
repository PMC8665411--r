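#' Volcano plot of differential results
#'
#' Log2 fold change (condition b over a) against the negative log10 raw
#' p-value, with the fold and significance cut-offs drawn as reference
#' lines and candidates (per the supplied thresholds and direction)
#' highlighted. Condition-specific features carry no coordinates and are
#' omitted, with a caption noting how many.
#'
#' @param object,x A `diff_results` table.
#' @param config A [quant_config()] supplying the cut-offs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.diff_results <- function(object, config = attr(object, "config"),
                                  ...) {
  config <- config %||% quant_config()
  df <- as_tibble(object) |> filter(!is.na(.data$log2_fc), !is.na(.data$raw_p))
  lfc_cut <- log2(config$fold_threshold)
  sign_ok <- if (config$direction == "increase") df$log2_fc >= lfc_cut else
    df$log2_fc <= -lfc_cut
  df$candidate <- sign_ok & !is.na(df$adj_p) & df$adj_p <= config$alpha &
    pmax(df$detect_reps_a, df$detect_reps_b) >= config$min_detect_reps
  n_spec <- sum(object$specific_flag != "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$raw_p),
                                   colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 name = "candidate") +
    ggplot2::labs(
      x = "log2 fold change (b / a)",
      y = "-log10 raw p-value",
      caption = if (n_spec) sprintf("%d condition-specific feature(s) not shown",
                                    n_spec) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.diff_results
#' @export
plot_volcano <- function(x, config = attr(x, "config"), ...) {
  autoplot.diff_results(x, config = config, ...)
}

#' Heatmap of integrated candidates
#'
#' Tile plot of the [build_heatmap_table()] output: rows are candidate
#' features, columns experiments, fill is the signed log2 fold change, and
#' cell labels carry the significance stars (or "sp." for
#' condition-specific members).
#'
#' @param object A `heatmap_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.heatmap_tbl <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      signed_lfc = dplyr::case_when(
        .data$direction == "specific" ~ NA_real_,
        .data$direction == "decrease" ~ -log2(.data$fold),
        TRUE ~ log2(.data$fold)
      ),
      label = ifelse(.data$is_specific, "sp.", .data$stars)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$row_id,
                                   fill = .data$signed_lfc)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "royalblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey85",
                                  name = "log2 FC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
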