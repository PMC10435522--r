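# ggplot2 views of the main result types.

#' Plot antigenicity profiles
#'
#' @param profiles a single [antigenicity_profile()] or a list of them.
#' @return a ggplot object (score vs window start, threshold dashed).
#' @export
plot_antigenicity <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  df <- bind_rows(lapply(profiles, function(p) {
    tibble(method = attr(p, "method"), position = p$position,
           score = p$score, threshold = attr(p, "threshold"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold), linetype = "dashed") +
    ggplot2::facet_wrap(~method, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window start (mature position)", y = "score") +
    ggplot2::theme_minimal()
}

#' Plot tiling-peptide signals with positivity calls
#'
#' @param calls output of [classify_peptide_binding()].
#' @param background_mean optional background line.
#' @return a ggplot object.
#' @export
plot_peptide_signals <- function(calls, background_mean = NULL) {
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$tile, y = .data$signal,
                                           fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "peptide tile", y = "signal (TRF units)", fill = "positive") +
    ggplot2::theme_minimal()
  if (!is.null(background_mean)) {
    p <- p + ggplot2::geom_hline(yintercept = background_mean, linetype = "dashed")
  }
  p
}

#' Plot display-normalized binding ratios by construct
#'
#' @param ratios tibble with `construct`, `ratio` and optionally
#'   `antibody`.
#' @return a ggplot object.
#' @export
plot_flow_ratios <- function(ratios) {
  p <- ggplot2::ggplot(ratios, ggplot2::aes(x = .data$construct, y = .data$ratio)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "MFI(binding) / MFI(display)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("antibody" %in% names(ratios)) p <- p + ggplot2::facet_wrap(~antibody)
  p
}

#' @describeIn interface_report per-residue buried-area barplot.
#' @param object an `interface_report`.
#' @param ... unused.
#' @export
autoplot.interface_report <- function(object, ...) {
  df <- object$residues %>% filter(.data$dsasa > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$resno), y = .data$dsasa,
                                   fill = .data$core)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue", y = expression(Delta * SASA ~ (ring(A)^2)),
                  fill = "core (>75% buried)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
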