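#' @importFrom ggplot2 autoplot ggplot aes geom_ribbon geom_line geom_point
#'   geom_col facet_wrap labs theme_bw scale_y_log10 geom_text
NULL

#' @export
ggplot2::autoplot

#' Plot a VPC result
#'
#' One panel per stratum: shaded simulation confidence bands per
#' percentile, observed percentile lines on top. Mixture VPCs annotate each
#' panel with the subpopulation's estimated mixing percentage (PMIX) and
#' the percentage of individuals allocated in the original (ORIGID) and
#' simulated (SIMID) data.
#'
#' @param object a `vpc_result`.
#' @param log_y put concentrations on a log axis (default FALSE).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vpc_result
#' @export
autoplot.vpc_result <- function(object, log_y = FALSE, ...) {
  b <- object$bands |>
    mutate(pct = factor(.data$percentile))
  g <- ggplot(b, aes(x = .data$t_mid)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi, group = .data$pct),
                fill = "steelblue", alpha = 0.25) +
    geom_line(aes(y = .data$mid, group = .data$pct),
              colour = "steelblue", linetype = 2, na.rm = TRUE) +
    geom_line(aes(y = .data$obs, group = .data$pct), colour = "black",
              na.rm = TRUE) +
    geom_point(aes(y = .data$obs), size = 0.8, na.rm = TRUE) +
    facet_wrap(~stratum) +
    labs(x = "Time (h)", y = "Concentration (mg/L)",
         title = paste0("VPC (", object$strategy, ")")) +
    theme_bw()
  if (!is.null(object$allocation)) {
    al <- as_tibble(object$allocation) |>
      mutate(stratum = paste0("subpop ", .data$component),
             label = sprintf("PMIX %.1f%%\nORIGID %.1f%%\nSIMID %.1f%%",
                             .data$pmix_pct, .data$origid_pct,
                             .data$simid_pct)) |>
      filter(.data$stratum %in% unique(b$stratum))
    g <- g + geom_text(data = al, aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.05, vjust = 1.1,
                       size = 3, inherit.aes = FALSE)
  }
  if (log_y) g <- g + scale_y_log10()
  g
}

#' Plot the IP_mix separation histogram
#'
#' @param object a `mix_separation` object from [separation_histogram()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mix_separation
#' @export
autoplot.mix_separation <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = (.data$lo + .data$hi) / 2, y = .data$count)) +
    geom_col(width = 0.05, fill = "grey40") +
    labs(x = expression(IP[mix1]), y = "Individuals",
         title = sprintf("Mixture separation (index = %.2f)",
                         attr(object, "separation_index"))) +
    theme_bw()
}

#' @rdname autoplot.vpc_result
#' @param x a `vpc_result`.
#' @param y ignored.
#' @export
plot.vpc_result <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot.mix_separation
#' @param x a `mix_separation`.
#' @param y ignored.
#' @export
plot.mix_separation <- function(x, y, ...) print(autoplot(x, ...))
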