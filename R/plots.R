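#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a meta-profile
#'
#' Line plot of mean mC and hmC per bin across elements (promoter bins or
#' CGI flank bins; bin 0 is the island body for CGI profiles).
#'
#' @param object an `oxbs_profile` from [profile_elements()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oxbs_profile <- function(object, ...) {
  d <- object |>
    tidyr::pivot_longer(c("mc", "hmc"), names_to = "modification",
                        values_to = "level") |>
    mutate(modification = factor(.data$modification, c("mc", "hmc"),
                                 c("5mC", "5hmC")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$level,
                                  colour = .data$modification)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "bin (5' to 3', 0 = element body)",
                  y = "mean level across elements", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a qPCR dilution series and its efficiency fit
#'
#' @param object an `oxbs_efficiency` from [fit_efficiency()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oxbs_efficiency <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = log10(.data$quantity), y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "log10 input quantity",
                  y = "Ct",
                  title = sprintf("Amplification efficiency %.0f%%",
                                  100 * object$efficiency)) +
    ggplot2::theme_minimal()
}

#' Plot per-sample pooled levels by chromosome class
#'
#' @param object an `oxbs_experiment`.
#' @param context `"CG"` or `"CH"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oxbs_experiment <- function(object, context = "CG", ...) {
  d <- object$chrom_summary |>
    filter(.data$context_class == context) |>
    tidyr::pivot_longer(c("mc", "hmc"), names_to = "modification",
                        values_to = "level") |>
    mutate(modification = factor(.data$modification, c("mc", "hmc"),
                                 c("5mC", "5hmC")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom_class, y = .data$level,
                                  colour = .data$sex, shape = .data$age)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::facet_wrap(~modification, scales = "free_y") +
    ggplot2::labs(x = NULL, y = paste0("pooled ", context, " level")) +
    ggplot2::theme_minimal()
}
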