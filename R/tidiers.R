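#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a plectoneme density profile
#'
#' @param x A `plectoneme_profile`.
#' @param ... Unused.
#' @return A plain tibble (one row per base).
#' @export
tidy.plectoneme_profile <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a plectoneme density profile
#'
#' @param x A `plectoneme_profile`.
#' @param ... Unused.
#' @return A one-row tibble: sequence length, defined positions, tension,
#'   parameter set, peak density and its position, and the standard deviation
#'   of the free-energy landscape (kBT).
#' @export
glance.plectoneme_profile <- function(x, ...) {
  d <- x$density[x$defined]
  tibble(n_bp = nrow(x), n_defined = sum(x$defined),
         tension = attr(x, "tension"), params = attr(x, "params_name"),
         circular = isTRUE(attr(x, "circular")),
         max_density = max(d),
         peak_position = x$position[x$defined][which.max(d)],
         sd_free_energy = stats::sd(x$free_energy[x$defined]))
}

#' @rdname tidy.plectoneme_profile
#' @export
tidy.plectoneme_metaprofile <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a TSS meta-profile
#'
#' @param x A `plectoneme_metaprofile`.
#' @param ... Unused.
#' @return A one-row tibble: sites averaged, window, smoothing, peak offset
#'   and height.
#' @export
glance.plectoneme_metaprofile <- function(x, ...) {
  tibble(n_sites = attr(x, "n_sites"),
         halfwidth = attr(x, "halfwidth"),
         smoothing_window = attr(x, "smoothing_window"),
         value = attr(x, "value"),
         peak_offset = x$offset[which.max(x$mean_density)],
         peak_value = max(x$mean_density))
}

#' Plot a plectoneme density profile
#'
#' Line plot of the per-base predicted density (and, if present, the
#' resolution-matched smoothed density).
#'
#' @param object A `plectoneme_profile`.
#' @param value Column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plectoneme_profile <- function(object, value = "density", ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data[[value]])) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
    ggplot2::labs(x = "position (bp)",
                  y = if (value == "free_energy") {
                    expression(-ln ~ W[tot] ~ (k[B] * T))
                  } else {
                    "predicted plectoneme density"
                  }) +
    ggplot2::theme_minimal()
  if (!is.null(df$smoothed_density) && value == "density") {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_density),
                                na.rm = TRUE, colour = "#2166ac",
                                linewidth = 0.8)
  }
  p
}

#' Plot a TSS meta-profile
#'
#' @param object A `plectoneme_metaprofile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plectoneme_metaprofile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_raw), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_density),
                       colour = "#b2182b", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "offset from TSS (bp; negative = upstream)",
                  y = paste("mean", attr(object, "value"))) +
    ggplot2::theme_minimal()
}
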