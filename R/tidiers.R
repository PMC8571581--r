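#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a replicated experiment
#'
#' One row per replicate with its derived seed and trailing-window means.
#'
#' @param x A `dol_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `seed`, `mean_q`, `mean_s`,
#'   `mean_P`.
#' @export
tidy.dol_experiment <- function(x, ...) {
  x$replicates
}

#' One-row summary of a replicated experiment
#'
#' Across-replicate means and standard errors of the evolved trait levels,
#' plus the experimental scale.
#'
#' @param x A `dol_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dol_experiment <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "trait",
                             values_from = c("mean", "se"))
  p <- x$config$params
  dplyr::bind_cols(
    tibble::tibble(l = p$l, m = p$m, n = p$n, epsilon = p$epsilon,
                   theta = p$theta,
                   n_replicates = nrow(x$replicates),
                   generations = x$config$generations,
                   seed = x$seed),
    wide
  )
}

#' Plot an invasion phase grid
#'
#' Tile plot of the invasion regions over essentiality (x) and group size
#' (y); cells that cannot be realized with integer lineages are blank.
#'
#' @param object A `dol_phase_grid` from [phase_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dol_phase_grid <- function(object, ...) {
  region_cols <- c(
    no_division_of_labor = "white",
    random_wins = "#3B6FB6",
    coordinated_wins = "#E08214",
    neither_invades = "grey15",
    mutual_invasion = "#8C510A"
  )
  dat <- dplyr::filter(object, .data$valid)
  ggplot2::ggplot(dat, ggplot2::aes(.data$epsilon, .data$n,
                                    fill = .data$region)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = region_cols, drop = FALSE) +
    ggplot2::labs(
      x = "essentiality of cooperation (ε)",
      y = "group size (n = l m)",
      fill = NULL,
      title = sprintf("Invasion phase diagram (l = %d, θ = %g, %s)",
                      object$l[1], object$theta[1], object$mode[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evolutionary trajectory
#'
#' Per-generation population means of the helper proportion `P`, target
#' proportion `q`, and coordination level `s`.
#'
#' @param object A `dol_trajectory` from [run_replicate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dol_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("mean_q", "mean_s", "mean_P"),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     color = .data$trait)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_manual(
      values = c(mean_q = "grey40", mean_s = "black", mean_P = "#D6604D"),
      labels = c(mean_q = "target q", mean_s = "coordination s",
                 mean_P = "helpers P")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "generation", y = "population mean", color = NULL) +
    ggplot2::theme_minimal()
}
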