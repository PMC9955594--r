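# ggplot2 views of the result types. Plots are conveniences; every figure
# is backed by a tidy table the user can export instead.

#' @export
autoplot.simulation_report <- function(object, exact = TRUE, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$accuracy)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy - 2 * .data$se,
      ymax = .data$accuracy + 2 * .data$se
    ), colour = "steelblue") +
    ggplot2::labs(
      x = "decision order n", y = "mean performance",
      title = sprintf("Simulated per-order accuracy (%d runs)", object$n_runs)
    )
  if (exact && nrow(object$profile) <= 25L) {
    ex <- exact_curve(object$profile)
    gg <- gg + ggplot2::geom_point(
      data = ex, ggplot2::aes(y = .data$performance),
      shape = 2, colour = "firebrick"
    )
  }
  if (length(unique(object$profile$ability)) == 1L) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = pi_max(object$profile$ability[1]),
      linetype = "dashed", colour = "grey50"
    )
  }
  gg
}

#' @export
autoplot.seq_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("primary", "answer"),
                              names_to = "stage", values_to = "choice")
  long$stage <- factor(long$stage, levels = c("primary", "answer"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order, y = .data$stage,
                                     fill = .data$choice)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$is_casting),
      ggplot2::aes(x = .data$order, y = "answer"),
      inherit.aes = FALSE, shape = 8
    ) +
    ggplot2::labs(x = "decision order n", y = NULL, fill = "option",
                  title = "Primary choices vs answers (* = casting voter)")
}

#' @export
autoplot.d_walk_stats <- function(object, ...) {
  ggplot2::ggplot(object$absorption,
                  ggplot2::aes(x = .data$order, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "order at which |d| first reaches 2", y = "runs",
      title = sprintf("Absorption of the casting-vote walk (max |d| = %d)",
                      object$max_abs_d)
    )
}

#' Phase plot of the third respondent's mean performance
#'
#' Renders a [three_person_grid()] as a raster over `(p1, p2)` with the
#' behavioural case boundaries overlaid; the drop in \eqn{E[\pi_3]} across
#' the `p1 = p2` diagonal is the visual signature of the cascade regime.
#'
#' @param grid A tibble from [three_person_grid()].
#' @return A ggplot object.
#' @examples
#' plot_three_person_phase(three_person_grid(0.7, step = 0.02))
#' @export
plot_three_person_phase <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$p1, y = .data$p2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$e_pi3)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "white",
                         linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = expression(E[pi[3]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(p[1]), y = expression(p[2]),
                  title = "Mean performance of the third respondent")
}
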