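#' Plot a dose-response curve
#'
#' Viability against dose on a log axis, with the fitted IC50 marked when it
#' is not censored.
#'
#' @param object A `dose_response_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_response_curve
#' @export
autoplot.dose_response_curve <- function(object, ...) {
  dat <- tidy(object)
  dat$dose_plot <- pmax(dat$dose_nM, min(dat$dose_nM[dat$dose_nM > 0]) / 10)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose_plot, y = .data$viability)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM, log scale; zero floored)", y = "viability",
                  title = sprintf("%s on %s", dat$drug[1], dat$cell_line[1])) +
    ggplot2::ylim(0, 1)
  ic <- attr(object, "ic50_nM")
  if (isFALSE(attr(object, "ic50_censored")) && is.finite(ic)) {
    p <- p + ggplot2::geom_vline(xintercept = ic, linetype = "dashed") +
      ggplot2::annotate("text", x = ic, y = 0.05,
                        label = sprintf("IC50 = %.0f nM", ic), hjust = -0.1)
  }
  p
}

#' Plot a combination killrate grid
#'
#' @param object A `combination_grid`.
#' @param ... Unused.
#' @return A ggplot heatmap of killrate over the dose matrix.
#' @method autoplot combination_grid
#' @export
autoplot.combination_grid <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(signif(.data$dose_A, 3)),
                                    y = factor(signif(.data$dose_B, 3)),
                                    fill = .data$killrate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s dose (nM)", object$drugA),
                  y = sprintf("%s dose (nM)", object$drugB),
                  fill = "killrate",
                  title = sprintf("%s + %s on %s", object$drugA, object$drugB,
                                  object$cell_line)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a Bliss synergy surface
#'
#' Clamped Bliss excess over the dose grid, with the argmax marked.
#'
#' @param object A `synergy_result`.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @method autoplot synergy_result
#' @export
autoplot.synergy_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(signif(.data$dose_A, 3)),
                                    y = factor(signif(.data$dose_B, 3)),
                                    fill = .data$bliss_clamped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::labs(x = sprintf("%s dose (nM)", object$drugA),
                  y = sprintf("%s dose (nM)", object$drugB),
                  fill = "Bliss excess",
                  title = sprintf("Bliss_max = %.3f at (%.0f, %.0f) nM",
                                  object$bliss_score,
                                  object$argmax_doses[["dose_A"]],
                                  object$argmax_doses[["dose_B"]])) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a biomarker screen
#'
#' Synergy shift against killrate shift for each tested perturbation,
#' colored by class, faceted by cell line.
#'
#' @param effects Output of [screen_biomarkers()].
#' @return A ggplot object.
#' @export
plot_biomarker_effects <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$killrate_shift, y = .data$synergy_shift,
                               color = .data$class,
                               shape = .data$scope)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_line)) +
    ggplot2::labs(x = "killrate shift at synergy argmax",
                  y = "Bliss score shift",
                  color = "class", shape = "scope")
}
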