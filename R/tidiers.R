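#' Tidy a replicate ensemble
#'
#' @param x A `sim_ensemble`.
#' @param ... Unused.
#' @return One row per replicate: readout scores, verdict, attractor status.
#' @method tidy sim_ensemble
#' @export
tidy.sim_ensemble <- function(x, ...) {
  dplyr::mutate(x$replicates, cell_line = x$cell_line, .before = 1)
}

#' @rdname tidy.sim_ensemble
#' @method glance sim_ensemble
#' @export
glance.sim_ensemble <- function(x, ...) {
  tibble(cell_line = x$cell_line,
         n_replicates = nrow(x$replicates),
         survival_fraction = x$survival_fraction,
         attractor_fraction = x$attractor_fraction,
         mean_cell_cycle = mean(x$replicates$cell_cycle_score),
         mean_apoptosis = mean(x$replicates$apoptosis_score))
}

#' Tidy a dose-response curve
#'
#' @param x A `dose_response_curve`.
#' @param ... Unused.
#' @return The per-dose viability/killrate tibble.
#' @method tidy dose_response_curve
#' @export
tidy.dose_response_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.dose_response_curve
#' @method glance dose_response_curve
#' @export
glance.dose_response_curve <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(cell_line = x$cell_line[1], drug = x$drug[1],
         ic50_nM = attr(x, "ic50_nM"),
         ic50_censored = attr(x, "ic50_censored"),
         converged = fit$converged,
         min_viability = min(x$viability))
}

#' Tidy a synergy result
#'
#' @param x A `synergy_result`.
#' @param ... Unused.
#' @return Long tibble of raw and clamped Bliss excess per dose pair.
#' @method tidy synergy_result
#' @export
tidy.synergy_result <- function(x, ...) {
  ex <- x$bliss_excess
  tibble(cell_line = x$cell_line, drugA = x$drugA, drugB = x$drugB,
         dose_A = rep(as.numeric(rownames(ex) %||% seq_len(nrow(ex))),
                      times = ncol(ex)),
         dose_B = rep(as.numeric(colnames(ex) %||% seq_len(ncol(ex))),
                      each = nrow(ex)),
         bliss_excess = as.vector(ex),
         bliss_clamped = pmax(as.vector(ex), 0))
}

#' @rdname tidy.synergy_result
#' @method glance synergy_result
#' @export
glance.synergy_result <- function(x, ...) {
  tibble(cell_line = x$cell_line, drugA = x$drugA, drugB = x$drugB,
         bliss_score = x$bliss_score, bliss_max_ic50 = x$bliss_max_ic50,
         argmax_dose_A = x$argmax_doses[["dose_A"]],
         argmax_dose_B = x$argmax_doses[["dose_B"]],
         qc_pass = x$qc_pass)
}

#' Tidy a combination grid
#'
#' @param x A `combination_grid`.
#' @param ... Unused.
#' @return Long tibble `cell_line`, `drugA`, `drugB`, `dose_A`, `dose_B`,
#'   `killrate`.
#' @method tidy combination_grid
#' @export
tidy.combination_grid <- function(x, ...) {
  x$grid
}
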