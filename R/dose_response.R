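#' Standard 16-point dose grid
#'
#' Zero dose plus `n - 1` log-spaced points from `min_nM` to `max_nM`
#' (defaults: 16 points, 1 nM to 10000 nM), the axis used for both
#' monotherapy sweeps and 16x16 combination matrices.
#'
#' @param n Number of doses including zero (default 16).
#' @param min_nM Smallest non-zero dose (default 1).
#' @param max_nM Largest dose (default 10000).
#' @return Strictly increasing numeric vector of length `n`, starting at 0.
#' @export
dose_grid <- function(n = 16, min_nM = 1, max_nM = 10000) {
  assert_that(n >= 2, "need at least 2 doses")
  c(0, 10^seq(log10(min_nM), log10(max_nM), length.out = n - 1))
}

#' Monotherapy dose-response screen
#'
#' Runs a replicate ensemble of the avatar at each dose of the grid,
#' normalizes survival to the same-seed untreated ensemble (so viability at
#' dose 0 is exactly 1 and initialization noise cancels), and fits an IC50.
#' Avatars that are natively dead (untreated survival 0) cannot be screened.
#'
#' @param avatar A `cell_avatar`.
#' @param profile Target profile tibble for the drug (see [target_profile()]).
#' @param doses Dose vector (default [dose_grid()]).
#' @param config A [sim_config()].
#' @return A `dose_response_curve`: tibble with columns `cell_line`, `drug`,
#'   `dose_nM`, `survival`, `viability`, `killrate`, carrying `ic50_nM`,
#'   `ic50_censored` and `fit` attributes.
#' @export
monotherapy_screen <- function(avatar, profile, doses = dose_grid(),
                               config = sim_config()) {
  drug <- unique(as_tibble(profile)$drug)[1]
  surv <- vapply(doses, function(d) {
    tr <- if (d > 0) as_treatment(profile, dose_nM = d) else NULL
    run_ensemble(avatar, tr, config)$survival_fraction
  }, numeric(1))
  if (surv[1] <= 0) {
    rlang::abort(sprintf("cell line '%s' is natively dead (untreated survival 0); not screened",
                         attr(avatar, "cell_line") %||% "cell"))
  }
  viability <- surv / surv[1]
  fit <- fit_ic50(doses, viability)
  out <- tibble(
    cell_line = attr(avatar, "cell_line") %||% NA_character_,
    drug = drug, dose_nM = doses, survival = surv,
    viability = viability, killrate = 1 - viability
  )
  structure(out, class = c("dose_response_curve", class(out)),
            ic50_nM = fit$ic50_nM, ic50_censored = fit$censored, fit = fit)
}

#' Fit an IC50 by a four-parameter logistic on log10 dose
#'
#' Fits `v(d) = lower + (upper - lower) / (1 + exp(slope * (log10(d) - log10(xmid))))`
#' to the viability points (zero dose floored at 0.1 nM) and reports the dose
#' where the fitted curve crosses absolute viability 0.5. If the fitted curve
#' never crosses 0.5 inside the dose range — or the fit fails to converge —
#' the IC50 is censored above the top dose.
#'
#' @param doses Dose vector (nM); may include 0.
#' @param viability Viability in \[0, 1\], same length.
#' @param threshold Absolute viability defining the IC50 (default 0.5).
#' @param zero_floor Stand-in for dose 0 on the log axis (default 0.1 nM).
#' @return List with `ic50_nM`, `censored` (logical), `converged`, and the
#'   fitted parameters.
#' @export
fit_ic50 <- function(doses, viability, threshold = 0.5, zero_floor = 0.1) {
  keep <- is.finite(doses) & is.finite(viability)
  doses <- doses[keep]; viability <- viability[keep]
  assert_that(length(doses) >= 4, "need at least 4 finite points for an IC50 fit")
  ld <- log10(pmax(doses, zero_floor))
  top_dose <- max(doses)

  censored_out <- function(converged) {
    list(ic50_nM = NA_real_, censored = TRUE, converged = converged,
         pars = NULL, threshold = threshold)
  }
  if (max(viability) - min(viability) < 1e-9) {
    return(censored_out(TRUE))
  }

  start <- c(lower = max(min(viability), 0), upper = min(max(viability), 1),
             lxmid = stats::median(ld), slope = 2)
  residual_4pl <- function(p) {
    p["lower"] + (p["upper"] - p["lower"]) /
      (1 + exp(p["slope"] * (ld - p["lxmid"]))) - viability
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = residual_4pl,
      lower = c(0, 0, min(ld) - 2, 0.05),
      upper = c(1, 1.2, max(ld) + 2, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    rlang::warn("IC50 fit did not converge; censoring")
    return(censored_out(FALSE))
  }
  p <- as.list(fit$par)
  predict_v <- function(l) p$lower + (p$upper - p$lower) / (1 + exp(p$slope * (l - p$lxmid)))

  lgrid <- seq(min(ld), log10(top_dose), length.out = 2000)
  vgrid <- predict_v(lgrid)
  cross <- which(vgrid <= threshold)
  if (length(cross) == 0) return(censored_out(TRUE))
  i <- cross[1]
  if (i == 1) {
    lx <- lgrid[1]
  } else {
    # linear interpolation between the bracketing grid points
    l0 <- lgrid[i - 1]; l1 <- lgrid[i]
    v0 <- vgrid[i - 1]; v1 <- vgrid[i]
    lx <- l0 + (threshold - v0) * (l1 - l0) / (v1 - v0)
  }
  list(ic50_nM = 10^lx, censored = FALSE, converged = TRUE, pars = p,
       threshold = threshold)
}

#' IC50 of a dose-response curve
#'
#' @param curve A `dose_response_curve`.
#' @return The fitted IC50 in nM, or `NA` with attribute `censored = TRUE`
#'   when the curve never reaches the viability threshold within the grid.
#' @export
ic50 <- function(curve) {
  structure(attr(curve, "ic50_nM"), censored = attr(curve, "ic50_censored"))
}

#' Flag monotherapy prediction accuracy
#'
#' A prediction is accurate when predicted and reference IC50 agree within an
#' order of magnitude on each side: `|log10(in vitro) - log10(in silico)| < 1`
#' (strict).
#'
#' @param ic50_in_vitro,ic50_in_silico Positive IC50 values (nM).
#' @return Character vector `"accurate"` / `"inaccurate"`.
#' @export
#' @examples
#' accuracy_flag(100, 999)   # accurate
#' accuracy_flag(100, 1000)  # inaccurate (strict)
accuracy_flag <- function(ic50_in_vitro, ic50_in_silico) {
  assert_that(all(ic50_in_vitro > 0) && all(ic50_in_silico > 0),
              "IC50 values must be positive")
  ifelse(abs(log10(ic50_in_vitro) - log10(ic50_in_silico)) < 1,
         "accurate", "inaccurate")
}
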