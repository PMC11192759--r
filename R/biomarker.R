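#' Perturbation codes
#'
#' The four single-node perturbation kinds and their parameter semantics,
#' using the field's shorthand codes:
#' \describe{
#'   \item{`0.0` (lof)}{knock-out: `activity_max := 0`}
#'   \item{`1.0` (gof)}{constitutive activation: `activity_min := 1`}
#'   \item{`mc5.0` (overexpress)}{concentration multiplied by 5}
#'   \item{`mc0.3` (underexpress)}{concentration multiplied by 0.3}
#' }
#'
#' @param node Node id.
#' @param kind One of `"lof"`, `"gof"`, `"overexpress"`, `"underexpress"` or
#'   the codes `"0.0"`, `"1.0"`, `"mc5.0"`, `"mc0.3"`.
#' @return A `perturbation` object (list with `node`, `kind`, `code`).
#' @export
perturbation <- function(node, kind) {
  codes <- c(lof = "0.0", gof = "1.0", overexpress = "mc5.0",
             underexpress = "mc0.3")
  if (kind %in% codes) kind <- names(codes)[match(kind, codes)]
  assert_that(kind %in% names(codes),
              sprintf("unknown perturbation kind '%s'", kind))
  structure(list(node = node, kind = kind, code = codes[[kind]]),
            class = "perturbation")
}

#' Apply a single-node perturbation to an avatar
#'
#' Returns a modified copy (the input avatar is untouched): loss-of-function
#' caps the node's activity at 0, gain-of-function pins it at 1, and the
#' expression perturbations scale its effective concentration by 5 or 0.3.
#'
#' @param avatar A `cell_avatar`.
#' @param p A [perturbation()].
#' @return A perturbed `cell_avatar`.
#' @export
apply_perturbation <- function(avatar, p) {
  i <- match(p$node, avatar$nodes$id)
  assert_that(!is.na(i), sprintf("unknown node id '%s'", p$node))
  nodes <- avatar$nodes
  if (!"concentration" %in% names(nodes)) {
    nodes$concentration <- nodes$base_concentration
  }
  switch(p$kind,
    lof = {
      nodes$activity_max[i] <- 0
      nodes$activity_min[i] <- 0
      nodes$base_activity[i] <- 0
    },
    gof = {
      nodes$activity_min[i] <- 1
      nodes$activity_max[i] <- 1
      nodes$base_activity[i] <- 1
    },
    overexpress = {
      nodes$concentration[i] <- nodes$concentration[i] * 5
    },
    underexpress = {
      nodes$concentration[i] <- nodes$concentration[i] * 0.3
    }
  )
  out <- avatar
  out$nodes <- nodes
  out
}

#' Wilcoxon rank-sum significance of a biomarker effect
#'
#' Two-sided Wilcoxon rank-sum test between baseline and perturbed score
#' samples. The exact null distribution is used when both samples have at
#' most 25 observations and there are no ties; otherwise the normal
#' approximation with tie correction. Identical samples give p = 1.
#'
#' @param baseline_values,perturbed_values Numeric vectors.
#' @return Two-sided p-value.
#' @export
test_significance <- function(baseline_values, perturbed_values) {
  assert_that(length(baseline_values) > 0 && length(perturbed_values) > 0,
              "both samples must be non-empty")
  pooled <- c(baseline_values, perturbed_values)
  if (length(unique(pooled)) == 1) return(1)
  exact <- length(baseline_values) <= 25 && length(perturbed_values) <= 25 &&
    !any(duplicated(pooled))
  suppressWarnings(stats::wilcox.test(
    perturbed_values, baseline_values,
    alternative = "two.sided", exact = exact, correct = !exact
  )$p.value)
}

#' Classify a biomarker effect
#'
#' A significant shift toward more synergy or more cell kill marks a
#' sensitivity biomarker; a significant shift the other way marks resistance.
#' The effect is combination-specific when neither monotherapy IC50 moved
#' (|delta log10 IC50| below `ic50_shift_tol` for both drugs); otherwise it
#' is monotherapy-specific for whichever drug's IC50 shifted.
#'
#' @param synergy_shift Perturbed minus baseline Bliss score.
#' @param killrate_shift Perturbed minus baseline killrate at the synergy
#'   argmax doses.
#' @param p_value From [test_significance()].
#' @param dlog_ic50_A,dlog_ic50_B Absolute log10 IC50 shifts of the two
#'   drugs (censored-to-censored comparisons count as 0).
#' @param alpha Significance level (default 0.001).
#' @param ic50_shift_tol Largest |delta log10 IC50| still counting as "no
#'   shift" (default 0.2).
#' @return List with `class` (`sensitivity`/`resistance`/`none`) and `scope`
#'   (`combination_specific`/`monotherapy_specific_A`/
#'   `monotherapy_specific_B`/`none`).
#' @export
classify_biomarker <- function(synergy_shift, killrate_shift, p_value,
                               dlog_ic50_A = 0, dlog_ic50_B = 0,
                               alpha = 0.001, ic50_shift_tol = 0.2) {
  if (is.na(p_value) || p_value >= alpha) {
    return(list(class = "none", scope = "none"))
  }
  direction <- if (abs(synergy_shift) >= abs(killrate_shift)) synergy_shift else killrate_shift
  cls <- if (direction > 0) "sensitivity" else "resistance"
  shift_a <- abs(dlog_ic50_A) >= ic50_shift_tol
  shift_b <- abs(dlog_ic50_B) >= ic50_shift_tol
  scope <- if (!shift_a && !shift_b) {
    "combination_specific"
  } else if (shift_a && !shift_b) {
    "monotherapy_specific_A"
  } else if (shift_b && !shift_a) {
    "monotherapy_specific_B"
  } else {
    "none"
  }
  list(class = cls, scope = scope)
}

# log10 IC50 shift treating censored fits as the censoring bound, so
# censored -> censored comparisons yield 0
dlog10_ic50 <- function(base_fit, pert_fit, top_dose = 10000) {
  b <- if (base_fit$censored) top_dose else base_fit$ic50_nM
  p <- if (pert_fit$censored) top_dose else pert_fit$ic50_nM
  log10(p) - log10(b)
}

#' Screen node perturbations for synergy and viability biomarkers
#'
#' For each perturbation and cell line: reruns both monotherapy screens and
#' the combination grid on the perturbed avatar, measures the log10 IC50
#' shifts, the Bliss-score shift and the killrate shift at the baseline
#' synergy-argmax doses, tests replicate-level significance with a Wilcoxon
#' rank-sum test and classifies the effect. Two exclusion filters mirror the
#' screen's design: (i) only combination-cell line pairs whose baseline
#' synergy argmax lies at sub-IC50 doses for both drugs are analyzed;
#' (ii) triplets where cell survival dropped significantly but synergy fell
#' to a non-synergistic state are excluded as suspected model artifacts.
#'
#' @param avatars Named list of baseline `cell_avatar` objects.
#' @param profile_a,profile_b Target profiles of the combination.
#' @param perturbations List of [perturbation()] objects.
#' @param config A [sim_config()].
#' @param doses Dose vector for both axes (default [dose_grid()]).
#' @param alpha Significance level (default 0.001).
#' @param ic50_shift_tol No-IC50-shift tolerance on log10 scale
#'   (default 0.2).
#' @param synergy_threshold Bliss score below which a combination counts as
#'   non-synergistic for the artifact-exclusion filter (default 0.2).
#' @param require_sub_ic50_argmax Apply exclusion filter (i) (default TRUE).
#' @return A tibble with one row per surviving (perturbation, cell line):
#'   shifts, p-value, class, scope and bookkeeping columns, with an
#'   `excluded` attribute recording per-reason exclusion counts.
#' @export
screen_biomarkers <- function(avatars, profile_a, profile_b, perturbations,
                              config = sim_config(), doses = dose_grid(),
                              alpha = 0.001, ic50_shift_tol = 0.2,
                              synergy_threshold = 0.2,
                              require_sub_ic50_argmax = TRUE) {
  if (inherits(avatars, "cell_avatar")) avatars <- list(avatars)
  if (is.null(names(avatars))) {
    names(avatars) <- vapply(avatars, function(a) attr(a, "cell_line") %||% "cell", "")
  }
  excluded <- c(native_dead = 0L, supra_ic50_argmax = 0L, artifact = 0L)
  rows <- list()

  for (cl in names(avatars)) {
    avatar <- avatars[[cl]]
    base_curve_a <- tryCatch(monotherapy_screen(avatar, profile_a, doses, config),
                             error = function(e) NULL)
    if (is.null(base_curve_a)) {
      excluded[["native_dead"]] <- excluded[["native_dead"]] + 1L
      next
    }
    base_curve_b <- monotherapy_screen(avatar, profile_b, doses, config)
    base_grid <- combination_screen(avatar, profile_a, profile_b, doses, doses, config)
    base_fit_a <- attr(base_curve_a, "fit")
    base_fit_b <- attr(base_curve_b, "fit")
    base_syn <- max_synergy(base_grid, base_fit_a$ic50_nM, base_fit_b$ic50_nM,
                            force = TRUE)

    if (require_sub_ic50_argmax) {
      lim_a <- if (base_fit_a$censored) Inf else base_fit_a$ic50_nM
      lim_b <- if (base_fit_b$censored) Inf else base_fit_b$ic50_nM
      if (!(base_syn$argmax_doses[["dose_A"]] < lim_a &&
            base_syn$argmax_doses[["dose_B"]] < lim_b)) {
        excluded[["supra_ic50_argmax"]] <- excluded[["supra_ic50_argmax"]] + 1L
        next
      }
    }

    base_score_cache <- new.env(parent = emptyenv())

    for (p in perturbations) {
      pert <- apply_perturbation(avatar, p)
      pcurve_a <- tryCatch(monotherapy_screen(pert, profile_a, doses, config),
                           error = function(e) NULL)
      pcurve_b <- tryCatch(monotherapy_screen(pert, profile_b, doses, config),
                           error = function(e) NULL)
      if (is.null(pcurve_a) || is.null(pcurve_b)) {
        # perturbation alone kills the cell: maximal viability effect,
        # not interpretable as a combination biomarker
        excluded[["native_dead"]] <- excluded[["native_dead"]] + 1L
        next
      }
      pgrid <- combination_screen(pert, profile_a, profile_b, doses, doses, config)
      pfit_a <- attr(pcurve_a, "fit")
      pfit_b <- attr(pcurve_b, "fit")
      psyn <- max_synergy(pgrid, pfit_a$ic50_nM, pfit_b$ic50_nM, force = TRUE)

      synergy_shift <- psyn$bliss_score - base_syn$bliss_score
      # shifts are evaluated at the synergy argmax of whichever grid shows
      # the stronger synergy, where the biomarker's effect is expressed
      eval_doses <- if (psyn$bliss_score > base_syn$bliss_score) {
        psyn$argmax_doses
      } else {
        base_syn$argmax_doses
      }
      arg_i <- match(eval_doses[["dose_A"]], base_grid$doses_A)
      arg_j <- match(eval_doses[["dose_B"]], base_grid$doses_B)
      killrate_shift <- pgrid$killrate_AB[arg_i, arg_j] -
        base_grid$killrate_AB[arg_i, arg_j]
      key <- paste(eval_doses, collapse = "_")
      if (is.null(base_score_cache[[key]])) {
        base_score_cache[[key]] <- ensemble_scores(avatar, profile_a, profile_b,
                                                   eval_doses, config)
      }
      pert_scores <- ensemble_scores(pert, profile_a, profile_b,
                                     eval_doses, config)
      p_value <- test_significance(base_score_cache[[key]], pert_scores)

      # artifact filter: significant survival decrease but synergy collapsed
      # below the non-synergy threshold
      if (!is.na(p_value) && p_value < alpha && killrate_shift > 0 &&
          base_syn$bliss_score >= synergy_threshold &&
          psyn$bliss_score < synergy_threshold) {
        excluded[["artifact"]] <- excluded[["artifact"]] + 1L
        next
      }

      dla <- dlog10_ic50(base_fit_a, pfit_a, max(doses))
      dlb <- dlog10_ic50(base_fit_b, pfit_b, max(doses))
      cls <- classify_biomarker(synergy_shift, killrate_shift, p_value,
                                dla, dlb, alpha, ic50_shift_tol)
      rows[[length(rows) + 1]] <- tibble(
        cell_line = cl, node = p$node, kind = p$kind, code = p$code,
        combination = paste(base_grid$drugA, base_grid$drugB, sep = "+"),
        synergy_shift = synergy_shift, killrate_shift = killrate_shift,
        p_value = p_value, dlog_ic50_A = dla, dlog_ic50_B = dlb,
        class = cls$class, scope = cls$scope,
        baseline_bliss = base_syn$bliss_score, perturbed_bliss = psyn$bliss_score
      )
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(cell_line = character(), node = character(), kind = character(),
           code = character(), combination = character(),
           synergy_shift = numeric(), killrate_shift = numeric(),
           p_value = numeric(), dlog_ic50_A = numeric(),
           dlog_ic50_B = numeric(), class = character(), scope = character(),
           baseline_bliss = numeric(), perturbed_bliss = numeric())
  }
  attr(out, "excluded") <- excluded
  out
}

# replicate-level kill indicator (1 - alive) of the combination at given
# doses; the per-replicate sample behind the Wilcoxon test
ensemble_scores <- function(avatar, profile_a, profile_b, doses_at, config) {
  tr <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(profile_a), dose_nM = doses_at[["dose_A"]]),
    dplyr::mutate(as_tibble(profile_b), dose_nM = doses_at[["dose_B"]])
  )
  tr <- tr[tr$dose_nM > 0, ]
  ens <- run_ensemble(avatar, if (nrow(tr)) tr else NULL, config)
  as.numeric(ens$replicates$verdict == "dead") +
    ens$replicates$apoptosis_score - ens$replicates$cell_cycle_score
}

#' Read a perturbation list TSV
#'
#' Columns: `node`, `kind` (accepting the shorthand codes `0.0`, `1.0`,
#' `mc5.0`, `mc0.3`).
#'
#' @param path TSV file.
#' @return List of [perturbation()] objects.
#' @export
read_perturbations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  purrr::map2(tab$node, tab$kind, perturbation)
}
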