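#' Run a 16x16 drug-combination grid
#'
#' Simulates every dose pair of the two drugs on the avatar, recording the
#' killrate (1 - viability normalized to the same-seed untreated ensemble).
#' Row/column zero of the matrix are the monotherapy killrates of drug A and
#' drug B.
#'
#' @param avatar A `cell_avatar`.
#' @param profile_a,profile_b Target profile tibbles of the two drugs.
#' @param doses_a,doses_b Dose vectors (default [dose_grid()]).
#' @param config A [sim_config()].
#' @return A `combination_grid`: list with `killrate_AB` (doses_a x doses_b
#'   matrix), marginal vectors `killrate_A`, `killrate_B`, the dose vectors,
#'   drug/cell-line identifiers and the long-format tibble `grid`.
#' @export
combination_screen <- function(avatar, profile_a, profile_b,
                               doses_a = dose_grid(), doses_b = dose_grid(),
                               config = sim_config()) {
  drug_a <- unique(as_tibble(profile_a)$drug)[1]
  drug_b <- unique(as_tibble(profile_b)$drug)[1]
  surv0 <- run_ensemble(avatar, NULL, config)$survival_fraction
  if (surv0 <= 0) {
    rlang::abort("cell line is natively dead (untreated survival 0); not screened")
  }
  kill <- matrix(NA_real_, length(doses_a), length(doses_b))
  for (i in seq_along(doses_a)) {
    for (j in seq_along(doses_b)) {
      da <- doses_a[i]; db <- doses_b[j]
      tr <- NULL
      if (da > 0 || db > 0) {
        parts <- list()
        if (da > 0) parts[[length(parts) + 1]] <- dplyr::mutate(as_tibble(profile_a), dose_nM = da)
        if (db > 0) parts[[length(parts) + 1]] <- dplyr::mutate(as_tibble(profile_b), dose_nM = db)
        tr <- dplyr::bind_rows(parts)
      }
      s <- run_ensemble(avatar, tr, config)$survival_fraction
      kill[i, j] <- 1 - s / surv0
    }
  }
  kill <- clamp(kill, 0, 1)
  new_combination_grid(kill, doses_a, doses_b, drug_a, drug_b,
                       attr(avatar, "cell_line") %||% NA_character_)
}

new_combination_grid <- function(kill, doses_a, doses_b, drug_a, drug_b,
                                 cell_line) {
  grid <- tibble(cell_line = cell_line, drugA = drug_a, drugB = drug_b,
                 dose_A = rep(doses_a, times = length(doses_b)),
                 dose_B = rep(doses_b, each = length(doses_a)),
                 killrate = as.vector(kill))
  structure(list(drugA = drug_a, drugB = drug_b, cell_line = cell_line,
                 doses_A = doses_a, doses_B = doses_b,
                 killrate_AB = kill, killrate_A = kill[, 1],
                 killrate_B = kill[1, ], grid = grid),
            class = "combination_grid")
}

#' @export
print.combination_grid <- function(x, ...) {
  cat(sprintf("<combination_grid> %s + %s on '%s': %dx%d doses, max killrate %.3f\n",
              x$drugA, x$drugB, x$cell_line, length(x$doses_A),
              length(x$doses_B), max(x$killrate_AB)))
  invisible(x)
}

#' Bliss independence excess over a combination grid
#'
#' Under Bliss independence the expected combined killrate is
#' `kA + kB - kA * kB` (the addition law of probability); the excess is the
#' observed killrate minus that expectation. Negative excess (antagonism) is
#' treated as zero at the scoring stage — only synergy is quantified.
#'
#' @param killrate_A,killrate_B Marginal monotherapy killrates in \[0, 1\].
#' @param killrate_AB Observed killrate matrix
#'   (`length(killrate_A)` x `length(killrate_B)`).
#' @return Matrix of raw (unclamped) Bliss excess values in \[-1, 1\].
#' @export
#' @examples
#' bliss_excess_grid(0.4, 0.5, matrix(0.9))  # 0.9 - 0.7 = 0.2
bliss_excess_grid <- function(killrate_A, killrate_B, killrate_AB) {
  killrate_AB <- as.matrix(killrate_AB)
  assert_that(nrow(killrate_AB) == length(killrate_A) &&
                ncol(killrate_AB) == length(killrate_B),
              "killrate matrix shape does not match the marginals")
  assert_that(all(c(killrate_A, killrate_B, killrate_AB) >= 0) &&
                all(c(killrate_A, killrate_B, killrate_AB) <= 1),
              "killrates must lie in [0, 1]")
  expected <- outer(killrate_A, killrate_B, function(a, b) a + b - a * b)
  killrate_AB - expected
}

#' Maximum Bliss synergy of a combination grid
#'
#' Scores a combination by the maximum negative-clamped Bliss excess over the
#' whole dose grid (`bliss_score`), and by the same maximum restricted to
#' dose pairs where both doses lie strictly below the respective monotherapy
#' IC50s (`bliss_max_ic50`; 0 when no such cell exists). The dose pair
#' attaining the overall maximum is recorded (first in row-major order on
#' ties).
#'
#' @param grid A `combination_grid`.
#' @param ic50_A,ic50_B Monotherapy IC50s (nM); censored/`NA` values are
#'   treated as above the top dose, so every grid dose counts as sub-IC50.
#' @param qc Result of [qc_grid()]; computed if missing. Scoring a failed
#'   grid requires `force = TRUE`.
#' @param force Score even when QC failed.
#' @return A `synergy_result`: list with `bliss_excess` (raw matrix),
#'   `bliss_score`, `bliss_max_ic50`, `argmax_doses`, `qc_pass`, identifiers.
#' @export
max_synergy <- function(grid, ic50_A = NA, ic50_B = NA, qc = NULL,
                        force = FALSE) {
  if (is.null(qc)) qc <- qc_grid(grid)
  if (!qc$pass && !force) {
    rlang::abort(c("combination grid failed quality control", qc$reasons))
  }
  excess <- bliss_excess_grid(grid$killrate_A, grid$killrate_B, grid$killrate_AB)
  dimnames(excess) <- list(grid$doses_A, grid$doses_B)
  clamped <- pmax(excess, 0)
  bliss_score <- max(clamped)
  # first maximum in row-major order
  idx <- which(t(clamped) == bliss_score, arr.ind = TRUE)[1, , drop = TRUE]
  arg <- c(dose_A = grid$doses_A[idx[["col"]]], dose_B = grid$doses_B[idx[["row"]]])

  top_a <- if (is.na(ic50_A)) Inf else ic50_A
  top_b <- if (is.na(ic50_B)) Inf else ic50_B
  sub <- outer(grid$doses_A < top_a, grid$doses_B < top_b, `&`)
  bliss_max_ic50 <- if (any(sub)) max(clamped[sub]) else 0

  structure(list(drugA = grid$drugA, drugB = grid$drugB,
                 cell_line = grid$cell_line, bliss_excess = excess,
                 bliss_score = bliss_score, bliss_max_ic50 = bliss_max_ic50,
                 argmax_doses = arg, qc_pass = qc$pass),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> %s + %s on '%s': Bliss_max %.3f (sub-IC50 %.3f), QC %s\n",
              x$drugA, x$drugB, x$cell_line, x$bliss_score, x$bliss_max_ic50,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Quality control of a combination grid
#'
#' Rejects grids that violate dose-response principles for either compound:
#' a marginal viability that increases with dose by more than the tolerance
#' `tau` anywhere along the axis, or any non-finite killrate entry.
#'
#' @param grid A `combination_grid`.
#' @param tau Largest tolerated positive jump in marginal viability
#'   (default 0.1).
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
qc_grid <- function(grid, tau = 0.1) {
  reasons <- character(0)
  if (any(!is.finite(grid$killrate_AB))) {
    reasons <- c(reasons, "non-finite killrate entries in the grid")
  }
  check_marginal <- function(kill, drug) {
    viab <- 1 - kill
    jumps <- diff(viab)
    if (length(jumps) && max(jumps) > tau) {
      sprintf("viability of %s increases by %.3f along its dose axis (tau = %.2f)",
              drug, max(jumps), tau)
    } else character(0)
  }
  reasons <- c(reasons,
               check_marginal(grid$killrate_A, grid$drugA),
               check_marginal(grid$killrate_B, grid$drugB))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Discretize synergy scores into non/moderate/strong categories
#'
#' One-dimensional k-means (k = 3, many restarts, seeded) on the score
#' vector; clusters are ordered by centroid and the two thresholds are the
#' midpoints of the gaps between adjacent clusters (mean of the lower
#' cluster's maximum and the upper cluster's minimum).
#'
#' @param scores Numeric vector of synergy scores (needs >= 3 distinct
#'   values).
#' @param seed RNG seed for the k-means restarts (default 1).
#' @param nstart Number of random restarts (default 100).
#' @return List with `thresholds` (t1 < t2), `labels` (factor `non` /
#'   `moderate` / `strong` per score) and `centers`.
#' @export
discretize_synergy <- function(scores, seed = 1L, nstart = 100) {
  assert_that(length(unique(scores)) >= 3,
              "need at least 3 distinct synergy scores to form 3 categories")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(scores, centers = 3, nstart = nstart, iter.max = 100)
  ord <- order(km$centers)
  rank_of <- match(km$cluster, ord)
  t1 <- mean(c(max(scores[rank_of == 1]), min(scores[rank_of == 2])))
  t2 <- mean(c(max(scores[rank_of == 2]), min(scores[rank_of == 3])))
  labels <- factor(c("non", "moderate", "strong")[rank_of],
                   levels = c("non", "moderate", "strong"))
  list(thresholds = c(t1 = t1, t2 = t2), labels = labels,
       centers = sort(as.vector(km$centers)))
}

#' Enumerate anchored drug combinations
#'
#' Every anchor (DDR) drug is paired with every other drug in the panel —
#' the remaining anchors and all partners — without self-pairing: with `a`
#' anchors and `p` partners this yields `a * (a - 1 + p)` ordered pairs
#' (e.g. 12 and 46 give 684).
#'
#' @param ddr_drugs Character vector of anchor drug ids.
#' @param nonddr_drugs Character vector of partner drug ids (disjoint from
#'   the anchors).
#' @return A tibble with columns `anchor`, `partner`.
#' @export
enumerate_combinations <- function(ddr_drugs, nonddr_drugs = character(0)) {
  assert_that(!anyDuplicated(ddr_drugs) && !anyDuplicated(nonddr_drugs),
              "drug lists must not contain duplicates")
  assert_that(length(intersect(ddr_drugs, nonddr_drugs)) == 0,
              "anchor and partner drug lists overlap")
  purrr::map_dfr(ddr_drugs, function(d) {
    partners <- c(setdiff(ddr_drugs, d), nonddr_drugs)
    if (length(partners) == 0) return(tibble(anchor = character(), partner = character()))
    tibble(anchor = d, partner = partners)
  })
}

#' Aggregate synergy and killrate by MoA group, with pairwise tests
#'
#' Reporting helper for combination screens: mean synergy and mean killrate
#' per mechanism-of-action group, plus pairwise two-sided Wilcoxon rank-sum
#' tests between groups with Benjamini-Hochberg correction.
#'
#' @param results Data frame with columns `moa_group`, `bliss_score` and
#'   optionally `killrate`.
#' @return List with `summary` (per-group means, n) and `pairwise_tests`
#'   (tibble `group1`, `group2`, `p_value`, `p_adj`).
#' @export
summarize_moa_synergy <- function(results) {
  results <- as_tibble(results)
  summary <- results |>
    dplyr::group_by(.data$moa_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_synergy = mean(.data$bliss_score),
      mean_killrate = if ("killrate" %in% names(results)) mean(.data$killrate) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_synergy))
  groups <- unique(results$moa_group)
  pairs <- if (length(groups) >= 2) utils::combn(sort(groups), 2) else matrix(character(0), 2, 0)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    p <- suppressWarnings(stats::wilcox.test(
      results$bliss_score[results$moa_group == g1],
      results$bliss_score[results$moa_group == g2]
    )$p.value)
    tibble(group1 = g1, group2 = g2, p_value = p)
  })
  if (nrow(tests) > 0) tests$p_adj <- stats::p.adjust(tests$p_value, "BH")
  list(summary = summary, pairwise_tests = tests)
}
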