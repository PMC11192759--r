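#' Balanced accuracy of dichotomized synergy predictions
#'
#' Both score vectors are dichotomized at their thresholds (score >= threshold
#' counts as synergistic) and compared: TPR (sensitivity), TNR (specificity)
#' and their mean, the balanced accuracy `BA = (TPR + TNR) / 2`.
#'
#' @param predicted_scores,reference_scores Numeric vectors of equal length.
#' @param threshold_pred,threshold_ref Dichotomization thresholds. Note the
#'   internal synergy scale is 0-1 while reference panels often report 0-100;
#'   multiply by 100 (or set thresholds accordingly) at this boundary.
#' @return A tibble with columns `TPR`, `TNR`, `BA`, `n_pos`, `n_neg`.
#' @export
balanced_accuracy <- function(predicted_scores, reference_scores,
                              threshold_pred, threshold_ref) {
  assert_that(length(predicted_scores) == length(reference_scores),
              "score vectors must have equal length")
  pred <- predicted_scores >= threshold_pred
  ref <- reference_scores >= threshold_ref
  if (all(ref) || !any(ref)) {
    rlang::abort("reference contains a single class after dichotomization; BA undefined")
  }
  tpr <- mean(pred[ref])
  tnr <- mean(!pred[!ref])
  tibble(TPR = tpr, TNR = tnr, BA = (tpr + tnr) / 2,
         n_pos = sum(ref), n_neg = sum(!ref))
}

#' ROC AUC via the rank (Mann-Whitney) statistic
#'
#' `AUC = (sum of ranks of positives - n1(n1+1)/2) / (n1 * n0)` with midranks
#' for ties; equal to the probability that a random positive outscores a
#' random negative (ties counting one half).
#'
#' @param predicted_scores Numeric scores.
#' @param reference_labels Binary labels (logical or 0/1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predicted_scores, reference_labels) {
  lab <- as.logical(reference_labels)
  assert_that(any(lab) && any(!lab),
              "need both classes in the reference labels; AUC undefined")
  r <- rank(predicted_scores)
  n1 <- sum(lab); n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train/test splits exclusive by cell line, drug, or both
#'
#' CEX holds out whole cell lines; DEX holds out whole drugs; AEX holds out
#' both a cell-line subset and a drug subset, keeping only test rows where
#' both entities are held out (rows mixing train and test entities are
#' dropped). Entity subsets are sampled with the given seed, so splits are
#' reproducible.
#'
#' @param dataset Data frame with columns `cell_line` and `drug` (rows may
#'   repeat per dose).
#' @param strategy `"CEX"`, `"DEX"` or `"AEX"`.
#' @param test_fraction Fraction of entities held out (default 0.2).
#' @param seed RNG seed.
#' @return List with integer row indices `train` and `test`.
#' @export
make_splits <- function(dataset, strategy = c("CEX", "DEX", "AEX"),
                        test_fraction = 0.2, seed = 1L) {
  strategy <- match.arg(strategy)
  dataset <- as_tibble(dataset)
  assert_that(nrow(dataset) > 0, "dataset is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  hold_out <- function(entities) {
    k <- max(1L, round(length(entities) * test_fraction))
    if (k >= length(entities)) {
      rlang::abort(sprintf("cannot hold out %d of %d entities; split infeasible",
                           k, length(entities)))
    }
    sample(entities, k)
  }

  cells <- unique(dataset$cell_line)
  drugs <- unique(dataset$drug)
  if (strategy == "CEX") {
    test_cells <- hold_out(cells)
    test <- which(dataset$cell_line %in% test_cells)
    train <- which(!dataset$cell_line %in% test_cells)
  } else if (strategy == "DEX") {
    test_drugs <- hold_out(drugs)
    test <- which(dataset$drug %in% test_drugs)
    train <- which(!dataset$drug %in% test_drugs)
  } else {
    if (length(cells) < 2 || length(drugs) < 2) {
      rlang::abort("AEX needs at least 2 cell lines and 2 drugs")
    }
    test_cells <- hold_out(cells)
    test_drugs <- hold_out(drugs)
    test <- which(dataset$cell_line %in% test_cells & dataset$drug %in% test_drugs)
    train <- which(!dataset$cell_line %in% test_cells & !dataset$drug %in% test_drugs)
  }
  if (length(test) == 0 || length(train) == 0) {
    rlang::abort("split produced an empty train or test side")
  }
  list(train = train, test = test)
}

# feature matrix: expression block (per cell line) + dose-dependent target
# inhibition block (per drug at the row's dose)
assemble_features <- function(dataset, expression_features, drug_profiles,
                              feature_targets) {
  expr_mat <- as.matrix(expression_features[match(dataset$cell_line,
                                                  rownames(expression_features)), ,
                                            drop = FALSE])
  inh <- matrix(0, nrow(dataset), length(feature_targets),
                dimnames = list(NULL, paste0("inh_", feature_targets)))
  for (r in seq_len(nrow(dataset))) {
    prof <- drug_profiles[[dataset$drug[r]]]
    if (is.null(prof)) next
    hit <- match(prof$target, feature_targets)
    ok <- !is.na(hit)
    inh[r, hit[ok]] <- target_inhibition(dataset$dose_nM[r], prof$affinity_nM[ok])
  }
  cbind(expr_mat, inh)
}

#' Run standard ML baselines on monotherapy killrate regression
#'
#' Trains ridge regression (glmnet), a small fully-connected neural network
#' (nnet, one hidden layer) and gradient-boosted trees (xgboost) to predict
#' monotherapy killrates from concatenated cell-line expression and
#' dose-dependent target-inhibition features, then evaluates Pearson
#' correlation on the held-out rows of each split.
#'
#' @param dataset Data frame with columns `cell_line`, `drug`, `dose_nM`,
#'   `killrate`.
#' @param expression_features Numeric matrix, one row per cell line
#'   (rownames = cell lines).
#' @param drug_profiles Named list of target-profile tibbles keyed by drug.
#' @param splits A list of splits from [make_splits()] (or a single split).
#' @param models Subset of `c("ridge", "nn", "gbt")`.
#' @param seed RNG seed for model fitting.
#' @return A tibble with one row per (model, split): `model`, `split`,
#'   `pearson_r`, `rmse`, `n_test`, plus a `predictions` list-column.
#' @export
run_baselines <- function(dataset, expression_features, drug_profiles, splits,
                          models = c("ridge", "nn", "gbt"), seed = 1L) {
  dataset <- as_tibble(dataset)
  if (!is.null(splits$train)) splits <- list(splits)
  feature_targets <- sort(unique(unlist(lapply(drug_profiles, function(p) p$target))))
  X <- assemble_features(dataset, expression_features, drug_profiles,
                         feature_targets)
  y <- dataset$killrate
  if (stats::sd(y) == 0) {
    rlang::abort("constant response: killrate has zero variance; training degenerate")
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  fit_one <- function(model, tr, te) {
    set.seed(seed)
    pred <- switch(model,
      ridge = {
        fit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0,
                                 nfolds = 5,
                                 lambda = 10^seq(2, -6, length.out = 80))
        as.vector(stats::predict(fit, X[te, , drop = FALSE], s = "lambda.min"))
      },
      nn = {
        sc <- scale(X[tr, , drop = FALSE])
        ctr <- attr(sc, "scaled:center")
        scl <- attr(sc, "scaled:scale"); scl[scl == 0] <- 1
        fit <- nnet::nnet(scale(X[tr, , drop = FALSE], ctr, scl), y[tr],
                          size = 16, linout = TRUE, decay = 1e-3,
                          maxit = 500, trace = FALSE, MaxNWts = 10000)
        as.vector(stats::predict(fit, scale(X[te, , drop = FALSE], ctr, scl)))
      },
      gbt = {
        fit <- xgboost::xgboost(X[tr, , drop = FALSE], y[tr],
                                nrounds = 200, max_depth = 4,
                                learning_rate = 0.1, subsample = 0.8,
                                verbosity = 0, nthreads = 1)
        stats::predict(fit, X[te, , drop = FALSE])
      }
    )
    r <- if (stats::sd(pred) == 0 || stats::sd(y[te]) == 0) NA_real_ else
      stats::cor(pred, y[te])
    tibble(model = model, pearson_r = r,
           rmse = sqrt(mean((pred - y[te])^2)), n_test = length(te),
           predictions = list(tibble(row = te, predicted = pred,
                                     observed = y[te])))
  }

  purrr::imap_dfr(splits, function(sp, k) {
    purrr::map_dfr(models, fit_one, tr = sp$train, te = sp$test) |>
      dplyr::mutate(split = as.character(k), .after = "model")
  })
}

#' Pearson correlation between predicted and reference IC50s
#'
#' Computed on log10 IC50 over the overlapping keys; censored predictions are
#' excluded and their count reported.
#'
#' @param predicted_ic50 Named numeric vector (or tibble with `key`,
#'   `ic50_nM`, `censored`).
#' @param reference_ic50 Named numeric vector of reference IC50s (nM).
#' @return List with `pearson_r`, `n_used`, `n_censored`.
#' @export
ic50_correlation <- function(predicted_ic50, reference_ic50) {
  if (is.data.frame(predicted_ic50)) {
    cens <- predicted_ic50$censored %||% rep(FALSE, nrow(predicted_ic50))
    pred <- stats::setNames(predicted_ic50$ic50_nM, predicted_ic50$key)
    pred[cens] <- NA_real_
  } else {
    pred <- predicted_ic50
  }
  keys <- intersect(names(pred), names(reference_ic50))
  vals <- tibble(pred = pred[keys], ref = reference_ic50[keys])
  n_censored <- sum(!is.finite(vals$pred) | !is.finite(vals$ref))
  vals <- vals[is.finite(vals$pred) & is.finite(vals$ref), ]
  if (nrow(vals) < 3) {
    rlang::abort("fewer than 3 overlapping finite IC50 pairs; correlation undefined")
  }
  list(pearson_r = stats::cor(log10(vals$pred), log10(vals$ref)),
       n_used = nrow(vals), n_censored = n_censored)
}
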