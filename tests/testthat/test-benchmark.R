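test_that("balanced accuracy reproduces hand-built confusion structures", {
  # 100 positives of which 37 called, 100 negatives of which 78 correctly rejected
  ref <- c(rep(1, 100), rep(0, 100))
  pred <- c(rep(1, 37), rep(0, 63), rep(1, 22), rep(0, 78))
  ba <- balanced_accuracy(pred, ref, 0.5, 0.5)
  expect_equal(ba$TPR, 0.37)
  expect_equal(ba$TNR, 0.78)
  expect_equal(ba$BA, 0.575)

  pred2 <- c(rep(1, 46), rep(0, 54), rep(1, 22), rep(0, 78))
  expect_equal(balanced_accuracy(pred2, ref, 0.5, 0.5)$BA, 0.62)

  expect_equal(balanced_accuracy(ref, ref, 0.5, 0.5)$BA, 1)
  expect_error(balanced_accuracy(pred, rep(1, 200), 0.5, 0.5), "single class")
})

test_that("balanced accuracy is invariant under simultaneous class swap", {
  set.seed(3)
  pred <- runif(200)
  ref <- runif(200)
  a <- balanced_accuracy(pred, ref, 0.4, 0.6)$BA
  # swap classes: negate both scores around their thresholds
  b <- balanced_accuracy(-pred, -ref, -0.4 + 1e-12, -0.6 + 1e-12)$BA
  expect_equal(a, b)
})

test_that("random scores give balanced accuracy near one half", {
  set.seed(10)
  pred <- runif(4000)
  ref <- runif(4000)
  expect_equal(balanced_accuracy(pred, ref, 0.5, 0.5)$BA, 0.5, tolerance = 0.05)
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  # 4 pos-neg pairs: concordant 0.8>0.1, 0.8>0.4, 0.35>0.1; discordant 0.35<0.4
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 3 / 4)

  set.seed(5)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 2)  # ties likely
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(roc_auc(scores, labels),
                   as.numeric(suppressMessages(
                     pROC::auc(labels, scores, direction = "<",
                               levels = c(0, 1)))))
    }
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

make_bench_dataset <- function(n_cells = 4, n_drugs = 2, doses = c(10, 100, 1000)) {
  tidyr::expand_grid(cell_line = paste0("c", seq_len(n_cells)),
                     drug = paste0("d", seq_len(n_drugs)),
                     dose_nM = doses)
}

test_that("splits are exclusive by the declared entities", {
  ds <- make_bench_dataset()
  sp <- make_splits(ds, "CEX", 0.5, seed = 2)
  expect_length(intersect(ds$cell_line[sp$train], ds$cell_line[sp$test]), 0)
  expect_equal(length(unique(ds$cell_line[sp$test])), 2)

  spd <- make_splits(ds, "DEX", 0.5, seed = 2)
  expect_length(intersect(ds$drug[spd$train], ds$drug[spd$test]), 0)

  ds2 <- make_bench_dataset(2, 2)
  spa <- make_splits(ds2, "AEX", 0.5, seed = 2)
  expect_length(intersect(ds2$cell_line[spa$train], ds2$cell_line[spa$test]), 0)
  expect_length(intersect(ds2$drug[spa$train], ds2$drug[spa$test]), 0)
  # 2x2 AEX at 0.5: one cell and one drug held out; mixed rows dropped
  expect_equal(length(unique(ds2$cell_line[spa$test])), 1)
  expect_equal(length(unique(ds2$drug[spa$test])), 1)
  expect_equal(length(sp$train) + length(sp$test), nrow(ds))
  expect_lt(length(spa$train) + length(spa$test), nrow(ds2))

  expect_error(make_splits(ds[ds$cell_line == "c1", ], "CEX", 0.9),
               "infeasible")
})

test_that("split exclusivity holds across random datasets and seeds", {
  for (seed in c(41, 42, 43)) {
    set.seed(seed)
    ds <- make_bench_dataset(sample(3:8, 1), sample(2:6, 1))
    for (strategy in c("CEX", "DEX", "AEX")) {
      sp <- make_splits(ds, strategy, 0.3, seed = seed)
      if (strategy != "DEX") {
        expect_length(intersect(ds$cell_line[sp$train], ds$cell_line[sp$test]), 0)
      }
      if (strategy != "CEX") {
        expect_length(intersect(ds$drug[sp$train], ds$drug[sp$test]), 0)
      }
      sp2 <- make_splits(ds, strategy, 0.3, seed = seed)
      expect_identical(sp, sp2)
    }
  }
})

test_that("ridge recovers a linear killrate rule on a cell-exclusive split", {
  set.seed(6)
  cells <- paste0("c", 1:10)
  expr <- matrix(rnorm(10 * 5), 10, 5,
                 dimnames = list(cells, paste0("g", 1:5)))
  profiles <- list(
    d1 = tibble::tibble(drug = "d1", target = "g1", affinity_nM = 100),
    d2 = tibble::tibble(drug = "d2", target = "g2", affinity_nM = 50)
  )
  ds <- make_bench_dataset(10, 2, doses = c(1, 10, 100, 1000, 10000))
  inh <- mapply(function(d, dr) target_inhibition(d, profiles[[dr]]$affinity_nM),
                ds$dose_nM, ds$drug)
  ds$killrate <- 0.3 * expr[match(ds$cell_line, cells), "g3"] + 0.6 * inh
  sp <- make_splits(ds, "CEX", 0.3, seed = 1)
  out <- run_baselines(ds, expr, profiles, sp, models = "ridge")
  expect_gt(out$pearson_r, 0.95)
})

test_that("all three baseline models train and emit finite metrics", {
  set.seed(6)
  cells <- paste0("c", 1:6)
  expr <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(cells, paste0("g", 1:3)))
  profiles <- list(d1 = tibble::tibble(drug = "d1", target = "g1",
                                       affinity_nM = 100))
  ds <- make_bench_dataset(6, 1, doses = c(1, 10, 100, 1000))
  ds$killrate <- target_inhibition(ds$dose_nM, 100) +
    0.05 * expr[match(ds$cell_line, cells), "g2"]
  sp <- make_splits(ds, "CEX", 0.3, seed = 3)
  out <- run_baselines(ds, expr, profiles, sp)
  expect_setequal(out$model, c("ridge", "nn", "gbt"))
  expect_true(all(is.finite(out$rmse)))

  ds$killrate <- 0.5
  expect_error(run_baselines(ds, expr, profiles, sp), "constant response")
})

test_that("shuffled responses carry no signal for the baselines", {
  set.seed(12)
  cells <- paste0("c", 1:12)
  expr <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(cells, paste0("g", 1:4)))
  profiles <- list(d1 = tibble::tibble(drug = "d1", target = "g1",
                                       affinity_nM = 100))
  ds <- make_bench_dataset(12, 1, doses = c(1, 10, 100, 1000, 10000))
  ds$killrate <- runif(nrow(ds))  # pure noise
  splits <- lapply(1:5, function(s) make_splits(ds, "CEX", 0.3, seed = s))
  out <- run_baselines(ds, expr, profiles, splits, models = "ridge")
  expect_lt(abs(mean(out$pearson_r)), 0.4)
})

test_that("IC50 correlation follows the textbook Pearson formula on the log scale", {
  ref <- c(a = 10, b = 100, c = 1000)
  expect_equal(ic50_correlation(ref, ref)$pearson_r, 1)
  anti <- c(a = 1000, b = 100, c = 10)
  expect_equal(ic50_correlation(anti, ref)$pearson_r, -1)

  pred <- c(k1 = 12, k2 = 40, k3 = 180, k4 = 900, k5 = 4000)
  refv <- c(k1 = 30, k2 = 25, k3 = 400, k4 = 600, k5 = 9000)
  x <- log10(pred); y <- log10(refv)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ic50_correlation(pred, refv)$pearson_r, manual)

  tab <- tibble::tibble(key = names(pred), ic50_nM = unname(pred),
                        censored = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- ic50_correlation(tab, refv)
  expect_equal(out$n_used, 4)
  expect_equal(out$n_censored, 1)
  expect_error(ic50_correlation(pred[1:2], refv[1:2]), "fewer than 3")
})
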