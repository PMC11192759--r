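toy_grid <- function(kill, doses_a, doses_b, drugs = c("A", "B"), cl = "CL") {
  cellavatar:::new_combination_grid(kill, doses_a, doses_b, drugs[1], drugs[2], cl)
}

test_that("Bliss excess follows the addition law and is clamped for scoring", {
  expect_equal(bliss_excess_grid(0.4, 0.5, matrix(0.9))[1, 1], 0.2)
  ex <- bliss_excess_grid(0.4, 0.5, matrix(0.6))
  expect_equal(ex[1, 1], -0.1)
  expect_equal(pmax(ex, 0)[1, 1], 0)
  expect_equal(bliss_excess_grid(0, 0, matrix(0))[1, 1], 0)
  expect_error(bliss_excess_grid(c(0, 1), 0.5, matrix(0.5)), "shape")
  expect_error(bliss_excess_grid(0.4, 0.5, matrix(1.2)), "\\[0, 1\\]")
})

test_that("excess is zero everywhere when observed equals the Bliss expectation", {
  kA <- seq(0, 1, length.out = 5)
  kB <- seq(0, 0.8, length.out = 4)
  observed <- outer(kA, kB, function(a, b) a + b - a * b)
  ex <- bliss_excess_grid(kA, kB, observed)
  expect_equal(max(abs(ex)), 0)
  g <- toy_grid(observed, seq_along(kA), seq_along(kB))
  s <- max_synergy(g, force = TRUE)
  expect_equal(s$bliss_score, 0)
})

test_that("max over grid and sub-IC50 restriction are scanned correctly", {
  doses <- c(0, 10, 100, 1000)
  kill <- matrix(0, 4, 4)
  kill[4, 4] <- 0.5   # supra-IC50 corner
  kill[2, 2] <- 0.2   # sub-IC50 cell
  g <- toy_grid(kill, doses, doses)
  s <- max_synergy(g, ic50_A = 500, ic50_B = 500, force = TRUE)
  expect_equal(s$bliss_score, 0.5)
  expect_equal(s$bliss_max_ic50, 0.2)
  expect_equal(unname(s$argmax_doses), c(1000, 1000))
  expect_gte(s$bliss_score, s$bliss_max_ic50)

  # brute-force scan oracle over the clamped excess
  ex <- pmax(bliss_excess_grid(g$killrate_A, g$killrate_B, g$killrate_AB), 0)
  expect_equal(s$bliss_score, max(ex))
  sub <- outer(doses < 500, doses < 500, `&`)
  expect_equal(s$bliss_max_ic50, max(ex[sub]))

  allzero <- max_synergy(toy_grid(matrix(0, 4, 4), doses, doses), force = TRUE)
  expect_equal(allzero$bliss_score, 0)
  expect_equal(allzero$bliss_max_ic50, 0)
})

test_that("swapping the two drugs transposes the excess and keeps the score", {
  set.seed(9)
  doses <- c(0, 1, 10, 100)
  kill <- matrix(runif(16, 0, 0.9), 4, 4)
  kill[1, 1] <- 0
  g1 <- toy_grid(kill, doses, doses)
  g2 <- toy_grid(t(kill), doses, doses, drugs = c("B", "A"))
  s1 <- max_synergy(g1, force = TRUE)
  s2 <- max_synergy(g2, force = TRUE)
  expect_equal(unname(s2$bliss_excess), unname(t(s1$bliss_excess)))
  expect_equal(s1$bliss_score, s2$bliss_score)
})

test_that("QC rejects rising marginal viability and passes lawful grids", {
  doses <- c(0, 10, 100, 1000)
  lawful <- outer(c(0, 0.2, 0.5, 0.9), c(0, 0.1, 0.4, 0.8),
                  function(a, b) pmin(a + b, 1))
  expect_true(qc_grid(toy_grid(lawful, doses, doses))$pass)

  # drug A's marginal viability rises 0.3 -> 0.9 along its axis
  bad <- lawful
  bad[, 1] <- c(0.7, 0.7, 0.4, 0.1)
  qc <- qc_grid(toy_grid(bad, doses, doses, drugs = c("drugX", "drugY")))
  expect_false(qc$pass)
  expect_true(any(grepl("drugX", qc$reasons)))

  inert <- toy_grid(matrix(0, 4, 4), doses, doses)
  expect_true(qc_grid(inert)$pass)

  nf <- lawful; nf[2, 2] <- NaN
  expect_false(qc_grid(toy_grid(nf, doses, doses))$pass)
})

test_that("1-D k-means discretization matches exhaustive partition search", {
  scores <- c(0, 0.01, 0.02, 0.5, 0.51, 0.95, 1.0)
  got <- discretize_synergy(scores)
  want <- oracle_kmeans_1d(scores, 3)
  expect_equal(got$centers, want$centers)
  expect_equal(as.vector(table(got$labels)), lengths(want$groups))
  expect_true(got$thresholds[["t1"]] < got$thresholds[["t2"]])

  # random score sets: k-means with restarts finds the optimal 1-D partition
  for (seed in c(31, 32)) {
    set.seed(seed)
    x <- round(runif(12), 3)
    if (length(unique(x)) < 3) next
    got <- discretize_synergy(x)
    want <- oracle_kmeans_1d(x, 3)
    expect_equal(got$centers, want$centers, tolerance = 1e-9)
  }

  expect_error(discretize_synergy(rep(0.5, 10)), "distinct")
  again <- discretize_synergy(scores)
  expect_identical(discretize_synergy(scores)$thresholds, again$thresholds)
})

test_that("combination enumeration counts anchored pairs", {
  pairs <- enumerate_combinations(paste0("ddr", 1:12), paste0("x", 1:46))
  expect_equal(nrow(pairs), 684)
  expect_equal(nrow(enumerate_combinations("d1", character(0))), 0)
  # brute force: 2 anchors, 1 partner -> (d1,d2),(d1,p),(d2,d1),(d2,p)
  got <- enumerate_combinations(c("d1", "d2"), "p")
  expect_equal(nrow(got), 4)
  expect_setequal(paste(got$anchor, got$partner),
                  c("d1 d2", "d1 p", "d2 d1", "d2 p"))
  expect_error(enumerate_combinations(c("a", "b"), c("b", "c")), "overlap")
})

test_that("dual-pathway blockade is synergistic on the redundant fixture; same-pathway is not", {
  av <- avatar_of("CL1")
  doses <- dose_grid()
  dual <- max_synergy(combination_screen(av, profile_of("DRUG_A"),
                                         profile_of("DRUG_B"), doses, doses,
                                         fast_cfg), force = TRUE)
  expect_gt(dual$bliss_score, 0.2)
  same <- max_synergy(combination_screen(av, profile_of("DRUG_A"),
                                         profile_of("DRUG_C"), doses, doses,
                                         fast_cfg), force = TRUE)
  expect_lt(same$bliss_score, 0.05)

  # the zero-dose row/column of the grid reproduces the monotherapy screens
  g <- combination_screen(av, profile_of("DRUG_A"), profile_of("DRUG_B"),
                          dose_grid(6), dose_grid(6), fast_cfg)
  mono_a <- monotherapy_screen(av, profile_of("DRUG_A"), dose_grid(6), fast_cfg)
  mono_b <- monotherapy_screen(av, profile_of("DRUG_B"), dose_grid(6), fast_cfg)
  expect_equal(g$killrate_A, mono_a$killrate, tolerance = 1e-9)
  expect_equal(g$killrate_B, mono_b$killrate, tolerance = 1e-9)
})

test_that("MoA aggregation reports group means and BH-adjusted pairwise tests", {
  set.seed(4)
  results <- tibble::tibble(
    moa_group = rep(c("DDR:DDR", "DDR:other"), each = 20),
    bliss_score = c(runif(20, 0.3, 0.7), runif(20, 0, 0.3)),
    killrate = runif(40)
  )
  out <- summarize_moa_synergy(results)
  expect_equal(out$summary$moa_group[1], "DDR:DDR")
  expect_equal(nrow(out$pairwise_tests), 1)
  expect_true(out$pairwise_tests$p_adj >= out$pairwise_tests$p_value - 1e-12)
  man <- suppressWarnings(stats::wilcox.test(
    results$bliss_score[results$moa_group == "DDR:DDR"],
    results$bliss_score[results$moa_group == "DDR:other"])$p.value)
  expect_equal(out$pairwise_tests$p_value, man)
})
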