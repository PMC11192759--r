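test_that("perturbation codes map to their parameter semantics", {
  expect_equal(perturbation("X", "0.0")$kind, "lof")
  expect_equal(perturbation("X", "mc5.0")$kind, "overexpress")
  expect_equal(perturbation("X", "gof")$code, "1.0")
  expect_equal(perturbation("X", "underexpress")$code, "mc0.3")
  expect_error(perturbation("X", "banana"), "unknown perturbation")

  av <- avatar_of("CL2")
  av$nodes$concentration[av$nodes$id == "DECOY1"] <- 2
  over <- apply_perturbation(av, perturbation("DECOY1", "overexpress"))
  expect_equal(over$nodes$concentration[over$nodes$id == "DECOY1"], 10)
  under <- apply_perturbation(av, perturbation("DECOY1", "underexpress"))
  expect_equal(under$nodes$concentration[under$nodes$id == "DECOY1"], 0.6)
  # original untouched
  expect_equal(av$nodes$concentration[av$nodes$id == "DECOY1"], 2)
  expect_error(apply_perturbation(av, perturbation("NOPE", "lof")),
               "unknown node")
})

test_that("lof and gof perturbations pin the node for the whole simulation", {
  av <- avatar_of("CL2")
  ko <- apply_perturbation(av, perturbation("RTK1", "lof"))
  tr <- run_trajectory(ko, sim_config(max_steps = 30, noise_sd = 0.1,
                                      rng_seed = 2))
  expect_true(all(tr$trajectory[, "RTK1"] == 0))
  up <- apply_perturbation(av, perturbation("K1", "gof"))
  tr2 <- run_trajectory(up, sim_config(max_steps = 30, noise_sd = 0.1,
                                       rng_seed = 2))
  expect_true(all(tr2$trajectory[, "K1"] == 1))
})

test_that("restoring the recorded node parameters inverts any perturbation exactly", {
  av <- avatar_of("CL1")
  for (kind in c("lof", "gof", "overexpress", "underexpress")) {
    p <- perturbation("K2", kind)
    saved <- av$nodes[av$nodes$id == "K2", ]
    pert <- apply_perturbation(av, p)
    pert$nodes[pert$nodes$id == "K2", ] <- saved
    expect_identical(pert$nodes, av$nodes)
  }
})

test_that("exact Wilcoxon p-values match full enumeration for all small layouts", {
  expect_equal(test_significance(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(test_significance(c(7, 7, 7), c(7, 7, 7)), 1)

  set.seed(77)
  for (n in 1:5) {
    for (m in seq_len(min(n, 10 - n))) {
      x <- round(rnorm(n), 6)
      y <- round(rnorm(m, 0.5), 6)
      if (any(duplicated(c(x, y)))) next
      expect_equal(test_significance(x, y), oracle_wilcoxon_exact(x, y),
                   tolerance = 1e-12,
                   label = sprintf("layout n=%d m=%d", n, m))
    }
  }
})

test_that("large well-separated samples are significant at the 0.001 level", {
  set.seed(8)
  x <- rnorm(50)
  y <- rnorm(50, mean = 3)
  expect_lt(test_significance(x, y), 0.001)
  # permutation oracle agreement within Monte-Carlo error
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[51:100])
  perm <- replicate(2000, {
    idx <- sample(100, 50)
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(p_perm, 0.005)
})

test_that("biomarker classes and scopes follow the shift/significance rules", {
  expect_equal(classify_biomarker(0.3, 0.1, 1e-5, 0, 0),
               list(class = "sensitivity", scope = "combination_specific"))
  expect_equal(classify_biomarker(-0.1, -0.4, 1e-5, 1.2, 0),
               list(class = "resistance", scope = "monotherapy_specific_A"))
  expect_equal(classify_biomarker(0.1, 0.4, 1e-5, 0.05, 0.9),
               list(class = "sensitivity", scope = "monotherapy_specific_B"))
  expect_equal(classify_biomarker(0.5, 0.5, 0.5, 0, 0),
               list(class = "none", scope = "none"))
})

test_that("the screen recovers the planted biomarkers and never flags decoys", {
  avs <- list(CL1 = avatar_of("CL1"), CL2 = avatar_of("CL2"))
  eff <- screen_biomarkers(avs, profile_of("DRUG_A"), profile_of("DRUG_B"),
                           the_bundle$perturbations,
                           sim_config(n_replicates = 15, rng_seed = 13))
  truth <- the_bundle$ground_truth$biomarkers
  for (k in seq_len(nrow(truth))) {
    row <- eff[eff$cell_line == truth$cell_line[k] & eff$node == truth$node[k] &
                 eff$kind == truth$kind[k], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$class,
                 if (truth$expected_sign[k] > 0) "sensitivity" else "resistance",
                 label = paste("planted biomarker", truth$node[k]))
    expect_equal(row$scope, truth$scope[k])
    expect_true(sign(row$synergy_shift) == truth$expected_sign[k])
    expect_lt(row$p_value, 0.001)
  }
  decoys <- eff[eff$node %in% c("DECOY1", "DECOY2"), ]
  expect_true(all(decoys$class == "none"))
  expect_true(all(decoys$synergy_shift == 0))
})
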