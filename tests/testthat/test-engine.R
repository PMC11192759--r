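test_that("a node with no inputs is a fixed point at its base activity", {
  net <- signaling_network(tibble::tibble(id = "A", base_activity = 0.7))
  a <- c(A = 0.7)
  for (i in 1:5) a <- sim_step(a, net)
  expect_equal(unname(a[["A"]]), 0.7, tolerance = 1e-9)
})

test_that("activity caps dominate any input", {
  net <- signaling_network(
    tibble::tibble(id = c("A", "B"), base_activity = c(0.9, 0),
                   activity_max = c(1, 0)),
    tibble::tibble(source = "A", target = "B", sign = 1, weight = 50)
  )
  a <- c(A = 0.9, B = 0)
  for (i in 1:10) a <- sim_step(a, net)
  expect_identical(unname(a[["B"]]), 0)
})

test_that("the two-node activator update matches the hand-iterated formula", {
  # A (pinned at 1) -> B with weight 3; B's bias is logit(0.1); conc 1 => chat 0.5
  net <- signaling_network(
    tibble::tibble(id = c("A", "B"), base_activity = c(1, 0.1)),
    tibble::tibble(source = "A", target = "B", sign = 1, weight = 3)
  )
  eps <- 1e-6
  logit <- function(p) log(pmin(pmax(p, eps), 1 - eps) / (1 - pmin(pmax(p, eps), 1 - eps)))
  sig <- function(x) 1 / (1 + exp(-x))
  a <- c(A = 1, B = 0.1)
  expected_a <- 1; expected_b <- 0.1
  for (t in 1:5) {
    new_b <- sig(logit(0.1) + 3 * expected_a * 0.5)
    expected_a <- sig(logit(1))   # bias-only node
    expected_b <- new_b
    a <- sim_step(a, net)
    expect_equal(unname(a[["B"]]), expected_b, tolerance = 1e-12)
  }
  expect_equal(unname(a[["B"]]), sig(logit(0.1) + 1.5 * sig(logit(1))),
               tolerance = 1e-9)
})

test_that("verdict rule is inclusive at both thresholds and apoptosis dominates", {
  expect_equal(compute_verdict(0.60, 0.20), "alive")
  expect_equal(compute_verdict(0.59, 0.00), "dead")
  expect_equal(compute_verdict(1.00, 0.21), "dead")
  expect_equal(compute_verdict(c(0.9, 0.2), c(0.1, 0.1)), c("alive", "dead"))
  expect_error(compute_verdict(1.2, 0), "\\[0, 1\\]")
})

test_that("trajectories respect activity bounds at every step", {
  for (seed in c(21, 22, 23)) {
    net <- random_network(seed)
    net$nodes$activity_min <- round(runif(nrow(net$nodes), 0, 0.2), 2)
    net$nodes$activity_max <- round(runif(nrow(net$nodes), 0.8, 1), 2)
    net$nodes$base_activity <- pmin(pmax(net$nodes$base_activity,
                                         net$nodes$activity_min),
                                    net$nodes$activity_max)
    tr <- run_trajectory(net, sim_config(max_steps = 60, noise_sd = 0.2,
                                         rng_seed = seed))
    lo <- matrix(net$nodes$activity_min, nrow(tr$trajectory),
                 ncol(tr$trajectory), byrow = TRUE)
    hi <- matrix(net$nodes$activity_max, nrow(tr$trajectory),
                 ncol(tr$trajectory), byrow = TRUE)
    expect_true(all(tr$trajectory >= lo - 1e-12))
    expect_true(all(tr$trajectory <= hi + 1e-12))
  }
})

test_that("ensembles are bit-identical under the same seed and diverge under another", {
  av <- avatar_of("CL1")
  e1 <- run_ensemble(av, NULL, sim_config(n_replicates = 8, rng_seed = 42))
  e2 <- run_ensemble(av, NULL, sim_config(n_replicates = 8, rng_seed = 42))
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$survival_fraction, e2$survival_fraction)
  e3 <- run_ensemble(av, NULL, sim_config(n_replicates = 8, rng_seed = 43))
  expect_false(identical(e1$replicates$cell_cycle_score,
                         e3$replicates$cell_cycle_score))
})

test_that("a noise-free bias-only network reaches its fixed point immediately", {
  net <- signaling_network(
    tibble::tibble(id = c("CC", "AP"), base_activity = c(0.9, 0.05),
                   readout = c("cell_cycle", "apoptosis"))
  )
  tr <- run_trajectory(net, sim_config(noise_sd = 0, rng_seed = 1))
  expect_equal(tr$attractor_type, "fixed_point")
  expect_lte(tr$steps, 2)
  expect_equal(tr$cell_cycle_score, 0.9, tolerance = 1e-6)
})

test_that("a strong negative feedback loop is detected as a limit cycle", {
  osc <- signaling_network(
    tibble::tibble(id = c("A", "B", "CC", "AP"),
                   base_activity = c(0.95, 0.05, 0.5, 0.5),
                   readout = c("none", "none", "cell_cycle", "apoptosis")),
    tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                   sign = c(1, -1), weight = 12)
  )
  tr <- run_trajectory(osc, sim_config(max_steps = 300, noise_sd = 0,
                                       rng_seed = 5))
  expect_equal(tr$attractor_type, "limit_cycle")
  expect_gt(tr$period, 1)
  ens <- run_ensemble(osc, NULL, sim_config(n_replicates = 5, noise_sd = 0.02,
                                            rng_seed = 5))
  expect_true(all(ens$replicates$attractor))
})

test_that("untreated fixture cells are alive and treated driver blockade kills", {
  av <- avatar_of("CL1")
  ens <- run_ensemble(av, NULL, fast_cfg)
  expect_equal(ens$survival_fraction, 1)
  expect_gte(ens$attractor_fraction, 0.999)

  # block both remaining survival pathways at saturating dose
  tr <- as_treatment(profile_of("DRUG_A"), profile_of("DRUG_B"),
                     dose_nM = c(10000, 10000))
  treated <- run_ensemble(av, tr, fast_cfg)
  expect_equal(treated$survival_fraction, 0)
})

test_that("survival is non-increasing in dose when the target drives the cell cycle", {
  spec <- fixture_spec(survival_logic = "AND", n_pathways = 2,
                       include_native_dead = FALSE)
  bundle <- make_fixture_bundle(spec)
  av <- fixture_avatar(bundle, "CL1")
  prof <- target_profile(filter_bioactivity(bundle$bioactivity), "DRUG_A")
  surv <- vapply(dose_grid(8), function(d) {
    trt <- if (d > 0) as_treatment(prof, dose_nM = d) else NULL
    run_ensemble(av, trt, fast_cfg)$survival_fraction
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
  expect_lt(surv[length(surv)], surv[1])
})

test_that("tidy and glance summarize ensembles consistently", {
  ens <- run_ensemble(avatar_of("CL2"), NULL, fast_cfg)
  td <- tidy(ens)
  expect_equal(nrow(td), fast_cfg$n_replicates)
  gl <- glance(ens)
  expect_equal(gl$survival_fraction, mean(td$verdict == "alive"))
})
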