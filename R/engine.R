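#' Simulation configuration
#'
#' @param max_steps Maximum number of discrete time steps (default 300; in
#'   practice trajectories settle far earlier and the run stops at the
#'   attractor).
#' @param n_replicates Number of noisy replicate trajectories per condition
#'   (default 100).
#' @param noise_sd Standard deviation of the multiplicative log-normal noise
#'   applied to initial activities and concentrations (default 0.05).
#' @param attractor_tol Fixed-point tolerance on the max absolute activity
#'   change per step (default 1e-6).
#' @param cycle_detection_window Number of recent states inspected for a
#'   recurring (rounded to 6 decimals) state, declaring a limit cycle
#'   (default 20).
#' @param rng_seed Master seed; every replicate draws its noise from a
#'   replicate-indexed substream so results are bit-reproducible.
#' @param cc_threshold,ap_threshold Verdict thresholds passed to
#'   [compute_verdict()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(max_steps = 300, n_replicates = 100, noise_sd = 0.05,
                       attractor_tol = 1e-6, cycle_detection_window = 20,
                       rng_seed = 1L, cc_threshold = 0.6, ap_threshold = 0.2) {
  assert_that(max_steps >= 1, "max_steps must be >= 1")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(attractor_tol > 0, "attractor_tol must be positive")
  structure(list(max_steps = as.integer(max_steps),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, attractor_tol = attractor_tol,
                 cycle_detection_window = as.integer(cycle_detection_window),
                 rng_seed = as.integer(rng_seed),
                 cc_threshold = cc_threshold, ap_threshold = ap_threshold),
            class = "sim_config")
}

# Precompute the dense matrices driving the update rule. `caps` (per-node
# activity ceilings from treatment) tighten activity_max.
engine_matrices <- function(avatar, caps = NULL) {
  nodes <- avatar$nodes
  n <- nrow(nodes)
  ids <- nodes$id
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(avatar$edges) > 0) {
    si <- match(avatar$edges$source, ids)
    ti <- match(avatar$edges$target, ids)
    W[cbind(si, ti)] <- avatar$edges$sign * avatar$edges$weight
  }
  amax <- nodes$activity_max
  if (!is.null(caps)) amax <- pmin(amax, caps[ids])
  amin <- pmin(nodes$activity_min, amax)  # a full drug cap overrides a GoF floor
  conc <- if ("concentration" %in% names(nodes)) {
    nodes$concentration
  } else {
    nodes$base_concentration
  }
  base <- clamp(nodes$base_activity, amin, amax)
  list(ids = ids, n = n, W = W, bias = clamped_logit(nodes$base_activity),
       amin = amin, amax = amax, base = base, conc = conc,
       cc_idx = which(nodes$readout == "cell_cycle"),
       ap_idx = which(nodes$readout == "apoptosis"))
}

# One synchronous update of an activity matrix (nodes x replicates).
# input_j = bias_j + sum_i sign_ij w_ij a_i chat_i ; a_j' = clamp(sigmoid(input_j))
step_matrix <- function(A, Chat, em) {
  inp <- em$bias + crossprod(em$W, A * Chat)
  if (!all(is.finite(inp))) rlang::abort("non-finite state during simulation")
  clamp(sigmoid(inp), em$amin, em$amax)
}

#' Advance a simulation state by one time step
#'
#' The discrete-time, continuous-valued update: each node j receives input
#' `bias_j + sum_i sign_ij * w_ij * a_i * c_i/(1+c_i)` where `bias_j` is the
#' (clamped) logit of its base activity, and the new activity is the logistic
#' of that input clamped to the node's activity bounds. A node with no
#' incoming edges therefore sits at its base activity; mutation- or drug-
#' capped nodes are held at their caps. Concentrations do not evolve.
#'
#' @param activities Named numeric vector of current activities (names =
#'   node ids) or unnamed in node-table order.
#' @param avatar A `cell_avatar` (or `signaling_network`).
#' @param treatments Optional treatment tibble (`target`, `affinity_nM`,
#'   `dose_nM`) whose caps are applied.
#' @return Named numeric vector of next-step activities.
#' @export
sim_step <- function(activities, avatar, treatments = NULL) {
  caps <- treatment_caps(treatments, avatar$nodes$id)
  em <- engine_matrices(avatar, caps)
  if (!is.null(names(activities))) activities <- activities[em$ids]
  A <- matrix(activities, ncol = 1)
  Chat <- matrix(conc_saturation(em$conc), ncol = 1)
  stats::setNames(as.vector(step_matrix(A, Chat, em)), em$ids)
}

# Replicate-substream seeds derived from the master seed.
replicate_seeds <- function(rng_seed, n_replicates) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  sample.int(.Machine$integer.max - 1L, n_replicates)
}

# Initial noisy state for one replicate: base values times exp(N(0, sd)),
# activities clamped to (possibly treatment-tightened) bounds.
init_state <- function(em, noise_sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- clamp(em$base * exp(stats::rnorm(em$n, 0, noise_sd)), em$amin, em$amax)
  conc <- em$conc * exp(stats::rnorm(em$n, 0, noise_sd))
  list(activities = a, conc = conc)
}

#' Run a single noisy trajectory to its attractor
#'
#' Iterates the synchronous update from a noisy initial condition until a
#' fixed point (max activity change below `attractor_tol`), a limit cycle
#' (a state, rounded to 6 decimals, recurring within
#' `cycle_detection_window` steps) or `max_steps`. Phenotype scores are the
#' mean activities of the cell-cycle and apoptosis readout nodes at the
#' attractor; for a limit cycle they are averaged over one period.
#'
#' @param avatar A `cell_avatar`.
#' @param config A [sim_config()].
#' @param replicate Replicate index selecting the noise substream.
#' @param treatments Optional treatment tibble (`target`, `affinity_nM`,
#'   `dose_nM`).
#' @return A list with `trajectory` (steps x nodes matrix), `attractor`
#'   (logical), `attractor_type` (`fixed_point`, `limit_cycle`, `none`),
#'   `period`, `steps`, `cell_cycle_score`, `apoptosis_score`, `verdict`.
#' @export
run_trajectory <- function(avatar, config = sim_config(), replicate = 1L,
                           treatments = NULL) {
  caps <- treatment_caps(treatments, avatar$nodes$id)
  em <- engine_matrices(avatar, caps)
  seed <- replicate_seeds(config$rng_seed, max(replicate, 1L))[replicate]
  st <- init_state(em, config$noise_sd, seed)
  Chat <- matrix(conc_saturation(st$conc), ncol = 1)
  A <- matrix(st$activities, ncol = 1)

  traj <- matrix(NA_real_, config$max_steps + 1L, em$n,
                 dimnames = list(NULL, em$ids))
  traj[1, ] <- A[, 1]
  window_keys <- character(0)
  attractor_type <- "none"
  period <- NA_integer_
  t_end <- config$max_steps

  for (t in seq_len(config$max_steps)) {
    A_new <- step_matrix(A, Chat, em)
    traj[t + 1L, ] <- A_new[, 1]
    if (max(abs(A_new - A)) < config$attractor_tol) {
      attractor_type <- "fixed_point"
      t_end <- t
      break
    }
    key <- paste(round(A_new[, 1], 6), collapse = ",")
    hit <- match(key, rev(window_keys))
    if (!is.na(hit)) {
      attractor_type <- "limit_cycle"
      period <- hit
      t_end <- t
      break
    }
    window_keys <- c(utils::tail(window_keys, config$cycle_detection_window - 1L), key)
    A <- A_new
  }
  traj <- traj[seq_len(t_end + 1L), , drop = FALSE]

  att_states <- if (attractor_type == "limit_cycle") {
    traj[seq(t_end + 1L - period + 1L, t_end + 1L), , drop = FALSE]
  } else {
    traj[t_end + 1L, , drop = FALSE]
  }
  cc <- if (length(em$cc_idx)) mean(att_states[, em$cc_idx]) else NA_real_
  ap <- if (length(em$ap_idx)) mean(att_states[, em$ap_idx]) else NA_real_

  list(trajectory = traj, attractor = attractor_type != "none",
       attractor_type = attractor_type, period = period, steps = t_end,
       cell_cycle_score = cc, apoptosis_score = ap,
       verdict = compute_verdict(cc, ap, config$cc_threshold, config$ap_threshold))
}

#' Cell-fate verdict from phenotype readout scores
#'
#' A simulated cell is called alive only when its cell-cycle readout reaches
#' at least 60% of maximum effect and its apoptotic readout is not activated
#' at more than 20%; active apoptosis kills the cell even with an intact cell
#' cycle.
#'
#' @param cell_cycle_score,apoptosis_score Scores in \[0, 1\] (mean readout
#'   node activity at the attractor).
#' @param cc_threshold Minimum cell-cycle score for life (default 0.6,
#'   inclusive).
#' @param ap_threshold Maximum tolerated apoptosis score (default 0.2,
#'   inclusive).
#' @return Character vector: `"alive"` or `"dead"`.
#' @export
#' @examples
#' compute_verdict(0.60, 0.20)  # alive (boundaries inclusive)
#' compute_verdict(0.59, 0.00)  # dead
#' compute_verdict(1.00, 0.21)  # dead
compute_verdict <- function(cell_cycle_score, apoptosis_score,
                            cc_threshold = 0.6, ap_threshold = 0.2) {
  ok <- stats::complete.cases(cell_cycle_score, apoptosis_score)
  rng <- c(cell_cycle_score[ok], apoptosis_score[ok])
  if (length(rng) && (any(rng < 0) || any(rng > 1))) {
    rlang::abort("readout scores must lie in [0, 1]")
  }
  ifelse(cell_cycle_score >= cc_threshold & apoptosis_score <= ap_threshold,
         "alive", "dead")
}

#' Run a replicate ensemble and summarize survival
#'
#' Runs `n_replicates` noisy trajectories of the avatar under a treatment and
#' summarizes them into a survival fraction (alive replicates / replicates)
#' and an attractor fraction (replicates reaching a stable attractor).
#' Replicates share the vectorized fast path; any replicate that has not
#' reached a fixed point at `max_steps` is re-examined individually for a
#' limit cycle. Fully reproducible for a given `rng_seed`.
#'
#' @param avatar A `cell_avatar`.
#' @param treatments `NULL` (untreated) or a tibble with columns `target`,
#'   `affinity_nM`, `dose_nM` — use [as_treatment()] to build one from target
#'   profiles and doses.
#' @param config A [sim_config()].
#' @return A `sim_ensemble` object: list with `replicates` tibble (one row
#'   per replicate: scores, verdict, attractor flag/type, steps),
#'   `survival_fraction`, `attractor_fraction`, `cell_line`, `config`.
#' @export
run_ensemble <- function(avatar, treatments = NULL, config = sim_config()) {
  report <- validate_network(avatar)
  if (nrow(report) > 0) {
    rlang::abort(c("avatar failed validation", report$message[1]))
  }
  caps <- treatment_caps(treatments, avatar$nodes$id)
  em <- engine_matrices(avatar, caps)
  nr <- config$n_replicates
  seeds <- replicate_seeds(config$rng_seed, nr)

  A <- matrix(NA_real_, em$n, nr)
  Chat <- matrix(NA_real_, em$n, nr)
  for (i in seq_len(nr)) {
    st <- init_state(em, config$noise_sd, seeds[i])
    A[, i] <- st$activities
    Chat[, i] <- conc_saturation(st$conc)
  }

  fixed <- rep(FALSE, nr)
  steps <- rep(config$max_steps, nr)
  for (t in seq_len(config$max_steps)) {
    A_new <- step_matrix(A, Chat, em)
    delta <- apply(abs(A_new - A), 2, max)
    newly <- !fixed & delta < config$attractor_tol
    steps[newly] <- t
    fixed <- fixed | newly
    A <- A_new
    if (all(fixed)) break
  }

  att_type <- ifelse(fixed, "fixed_point", "none")
  cc <- if (length(em$cc_idx)) colMeans(A[em$cc_idx, , drop = FALSE]) else rep(NA_real_, nr)
  ap <- if (length(em$ap_idx)) colMeans(A[em$ap_idx, , drop = FALSE]) else rep(NA_real_, nr)

  # slow path: limit-cycle detection for replicates without a fixed point
  for (i in which(!fixed)) {
    tr <- run_trajectory(avatar, config, replicate = i, treatments = treatments)
    att_type[i] <- tr$attractor_type
    steps[i] <- tr$steps
    cc[i] <- tr$cell_cycle_score
    ap[i] <- tr$apoptosis_score
  }

  verdict <- compute_verdict(cc, ap, config$cc_threshold, config$ap_threshold)
  replicates <- tibble(
    replicate = seq_len(nr), cell_cycle_score = cc, apoptosis_score = ap,
    verdict = verdict, attractor = att_type != "none",
    attractor_type = att_type, steps = steps
  )
  structure(list(
    replicates = replicates,
    survival_fraction = mean(verdict == "alive"),
    attractor_fraction = mean(att_type != "none"),
    cell_line = attr(avatar, "cell_line") %||% NA_character_,
    config = config
  ), class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> '%s': %d replicates, survival %.3f, attractor %.3f\n",
              x$cell_line, nrow(x$replicates), x$survival_fraction,
              x$attractor_fraction))
  invisible(x)
}

#' Combine target profiles and doses into a treatment table
#'
#' @param ... Target profile tibbles (see [target_profile()]).
#' @param dose_nM Numeric vector of doses, one per profile.
#' @return A treatment tibble with columns `drug`, `target`, `affinity_nM`,
#'   `dose_nM`, suitable for [run_ensemble()].
#' @export
as_treatment <- function(..., dose_nM) {
  profiles <- list(...)
  assert_that(length(profiles) == length(dose_nM),
              "need one dose per target profile")
  purrr::map2_dfr(profiles, dose_nM, function(p, d) {
    dplyr::mutate(as_tibble(p), dose_nM = d)
  })
}
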