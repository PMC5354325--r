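test_that("planted covariance is exactly block-diagonal in the independence case", {
  spec <- cohort_spec(n_participants = 2, age_grid = c(0, 0),
                      n_systems = 2, nodes_per_system = 4,
                      system_types = c("sensory-motor", "association"),
                      connector_fraction = 1 / 4,
                      rho_within = 0.36, rho_between = 0,
                      within_spread = 0, connector_boost = 0,
                      dediff_slope_within = 0, dediff_slope_between = 0)
  out <- plant_covariance(spec, age = 0.5)
  corr <- out$corr
  # loading sqrt(0.36) = 0.6 on the own factor only: within off-diagonals
  # are 0.36 exactly, cross-block entries 0
  expect_equal(diag(corr), rep(1, 8), ignore_attr = TRUE)
  within <- corr[1:4, 1:4][upper.tri(diag(4))]
  expect_equal(within, rep(0.36, 6), tolerance = 1e-12)
  expect_equal(max(abs(corr[1:4, 5:8])), 0)
})

test_that("age zero reproduces the baseline matrix entrywise", {
  spec <- small_spec()
  c0 <- plant_covariance(spec, 0)$corr
  c0b <- plant_covariance(spec, 0)$corr
  expect_identical(c0, c0b)
  # and ageing changes it
  c1 <- plant_covariance(spec, 1)$corr
  expect_gt(max(abs(c1 - c0)), 0.01)
})

test_that("planted matrix is a valid correlation matrix at all ages", {
  spec <- small_spec()
  for (a in c(0, 0.5, 1)) {
    corr <- plant_covariance(spec, a)$corr
    expect_equal(corr, t(corr))
    expect_equal(diag(corr), rep(1, nrow(corr)), ignore_attr = TRUE)
    expect_true(all(abs(corr[upper.tri(corr)]) < 1))
    expect_gt(min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("truth carries one system and one role per node, matching the connector fraction", {
  spec <- small_spec()
  truth <- plant_covariance(spec, 0)$truth
  expect_equal(nrow(truth$partition), 100)
  expect_false(any(is.na(truth$partition$system)))
  counts <- table(truth$partition$system,
                  truth$roles[truth$partition$node_id])
  expect_true(all(counts[, "connector"] == 10))
  expect_true(all(counts[, "non-connector"] == 10))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(connector_fraction = 0), "strictly between")
  expect_error(cohort_spec(nodes_per_system = 3), ">= 4")
  expect_error(cohort_spec(rho_within = 0.2, rho_between = 0.15,
                           within_spread = 0.1), "must exceed")
  expect_error(cohort_spec(system_types = c("visual", "a", "b", "c", "d")),
               "system_types")
})

test_that("participant generation is bitwise deterministic in the seed", {
  spec <- small_spec()
  p1 <- generate_participant(spec, age = 0.3, seed = 11)
  p2 <- generate_participant(spec, age = 0.3, seed = 11)
  expect_identical(p1$ts, p2$ts)
  expect_identical(p1$motion, p2$motion)
  expect_identical(p1$betas, p2$betas)
  p3 <- generate_participant(spec, age = 0.3, seed = 12)
  expect_false(identical(p1$ts, p3$ts))
})

test_that("empirical correlations converge to the planted matrix", {
  spec <- cohort_spec(n_participants = 1, age_grid = 0,
                      n_systems = 2, nodes_per_system = 5,
                      system_types = c("sensory-motor", "association"),
                      rho_within = 0.36, rho_between = 0,
                      within_spread = 0, connector_boost = 0,
                      n_frames = 10000, spike_prob = 0)
  p <- generate_participant(spec, age = 0, seed = 4)
  emp <- stats::cor(p$ts)
  planted <- plant_covariance(spec, 0)$corr
  within_mask <- planted > 0.3 & upper.tri(planted)
  expect_lt(abs(mean(emp[within_mask]) - 0.36), 0.02)
  expect_lt(max(abs(emp - planted)), 3 / sqrt(spec$n_frames) + 0.02)
})

test_that("motion traces respect the spike model", {
  spec <- small_spec(spike_prob = 0)
  p <- generate_participant(spec, age = 0, seed = 21)
  expect_true(all(compute_fd(p$motion) < 0.3))

  spec2 <- small_spec(spike_prob = 0.1)
  p2 <- generate_participant(spec2, age = 0, seed = 21)
  fd <- compute_fd(p2$motion)
  expect_gt(sum(fd > 0.3), 0)
  # spike frames reach approximately the configured FD magnitude
  expect_gt(max(fd), 0.9 * spec2$spike_fd_mm)
})

test_that("noiseless null betas are constant within system type", {
  spec <- small_spec(task_specs = list(
    flat = task_spec("sensory-motor",
                     c("sensory-motor" = 1, "association" = 0.5,
                       "default" = 0),
                     delta = 0, beta_noise_sd = 0)))
  p <- generate_participant(spec, age = 0, seed = 3)
  types <- p$truth$partition$system_type[match(p$betas$node_id,
                                               p$truth$partition$node_id)]
  for (tp in unique(types))
    expect_equal(stats::sd(p$betas$beta[types == tp]), 0)
})

test_that("planted connectors out-participate non-connectors at age 0", {
  spec <- small_spec()
  truth <- plant_covariance(spec, 0)$truth
  roles <- truth$roles
  diffs <- matrix(NA_real_, 5, spec$n_systems)
  for (s in 1:5) {
    p <- generate_participant(spec, age = 0, seed = 400 + s)
    sp <- suppressWarnings(
      summed_pc(participant_z(p), truth$partition, densities_band))
    for (sys in unique(truth$partition$system)) {
      in_sys <- truth$partition$system == sys
      diffs[s, match(sys, unique(truth$partition$system))] <-
        mean(sp$pc_sum[in_sys & roles == "connector"]) -
        mean(sp$pc_sum[in_sys & roles == "non-connector"])
    }
  }
  # in expectation over seeds, every system separates its roles
  expect_true(all(colMeans(diffs) > 0))
})

test_that("the planted PC gap is non-increasing in age on the noise-free matrix", {
  spec <- small_spec()
  truth <- plant_covariance(spec, 0)$truth
  roles <- truth$roles
  gaps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    sp <- suppressWarnings(
      summed_pc(planted_zmatrix(spec, a), truth$partition, densities_band))
    mean(sp$pc_sum[roles == "connector"]) -
      mean(sp$pc_sum[roles == "non-connector"])
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-9))
  expect_gt(gaps[1], gaps[5])
})

test_that("participant writers round-trip through their readers", {
  spec <- small_spec()
  p <- generate_participant(spec, age = 0.5, seed = 9)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "ts.tsv"); f2 <- file.path(td, "betas.tsv")
  write_timeseries_tsv(p$ts, f1)
  expect_equal(read_timeseries_tsv(f1), p$ts, ignore_attr = TRUE,
               tolerance = 0)
  write_betas_tsv(p$betas, f2)
  rb <- read_betas_tsv(f2)
  expect_identical(rb$beta, p$betas$beta)
  f3 <- file.path(td, "truth.json")
  write_truth_json(p$truth, f3)
  tr <- jsonlite::read_json(f3)
  expect_equal(tr$age, 0.5)
  expect_equal(unlist(tr$roles[["n001"]]), p$truth$roles[["n001"]],
               ignore_attr = TRUE)
})
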