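toy_partition <- function(n = 9) {
  partition_df(sprintf("n%03d", 1:n),
               rep(c("V", "FP", "DMN"), each = n / 3),
               rep(c("sensory-motor", "association", "default"), each = n / 3))
}

test_that("selectivity is the negated PC-beta correlation with known values", {
  part <- partition_df(c("a", "b", "c"), rep("S", 3),
                       rep("association", 3))
  pc <- stats::setNames(c(0.1, 0.5, 0.9), c("a", "b", "c"))

  beta_dec <- stats::setNames(5 - 2 * pc, names(pc))
  expect_equal(selectivity_score(pc, beta_dec, part)$score, 1)
  expect_equal(selectivity_score(pc, pc, part)$score, -1)

  # hand-computed three-point Pearson: r = -0.5 -> score 0.5
  beta <- stats::setNames(c(2.0, 1.0, 1.5), names(pc))
  out <- selectivity_score(pc, beta, part)
  expect_equal(out$score, 0.5, tolerance = 1e-12)
  expect_equal(out$n_nodes, 3)
})

test_that("default-system nodes are excluded unless requested", {
  part <- toy_partition()
  pc <- stats::setNames(seq(0.1, 0.9, length.out = 9), part$node_id)
  beta <- stats::setNames(rep(1, 9), part$node_id)
  beta[part$system_type == "default"] <- 100  # only matters if included
  beta[1:6] <- 6:1
  out <- selectivity_score(pc, beta, part)
  expect_equal(out$n_nodes, 6)
  out_incl <- selectivity_score(pc, beta, part, include_default = TRUE)
  expect_equal(out_incl$n_nodes, 9)
  expect_false(isTRUE(all.equal(out$score, out_incl$score)))
})

test_that("selectivity errors on degenerate inputs", {
  part <- toy_partition()
  pc <- stats::setNames(rep(0.5, 9), part$node_id)
  beta <- stats::setNames(rnorm(9), part$node_id)
  expect_error(selectivity_score(pc, beta, part), "constant")
  pc2 <- stats::setNames(seq_len(9) / 10, part$node_id)
  expect_error(selectivity_score(pc2, beta, part,
                                 node_mask = part$node_id[1:2]),
               "fewer than 3")
})

test_that("selectivity is invariant to beta shifts and positive scalings, and flips with negation", {
  part <- toy_partition()
  set.seed(1)
  pc <- stats::setNames(runif(9), part$node_id)
  beta <- stats::setNames(rnorm(9), part$node_id)
  s0 <- selectivity_score(pc, beta, part)$score
  expect_equal(selectivity_score(pc, beta + 5, part)$score, s0)
  expect_equal(selectivity_score(pc, beta * 3, part)$score, s0)
  expect_equal(selectivity_score(pc * 2, beta, part)$score, s0)
  expect_equal(selectivity_score(pc, -beta, part)$score, -s0)
})

test_that("system-type selectivity separates scopes", {
  part <- toy_partition(12)
  set.seed(7)
  pc <- stats::setNames(runif(12), part$node_id)
  beta <- stats::setNames(rnorm(12, 1), part$node_id)
  # plant anti-relation only in the sensory-motor scope
  sm <- part$system_type == "sensory-motor"
  beta[sm] <- 2 - pc[sm] * 1.5
  out <- system_type_selectivity(pc, beta, part)
  expect_equal(out$scope, c("sensory-motor", "association"))
  expect_equal(out$score[1], 1)
  expect_lt(abs(out$score[2]), 1)
})

test_that("activation means by node type are cell means with empty-cell errors", {
  part <- toy_partition(12)
  roles <- data.frame(node_id = part$node_id,
                      role = rep(c("connector", "non-connector"), 6),
                      stringsAsFactors = FALSE)
  beta <- stats::setNames(rep(2, 12), part$node_id)
  out <- activation_by_node_type(beta, roles, part)
  expect_equal(nrow(out), 4)
  expect_true(all(out$mean_beta == 2))

  beta2 <- stats::setNames(seq_len(12), part$node_id)
  out2 <- activation_by_node_type(beta2, roles, part)
  cell <- out2[out2$system_type == "sensory-motor" &
                 out2$role == "connector", ]
  expect_equal(cell$mean_beta, mean(c(1, 3)))

  roles_bad <- roles
  roles_bad$role[roles_bad$node_id %in% part$node_id[1:4]] <- "connector"
  roles_bad$role[5:12] <- "connector"
  expect_error(activation_by_node_type(beta, roles_bad, part), "empty cell")
})

test_that("role permutation test centers on zero and detects a planted bonus", {
  set.seed(10)
  n <- 80
  roles <- data.frame(node_id = sprintf("n%03d", 1:n),
                      role = rep(c("connector", "non-connector"), n / 2),
                      stringsAsFactors = FALSE)
  beta_null <- stats::setNames(rnorm(n), roles$node_id)
  out <- role_permutation_test(beta_null, roles, n_perm = 500, seed = 2)
  expect_lt(abs(mean(out$null)), 0.05)
  expect_gt(out$p, 0.05)

  beta_sig <- beta_null
  beta_sig[roles$role == "non-connector"] <-
    beta_sig[roles$role == "non-connector"] + 1.5
  out2 <- role_permutation_test(beta_sig, roles, n_perm = 500, seed = 2)
  expect_gt(out2$observed, out2$ci95[2])
  expect_lt(out2$p, 0.01)
})

test_that("cohort summary reports age correlations and trends", {
  ages <- stats::setNames(seq(0, 1, length.out = 12),
                          sprintf("p%02d", 1:12))
  scores <- data.frame(participant = names(ages), task = "t",
                       scope = "all",
                       score = 1 - ages + 0,   # perfect negative trend
                       stringsAsFactors = FALSE)
  out <- cohort_summary(scores, ages)
  expect_equal(out$r_age, -1)
  expect_equal(out$n, 12)
  trend <- attr(out, "trend")[["t:all"]]
  expect_equal(nrow(trend), 25)
  expect_lt(trend$fitted[25], trend$fitted[1])

  scores$score <- 0.5
  expect_error(cohort_summary(scores, ages), "constant")
  expect_error(cohort_summary(scores[1:3, ], ages), "at least 4")
})
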