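test_that("participation coefficient matches hand-derived values", {
  # star node 1 with all weight inside its own system -> PC 0
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 1
  part <- partition_df(sprintf("n%03d", 1:4), rep("A", 4))
  pc <- participation_coefficient(graph_from_weights(w), part)
  expect_equal(unname(pc[1]), 0)

  # equal split over 4 systems -> 1 - 4 * (1/4)^2 = 0.75
  w2 <- matrix(0, 5, 5)
  w2[1, 2:5] <- w2[2:5, 1] <- 1
  part2 <- partition_df(sprintf("n%03d", 1:5), c("A", "A", "B", "C", "D"))
  pc2 <- suppressWarnings(
    participation_coefficient(graph_from_weights(w2), part2))
  expect_equal(unname(pc2[1]), 0.75)

  # weights {own 2, B 1, C 1} -> 1 - (0.5^2 + 0.25^2 + 0.25^2) = 0.625
  w3 <- matrix(0, 4, 4)
  w3[1, 2] <- w3[2, 1] <- 2
  w3[1, 3] <- w3[3, 1] <- 1
  w3[1, 4] <- w3[4, 1] <- 1
  part3 <- partition_df(sprintf("n%03d", 1:4), c("A", "A", "B", "C"))
  pc3 <- suppressWarnings(
    participation_coefficient(graph_from_weights(w3), part3))
  expect_equal(unname(pc3[1]), 0.625)

  # literal-text variant omits the own-system term: fully-within node -> 1
  pcl <- participation_coefficient(graph_from_weights(w), part,
                                   variant = "literal")
  expect_equal(unname(pcl[1]), 1)
})

test_that("module PC equals the naive double-loop oracle on random graphs", {
  set.seed(23)
  for (k in 1:40) {
    n <- sample(5:30, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2) *
      (runif(n * (n - 1) / 2) < 0.4)
    w <- w + t(w)
    sys <- sample(LETTERS[seq_len(sample(2:6, 1))], n, replace = TRUE)
    part <- partition_df(sprintf("n%03d", seq_len(n)), sys)
    g <- graph_from_weights(w)
    for (v in c("standard", "literal")) {
      got <- suppressWarnings(participation_coefficient(g, part, variant = v))
      want <- naive_pc(g, part, variant = v)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("PC stays within its theoretical range", {
  set.seed(31)
  n <- 25
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  S <- 5
  part <- partition_df(sprintf("n%03d", 1:n),
                       rep(LETTERS[1:S], length.out = n))
  pc <- participation_coefficient(graph_from_weights(w), part)
  expect_true(all(pc >= 0))
  expect_true(all(pc <= 1 - 1 / S + 1e-12))
})

test_that("edges to unassigned-system nodes are excluded from PC", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1   # own system
  w[1, 3] <- w[3, 1] <- 1   # other system
  w[1, 4] <- w[4, 1] <- 5   # unassigned, must be ignored
  part <- partition_df(sprintf("n%03d", 1:4),
                       c("A", "A", "B", "unassigned"))
  pc <- suppressWarnings(participation_coefficient(graph_from_weights(w), part))
  expect_equal(unname(pc[1]), 0.5)

  # nodes whose only neighbors are unassigned get PC 0 with a warning
  w5 <- matrix(0, 3, 3)
  w5[1, 2] <- w5[2, 1] <- 1
  w5[1, 3] <- w5[3, 1] <- 2
  part5 <- partition_df(sprintf("n%03d", 1:3), c("unassigned", "A", "A"))
  expect_warning(
    pc5 <- participation_coefficient(graph_from_weights(w5), part5),
    "no retained weight")
  expect_equal(unname(pc5[2]), 0)
  expect_equal(unname(pc5[3]), 0)
})

test_that("summed PC equals independently recomputed per-density PCs", {
  spec <- small_spec()
  zm <- planted_zmatrix(spec, 0)
  truth <- plant_covariance(spec, 0)$truth
  sp <- suppressWarnings(summed_pc(zm, truth$partition, densities_band))
  manual <- rowSums(vapply(densities_band, function(d)
    unname(naive_pc(threshold_density(zm, d), truth$partition)),
    numeric(length(zm$node_id))))
  expect_lt(max(abs(unname(sp$pc_sum) - manual)), 1e-10)

  one <- suppressWarnings(summed_pc(zm, truth$partition, 0.05))
  expect_equal(one$pc_sum, one$pc_by_density[, 1])
})

test_that("connector classification applies the within-system median rule", {
  pc <- stats::setNames(c(0.2, 0.4, 0.6), c("a", "b", "c"))
  part <- partition_df(c("a", "b", "c"), rep("S", 3))
  out <- classify_connectors(pc, part)
  expect_equal(out$role, c("non-connector", "non-connector", "connector"))

  # two nodes with distinct PCs split evenly
  pc2 <- stats::setNames(c(0.1, 0.9), c("a", "b"))
  out2 <- classify_connectors(pc2, partition_df(c("a", "b"), c("S", "S")))
  expect_equal(sort(out2$role), c("connector", "non-connector"))

  # all equal -> all non-connector (ties go below the median)
  pc3 <- stats::setNames(rep(0.5, 4), letters[1:4])
  out3 <- classify_connectors(pc3, partition_df(letters[1:4], rep("S", 4)))
  expect_true(all(out3$role == "non-connector"))

  # unassigned nodes are excluded; tiny systems error
  pc4 <- stats::setNames(c(0.1, 0.2, 0.3), letters[1:3])
  out4 <- classify_connectors(
    pc4, partition_df(letters[1:3], c("S", "S", "unassigned")))
  expect_equal(out4$role[3], "excluded")
  expect_error(
    classify_connectors(pc4, partition_df(letters[1:3], c("S", "S", "T"))),
    "fewer than 2")
})

test_that("no system ever has more connectors than non-connectors", {
  set.seed(44)
  for (k in 1:20) {
    n <- sample(6:40, 1)
    pc <- stats::setNames(round(runif(n), 2), sprintf("n%03d", 1:n))
    sys <- sample(c("A", "B"), n, replace = TRUE)
    if (min(table(sys)) < 2) next
    out <- classify_connectors(pc, partition_df(names(pc), sys))
    for (s in unique(sys)) {
      tab <- table(out$role[out$system == s])
      n_conn <- if ("connector" %in% names(tab)) tab[["connector"]] else 0
      n_nc <- if ("non-connector" %in% names(tab)) tab[["non-connector"]] else 0
      expect_lte(n_conn, n_nc)
    }
  }
})
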