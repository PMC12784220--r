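two_cliques <- function(sizes = c(4, 4), bridge = 1) {
  n <- sum(sizes)
  W <- matrix(0, n, n)
  W[seq_len(sizes[1]), seq_len(sizes[1])] <- 1
  W[(sizes[1] + 1):n, (sizes[1] + 1):n] <- 1
  diag(W) <- 0
  if (bridge > 0) W[sizes[1], sizes[1] + 1] <- W[sizes[1] + 1, sizes[1]] <- bridge
  W
}

test_that("ROI selection applies the strict counting rule", {
  T <- matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(select_rois(T), character(0))
  T[1, "a"] <- 2.5                       # |T| > 1.96 in exactly 1 of 10
  T[1, "b"] <- 1.96                      # exactly at threshold: not counted
  T[1:2, "c"] <- -3                      # negative activations count via |T|
  expect_identical(select_rois(T), c("a", "c"))
  expect_error(select_rois(T[0, , drop = FALSE]), "empty")
})

test_that("inter-subject correlation matches hand computation", {
  set.seed(4)
  B <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, paste0("r", 1:5)))
  B[, 2] <- B[, 1]                       # duplicate
  B[, 3] <- -B[, 1]                      # negation
  net <- intersubject_correlation(B)
  expect_equal(net$weights[1, 2], 1)
  expect_equal(net$weights[1, 3], -1)
  expect_equal(unname(diag(net$weights)), rep(0, 5))
  # hand-computed covariance / sd quotient for an independent pair
  x <- B[, 4]; y <- B[, 5]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(net$weights[4, 5], r_hand, tolerance = 1e-12)
  B[, 5] <- 7
  expect_error(intersubject_correlation(B), "r5")
})

test_that("modularity matches hand-computed clique values", {
  W <- two_cliques()
  expect_equal(modularity_q(W, rep(1, 8), gamma = 1), 0)
  expect_equal(modularity_q(W, rep(1:2, each = 4), gamma = 1), 12 / 13 - 1 / 2,
               tolerance = 1e-12)
  split_part <- c(1, 1, 3, 3, 2, 2, 2, 2)
  expect_lt(modularity_q(W, split_part, gamma = 1), 12 / 13 - 1 / 2)
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "no positive weight")
})

test_that("the clique partition is the exhaustive modularity optimum", {
  W <- two_cliques()
  bo <- brute_modularity_optimum(W, gamma = 1)
  expect_equal(bo$q, 12 / 13 - 1 / 2, tolerance = 1e-12)
  expect_equal(bo$membership, rep(1:2, each = 4))
})

test_that("Louvain recovers planted structure on canonical graphs", {
  W <- two_cliques(c(5, 5), bridge = 0)
  p <- louvain_partition(W, gamma = 1, seed = 3)
  expect_equal(p$n_modules, 2)
  expect_equal(p$q, brute_modularity_optimum(W, 1)$q, tolerance = 1e-12)
  clique6 <- matrix(1, 6, 6); diag(clique6) <- 0
  expect_equal(louvain_partition(clique6, gamma = 1, seed = 1)$n_modules, 1)
})

test_that("Louvain attains the exhaustive optimum on random small graphs", {
  set.seed(11)
  for (g in 1:8) {
    n <- sample(4:7, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.6)
    W <- W + t(W)
    if (sum(W) == 0) next
    gamma <- sample(c(0.8, 1, 1.2), 1)
    q_best <- max(vapply(1:5, function(s)
      louvain_partition(W, gamma, seed = s)$q, 0))
    expect_equal(q_best, brute_modularity_optimum(W, gamma)$q,
                 tolerance = 1e-9)
  }
})

test_that("Louvain recovers a noise-free planted correlation network", {
  coh <- small_cohort(seed = 9, module_sizes = c(8, 8, 8), n_subgroups = 3,
                      roi_noise_sd = 0.02, module_factor_sd = 0.3)
  mods <- coh$truth$roi_module
  active <- names(mods)[mods > 0]
  net <- intersubject_correlation(coh$betas, active)
  p <- louvain_partition(net, gamma = 1.2, seed = 5)
  expect_equal(adjusted_mutual_information(p, mods[active]), 1)
})

test_that("partition quality beats the trivial partitions", {
  coh <- small_cohort(seed = 30)
  net <- intersubject_correlation(coh$betas,
                                  names(coh$truth$roi_module))
  p <- louvain_partition(net, gamma = 1, seed = 2)
  n <- length(p$membership)
  expect_gte(p$q, modularity_q(net, rep(1, n), 1))
  expect_gte(p$q, modularity_q(net, seq_len(n), 1))
})

test_that("AMI is 1 for identical partitions up to relabelling", {
  l <- rep(1:3, each = 5)
  expect_equal(adjusted_mutual_information(l, l), 1)
  expect_equal(adjusted_mutual_information(l, c(9, 2, 5)[l]), 1)
  expect_error(adjusted_mutual_information(l, l[-1]), "same nodes")
})

test_that("AMI matches the brute-force expected-MI evaluation", {
  l1 <- c(1, 1, 2, 2, 3, 3)
  l2 <- c(1, 2, 2, 3, 3, 3)
  expect_equal(adjusted_mutual_information(l1, l2), ami_oracle(l1, l2),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_mutual_information(a, b), ami_oracle(a, b),
                 tolerance = 1e-10)
    expect_equal(adjusted_mutual_information(a, b),
                 adjusted_mutual_information(b, a), tolerance = 1e-10)
  }
})

test_that("AMI of independent random partitions is near zero", {
  set.seed(6)
  vals <- replicate(100, {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:4, 200, replace = TRUE)
    adjusted_mutual_information(a, b)
  })
  expect_lt(mean(abs(vals)), 0.05)
})

test_that("consensus returns immediately when all repetitions agree", {
  W <- two_cliques(c(5, 5), bridge = 0)
  cp <- consensus_partition(W, gamma = 1,
                            config = consensus_config(n_repetitions = 20,
                                                      null_permutations = 10,
                                                      seed = 3))
  expect_equal(cp$n_iterations, 1)
  expect_equal(unname(cp$partition$membership), rep(1:2, each = 5))
  ag <- cp$agreement
  expect_true(all(ag >= 0 & ag <= 1))
  expect_true(all(ag[1:5, 1:5][upper.tri(diag(5))] == 1))
})

test_that("consensus recovers a planted two-module network", {
  amis <- vapply(1:5, function(s) {
    coh <- small_cohort(seed = 100 + s)
    mods <- coh$truth$roi_module
    active <- names(mods)[mods > 0]
    net <- intersubject_correlation(coh$betas, active)
    cp <- consensus_partition(net, gamma = 1,
                              config = consensus_config(n_repetitions = 50,
                                                        null_permutations = 10,
                                                        seed = s))
    adjusted_mutual_information(cp$partition, mods[active])
  }, 0)
  expect_gte(mean(amis), 0.9)
})

test_that("consensus on a pure-noise network carries no planted signal", {
  set.seed(40)
  B <- matrix(rnorm(60 * 24), 60, 24,
              dimnames = list(NULL, paste0("r", 1:24)))
  net <- intersubject_correlation(B)
  cp <- consensus_partition(net, gamma = 1,
                            config = consensus_config(n_repetitions = 50,
                                                      null_permutations = 10,
                                                      seed = 8))
  planted <- rep(1:2, each = 12)
  expect_lt(abs(adjusted_mutual_information(cp$partition, planted)), 0.1)
})

test_that("gamma sweep selects by AMI and filters small modules", {
  expect_equal(eval(formals(choose_gamma)$gamma_grid), seq(1, 1.5, by = 0.05))
  coh <- small_cohort(seed = 55, module_sizes = c(12, 12, 12), n_subgroups = 3)
  mods <- coh$truth$roi_module
  active <- names(mods)[mods > 0]
  net <- intersubject_correlation(coh$betas, active)
  cfg <- consensus_config(n_repetitions = 30, null_permutations = 10, seed = 2)
  cg <- choose_gamma(net, gamma_grid = c(1, 1.25), reference = mods[active],
                     min_module_size = 5, config = cfg)
  expect_equal(cg$partition$ami_vs_reference, max(cg$diagnostics$ami))
  expect_gte(cg$partition$ami_vs_reference, 0.9)
  expect_error(choose_gamma(net, gamma_grid = c(1), reference = mods[active],
                            min_module_size = 50, config = cfg),
               "min_module_size")
})
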