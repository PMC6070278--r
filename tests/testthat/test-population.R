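test_that("kernel entries combine fitness with the Wright-Fisher marginal", {
  net <- network_fixture("keystone_recycler")
  p <- lifecycle_params(N = 4, q = 0.9, g = 2)
  ker <- build_kernel(net, p)
  expect_true(ker$include_sink)
  # columns match Phi(m) * marginal(m | j) for a few source compositions
  for (r in c(1L, 5L, nrow(ker$lattice))) {
    j <- ker$lattice[r, ]
    marg <- lifecycle_offspring_marginal(j, p)
    idx <- apply(marg$counts, 1, paste, collapse = ",")
    kidx <- apply(ker$lattice, 1, paste, collapse = ",")
    expect_equal(ker$K[, r], (ker$Phi * marg$prob[match(kidx, idx)]),
                 tolerance = 1e-12)
  }
  # the all-omega source is a dead lineage: its column has zero mass
  allo <- which(ker$lattice[, 3] == 4)
  expect_equal(sum(ker$K[, allo]), 0)
  expect_error(build_kernel(net, lifecycle_params(N = 4, q = 1, g = 3)),
               "does not match")
  expect_error(build_kernel(net, lifecycle_params(N = 4, q = 0.9, g = 2),
                            include_sink = FALSE), "cannot be dropped")
})

test_that("keystone-only kernel at q = 1 reduces to a flux-weighted binomial", {
  # g = 1 network: one keystone, no intermediates
  net <- network_spec(
    list(metabolite("A", "environmental_input"),
         metabolite("M", "critical_output")),
    list(catalyst("alpha", 2, "A", c(M = 1), saturated = TRUE)),
    name = "keystone_only")
  N <- 6
  p <- lifecycle_params(N = N, q = 1, g = 1)
  ker <- build_kernel(net, p, include_sink = TRUE)
  for (j in 0:N) {                         # alpha count of the source
    col <- which(ker$lattice[, 1] == j)
    expected <- (2 * ker$lattice[, 1]) *
      stats::dbinom(ker$lattice[, 1], N, j / N)
    expect_equal(ker$K[, col], expected, tolerance = 1e-12)
  }
  st <- stationary_distribution(ker)
  expect_equal(st$F[which(ker$lattice[, 1] == N)], 1, tolerance = 1e-9)
  expect_equal(st$W_bar, 2 * N, tolerance = 1e-9)
})

test_that("power iteration solves the eigen problem and flags degeneracy", {
  net <- network_fixture("keystone_recycler")
  p <- lifecycle_params(N = 12, q = 1, g = 2)
  ker <- build_kernel(net, p)
  st <- stationary_distribution(ker)
  expect_true(all(st$F >= 0))
  expect_equal(sum(st$F), 1, tolerance = 1e-12)
  # residual of the eigen equation, and agreement with a dense eigen solve
  expect_lte(sum(abs(ker$K %*% st$F - st$W_bar * st$F)) / st$W_bar, 1e-11)
  ev <- eigen(ker$K)
  v <- Re(ev$vectors[, 1]); v <- v / sum(v)
  expect_equal(st$F, v, tolerance = 1e-8)
  expect_equal(st$W_bar, Re(ev$values[1]), tolerance = 1e-10)
  # neutral fitness: mean fitness is exactly 1
  nk <- build_kernel(neutral_flux(1), lifecycle_params(N = 4, q = 0.9, g = 1),
                     include_sink = TRUE)
  expect_equal(stationary_distribution(nk)$W_bar, 1, tolerance = 1e-9)
  # identically-zero flux is rejected
  zk <- build_kernel(neutral_flux(1, value = 0),
                     lifecycle_params(N = 2, q = 1, g = 1),
                     include_sink = TRUE)
  expect_error(stationary_distribution(zk), "identically zero")
})

test_that("pps selection has linear inclusion probabilities; successive draws match enumeration", {
  set.seed(21)
  # weights (2,1,1), keep 2 of 3: successive-draw inclusion of index 1 is 5/6
  hits_succ <- hits_pps <- integer(3)
  nrep <- 8000
  for (i in seq_len(nrep)) {
    s <- select_half_without_replacement(c(2, 1, 1), 2, method = "successive")
    hits_succ[s] <- hits_succ[s] + 1L
    s <- select_half_without_replacement(c(2, 1, 1), 2, method = "pps")
    hits_pps[s] <- hits_pps[s] + 1L
  }
  se <- sqrt(5 / 6 * 1 / 6 / nrep)
  expect_lt(abs(hits_succ[1] / nrep - 5 / 6), 4 * se)
  # pps: inclusion probabilities exactly proportional to weight (1, .5, .5)
  expect_equal(hits_pps[1] / nrep, 1, tolerance = 1e-12)
  expect_lt(abs(hits_pps[2] / nrep - 0.5), 4 * sqrt(0.25 / nrep))

  # equal weights: uniformly random subset
  set.seed(22)
  cnt <- integer(4)
  for (i in 1:4000) {
    s <- select_half_without_replacement(rep(1, 4), 2)
    cnt[s] <- cnt[s] + 1L
  }
  expect_true(all(abs(cnt / 4000 - 0.5) < 4 * sqrt(0.25 / 4000)))

  # zero weights are never selected; too few positives is an error
  for (m in c("pps", "successive")) {
    s <- replicate(200, select_half_without_replacement(c(0, 1, 2, 3), 3,
                                                        method = m))
    expect_false(any(s == 1L))
  }
  expect_error(select_half_without_replacement(c(0, 0, 1), 2), "positive")
})

test_that("agent-based runs are reproducible, conservative and handle extinction", {
  net <- network_fixture("keystone_recycler")
  p <- lifecycle_params(N = 8, q = 0.95, g = 2)
  a1 <- run_agent_based(net, p, pop_size = 50, generations = 40, seed = 77)
  a2 <- run_agent_based(net, p, pop_size = 50, generations = 40, seed = 77)
  expect_identical(a1$series, a2$series)
  expect_identical(a1$population, a2$population)
  expect_true(all(rowSums(a1$population) == 8))
  expect_error(run_agent_based(net, p, pop_size = 51, generations = 5), "even")

  # an all-defective start has zero flux everywhere: extinction is signalled
  dead <- run_agent_based(net, p, pop_size = 20, generations = 10,
                          init = c(0, 0, 8), seed = 1)
  expect_identical(dead$status, "extinct")
  expect_null(dead$stationary)

  # q = 1 keystone-only: the homogeneous state is absorbing
  keyonly <- network_spec(
    list(metabolite("A", "environmental_input"),
         metabolite("M", "critical_output")),
    list(catalyst("alpha", 1, "A", c(M = 1), saturated = TRUE)),
    name = "keystone_only")
  ab <- run_agent_based(keyonly, lifecycle_params(N = 5, q = 1, g = 1),
                        pop_size = 30, generations = 30, seed = 3)
  expect_true(all(ab$population[, 1] == 5))
  expect_equal(ab$stationary$coexistence, 1)
})

test_that("agent-based stationary observables agree with the exact solver", {
  net <- network_fixture("keystone_recycler")
  p <- lifecycle_params(N = 10, q = 1, g = 2)
  st <- stationary_distribution(build_kernel(net, p))
  cx <- mf <- numeric(3)
  for (s in 1:3) {
    ab <- run_agent_based(net, p, pop_size = 500, generations = 1200,
                          seed = 500 + s)
    cx[s] <- coexistence_fraction(ab)
    mf[s] <- as.numeric(mean_flux(ab))
  }
  expect_lt(abs(mean(cx) - coexistence_fraction(st)),
            3 * stats::sd(cx) / sqrt(3) + 0.02)
  expect_lt(abs(mean(mf) - st$W_bar), 3 * stats::sd(mf) / sqrt(3) + 0.15)
})
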