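test_that("mm_velocity follows the Michaelis-Menten form and bounds", {
  expect_identical(mm_velocity(0, 5, 2, 1), 0)
  expect_identical(mm_velocity(1, 1, 2, 1), 1)          # half saturation
  expect_equal(mm_velocity(1, 1e12, 2, 1), 2, tolerance = 1e-10)  # saturation
  set.seed(1)
  S <- sort(runif(50, 0, 50))
  v <- mm_velocity(3, S, 2, 0.7)
  expect_true(all(diff(v) >= 0))            # monotone in substrate
  expect_true(all(v <= 2 * 3))              # limiting velocity bound
  expect_error(mm_velocity(-1, 1, 1, 1), "nonnegative")
  expect_error(mm_velocity(1, 1, 1, 0), "Km")
})

test_that("piecewise motif velocities take the min of flux and capacity", {
  expect_identical(motif_flux_uni(3, 5, 1), 3)    # substrate-limited
  expect_identical(motif_flux_uni(7, 5, 1), 5)    # enzyme-limited
  expect_identical(motif_flux_uni(0, 5, 1), 0)
  expect_identical(motif_flux_bi(2, 3, 5, 1), 2)
  expect_identical(motif_flux_bi(0, 9, 1, 1), 0)
  expect_identical(motif_flux_bi(9, 9, 4, 1), 4)
  expect_error(motif_flux_uni(-1, 1, 1), "negative")
})

test_that("leaky unimolecular velocity matches the bisection oracle and its limits", {
  set.seed(42)
  for (i in 1:50) {
    j <- runif(1, 0, 10); E <- runif(1, 0, 10)
    Km <- runif(1, 0.2, 3); delta <- 10^runif(1, -4, -0.5)
    v <- motif_flux_uni_delta(j, E, 1.3, Km, delta)
    expect_equal(v, bisect_uni_root(j, 1.3 * E, Km, delta), tolerance = 1e-9)
    # strictly below the piecewise value, implied [S] nonnegative
    if (j > 0 && E > 0) expect_lt(v, min(j, 1.3 * E))
    expect_gte(j - v, 0)
  }
  # continuity with the zero-leak limit
  expect_equal(motif_flux_uni_delta(3, 5, 1, 1, 1e-9), 3, tolerance = 1e-7)
  expect_equal(motif_flux_uni_delta(7, 5, 1, 1, 1e-9), 5, tolerance = 1e-7)
  # at the kink j = kcat E the gap closes like sqrt(delta * Km)
  for (delta in c(1e-3, 1e-5)) {
    gap <- 1 - motif_flux_uni_delta(1, 1, 1, 1, delta)
    expect_gt(gap, 0.5 * sqrt(delta))
    expect_lt(gap, 2 * sqrt(delta))
  }
})

test_that("leaky bimolecular velocity is kinetically consistent and continuous", {
  set.seed(43)
  for (i in 1:40) {
    j1 <- runif(1, 0.1, 8); j2 <- runif(1, 0.1, 8); E <- runif(1, 0.1, 8)
    kcat <- runif(1, 0.5, 2); Km <- runif(1, 0.2, 2)
    a1 <- runif(1, 0, 2); a2 <- runif(1, 0, 2)
    delta <- 10^runif(1, -4, -1)
    v <- motif_flux_bi_delta(j1, j2, E, kcat, Km, a1, a2, delta)
    S1 <- (j1 - v) / delta; S2 <- (j2 - v) / delta
    expect_gte(S1, -1e-8); expect_gte(S2, -1e-8)
    # the root satisfies the original two-substrate rate law
    rate <- kcat * E * S1 * S2 / (Km + a1 * S1 + a2 * S2 + S1 * S2)
    expect_equal(v, rate, tolerance = 1e-6)
    expect_lte(v, min(j1, j2, kcat * E) + 1e-9)
  }
  expect_equal(motif_flux_bi_delta(2, 3, 5, 1, 1, 1, 1, 1e-9), 2,
               tolerance = 1e-6)
  # symmetric inputs reduce to the unimolecular-like balance with S1 = S2
  v <- motif_flux_bi_delta(2, 2, 5, 1, 1, 0.7, 0.7, 1e-2)
  S <- (2 - v) / 1e-2
  expect_equal(v, 5 * S^2 / (1 + 1.4 * S + S^2), tolerance = 1e-8)
})

test_that("composed network flux reproduces the closed forms exactly", {
  set.seed(7)
  for (nm in names(closed_form_flux)) {
    net <- network_fixture(nm)
    g <- length(net$catalysts)
    cc <- random_compositions(300, g)
    expect_equal(network_flux(net, cc), closed_form_flux[[nm]](cc),
                 tolerance = 0, label = nm)
  }
  # all-zero functional counts give zero flux; omega column is inert
  for (nm in c("keystone_recycler", "parallel4")) {
    net <- network_fixture(nm)
    g <- length(net$catalysts)
    expect_identical(network_flux(net, matrix(0, 1, g)), 0)
    cc <- random_compositions(20, g)
    colnames(cc) <- names(net$catalysts)
    expect_equal(network_flux(net, cbind(cc, omega = 99L)),
                 network_flux(net, cc), tolerance = 0)
    # unnamed g+1 columns: the trailing column is the defective type
    expect_equal(network_flux(net, unname(cbind(cc, 7L))),
                 network_flux(net, cc), tolerance = 0)
    expect_error(network_flux(net, cbind(cc, bogus = 1L)), "unknown sequence")
  }
})

test_that("flux is monotone in each functional count and kcat-homogeneous", {
  set.seed(8)
  for (nm in c("serial3", "bimolecular3", "bimolecular4")) {
    net <- network_fixture(nm)
    g <- length(net$catalysts)
    cc <- random_compositions(50, g, max_count = 30)
    base <- network_flux(net, cc)
    for (col in seq_len(g)) {
      up <- cc; up[, col] <- up[, col] + 1L
      expect_true(all(network_flux(net, up) >= base), label = nm)
    }
  }
  # degree-1 homogeneity in kcat at fixed counts
  lam <- 3.5
  n1 <- network_fixture("serial3")
  n2 <- network_fixture("serial3", kcat_alpha = lam, kcat_beta = lam,
                        kcat_gamma = lam)
  cc <- random_compositions(50, 3)
  expect_equal(network_flux(n2, cc), lam * network_flux(n1, cc),
               tolerance = 1e-12)
})

test_that("keystone-recycler flux peaks where waste supply matches recycler capacity", {
  # kcat_alpha = kcat_beta = cw_alpha = 1: peak exactly at equal counts
  net <- network_fixture("keystone_recycler", kcat_beta = 1, cM_beta = 2)
  N <- 200
  a <- 0:N
  phi <- network_flux(net, cbind(alpha = a, beta = N - a))
  expect_identical(a[which.max(phi)], 100L)       # cwa*ka*a == kb*b
  # far-boundary variant: cwa=2 -> peak at 2a == b
  far <- network_fixture("keystone_recycler", cw_alpha = 2, kcat_beta = 1,
                         cM_beta = 2)
  phif <- network_flux(far, cbind(alpha = a, beta = N - a))
  expect_lt(abs(a[which.max(phif)] - N / 3), 1)
  # the two published variants share the same maximum flux (exactly at the
  # continuous optima; on the integer lattice up to discretisation)
  near <- network_fixture("keystone_recycler")
  phin <- network_flux(near, cbind(alpha = a, beta = N - a))
  expect_equal(network_flux(far, c(alpha = N / 3, beta = 2 * N / 3)),
               network_flux(near, c(alpha = 2 * N / 3, beta = N / 3)),
               tolerance = 1e-12)
  expect_lt(abs(max(phif) - max(phin)), 1)
})

test_that("finite-permeability steady state: algebraic route agrees with ODE integration", {
  for (nm in c("keystone_recycler", "serial3", "bimolecular3")) {
    net <- network_fixture(nm)
    g <- length(net$catalysts)
    cc <- stats::setNames(c(10, 4, 7)[seq_len(g)], names(net$catalysts))
    alg <- ode_steady_state_flux(net, cc, delta = 0.05)
    num <- ode_steady_state_flux(net, cc, delta = 0.05, method = "integrate")
    expect_equal(alg, num, tolerance = 1e-7, label = nm)
  }
  # no recycler: the flux is the keystone's limiting velocity for any delta
  net <- network_fixture("keystone_recycler")
  expect_equal(ode_steady_state_flux(net, c(alpha = 10, beta = 0), delta = 0.3),
               10, tolerance = 1e-12)
  expect_error(ode_steady_state_flux(net, c(alpha = 1, beta = 1), delta = 0))
})
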