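# Independent oracles used across tests.

# Hand-written closed-form fluxes of the four published two/three-catalyst
# architectures (the fixture defaults). cc: matrix of functional counts in
# catalyst order.
closed_form_flux <- list(
  keystone_recycler = function(cc, ka = 1, cwa = 1, kb = 2, cMb = 1.5)
    ka * cc[, 1] + cMb * pmin(cwa * ka * cc[, 1], kb * cc[, 2]),
  serial3 = function(cc, ka = 1, kb = 1, kg = 1, cMb = 4, cMg = 4)
    ka * cc[, 1] + cMb * pmin(ka * cc[, 1], kb * cc[, 2]) +
      cMg * pmin(ka * cc[, 1], kb * cc[, 2], kg * cc[, 3]),
  parallel3 = function(cc, ka = 1, kb = 1, kg = 1, cMb = 4, cMg = 4)
    ka * cc[, 1] + cMb * pmin(ka * cc[, 1], kb * cc[, 2]) +
      cMg * pmin(ka * cc[, 1], kg * cc[, 3]),
  bimolecular3 = function(cc, ka = 1, kb = 1, kg = 1,
                          cMa = 2.5, cMb = 2.5, cMg = 4)
    cMa * ka * cc[, 1] + cMb * kb * cc[, 2] +
      cMg * pmin(ka * cc[, 1], kb * cc[, 2], kg * cc[, 3])
)

# bisection root of the leaky unimolecular steady-state balance
# (v - j)(v - kE) = delta * Km * v  on (0, min(j, kE))
bisect_uni_root <- function(j, kE, Km, delta, iters = 200) {
  if (j == 0 || kE == 0) return(0)
  gfun <- function(v) (v - j) * (v - kE) - delta * Km * v
  lo <- 0; hi <- min(j, kE)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (gfun(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force marginalisation of development followed by assortment
brute_force_daughter_marginal <- function(j, params) {
  dev <- development_distribution(j, params)
  marg <- lifecycle_offspring_marginal(j, params)   # for the support only
  key <- apply(marg$counts, 1, paste, collapse = ",")
  acc <- stats::setNames(numeric(length(key)), key)
  for (r in seq_len(nrow(dev$counts))) {
    if (dev$prob[r] == 0) next
    as <- assortment_distribution(dev$counts[r, ], N = params$N)
    k2 <- apply(as$counts, 1, paste, collapse = ",")
    acc[k2] <- acc[k2] + dev$prob[r] * as$prob
  }
  list(counts = marg$counts, prob = unname(acc))
}

# fabricate a pf_stationary with a given lattice and frequency vector
fake_stationary <- function(lattice, F, g, N, q = 1,
                            include_sink = ncol(lattice) == g + 1) {
  structure(list(F = F, W_bar = NA_real_, wbar_j = rep(NA_real_, length(F)),
                 lattice = lattice, Phi = rep(NA_real_, length(F)),
                 params = lifecycle_params(N = N, q = q, g = g),
                 include_sink = include_sink,
                 iterations = 0L, residual = 0),
            class = "pf_stationary")
}

# constant-fitness flux function (for neutral-kernel tests)
neutral_flux <- function(g, value = 1)
  structure(function(cc) rep(value, nrow(cc)),
            class = c("pf_flux", "function"), g = g)

random_compositions <- function(n, g, max_count = 200) {
  matrix(sample.int(max_count + 1L, n * g, replace = TRUE) - 1L, n, g)
}
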