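# Stationary protocell populations: exact infinite-population eigen-solver
# and the finite-population agent-based Wright-Fisher simulator.

#' Build the life-cycle kernel over the composition lattice
#'
#' The kernel entry \eqn{K(m|j) = \Phi(m) \, P_{WF}(m|j)} combines the
#' Wright-Fisher daughter marginal (multinomial over N draws with mutation to
#' the defective type) with selection weight equal to the daughter's
#' metabolic flux. It is *not* column-stochastic: its leading eigenvalue is
#' the stationary mean fitness.
#'
#' When `q = 1` the defective type is unreachable from omega-free states and
#' makes the full kernel reducible, so the sink dimension is dropped by
#' default (`include_sink = params$q < 1`).
#'
#' @param flux A `pf_flux` fitness function (see [flux_function()]) or a
#'   `pf_network` (wrapped with piecewise-linear flux).
#' @param params [lifecycle_params()]; `params$g` must match the network.
#' @param include_sink Keep the defective-type dimension of the lattice.
#' @param cap Maximum lattice size (see [enumerate_compositions()]).
#' @return Object of class `pf_kernel`: list with the dense matrix `K`
#'   (indexed \[to, from\]), flux vector `Phi`, the `lattice`, `params`,
#'   `include_sink`.
#' @export
build_kernel <- function(flux, params, include_sink = params$q < 1,
                         cap = 1e5) {
  if (inherits(flux, "pf_network")) flux <- flux_function(flux)
  stopifnot(inherits(flux, "pf_flux"), inherits(params, "pf_params"))
  if (attr(flux, "g") != params$g)
    stop("params$g (", params$g, ") does not match the flux function's ",
         "number of functional types (", attr(flux, "g"), ")", call. = FALSE)
  if (!include_sink && params$q < 1)
    stop("the defective-type dimension cannot be dropped when q < 1",
         call. = FALSE)
  lattice <- enumerate_compositions(params$N, params$g,
                                    include_sink = include_sink, cap = cap)
  L <- nrow(lattice)
  Phi <- flux(lattice[, seq_len(params$g), drop = FALSE])

  # per-draw probabilities for every source composition j
  N <- params$N; q <- params$q
  if (include_sink) {
    P <- q * lattice / N
    P[, params$g + 1L] <- 1 - q + q * lattice[, params$g + 1L] / N
  } else {
    P <- lattice / N                       # q = 1
  }
  logP <- log(P)
  logP[!is.finite(logP)] <- -1e9           # exp(m * -1e9) == 0 for m >= 1
  lmc <- lgamma(N + 1) - rowSums(lgamma(lattice + 1))
  # log K[m, j] = log Phi(m) + lmc(m) + sum_i lattice[m, i] * logP[j, i]
  K <- exp((lattice %*% t(logP)) + lmc) * Phi
  structure(list(K = K, Phi = Phi, lattice = lattice, params = params,
                 include_sink = include_sink),
            class = "pf_kernel")
}

#' Stationary population distribution by Perron-Frobenius power iteration
#'
#' Iterates \eqn{F \leftarrow K F / \|K F\|_1} until the relative L1
#' eigen-residual \eqn{\|K F - \bar W F\|_1 / \bar W} drops below `tol`. The
#' normaliser at convergence is the leading eigenvalue \eqn{\bar W}, the
#' stationary mean fitness.
#'
#' @param kernel A `pf_kernel`.
#' @param tol Relative L1 residual tolerance (default `1e-12`).
#' @param max_iter Iteration cap.
#' @return Object of class `pf_stationary`: frequencies `F` over the lattice,
#'   mean fitness `W_bar`, per-source expected offspring flux `wbar_j`,
#'   `lattice`, `Phi`, `params`, iteration diagnostics.
#' @export
stationary_distribution <- function(kernel, tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(kernel, "pf_kernel"))
  K <- kernel$K
  if (all(kernel$Phi == 0))
    stop("degenerate kernel: the flux is identically zero", call. = FALSE)
  L <- nrow(K)
  F <- rep(1 / L, L)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    y <- as.numeric(K %*% F)
    lam <- sum(y)
    if (lam <= 0)
      stop("power iteration collapsed: K F vanished (reducible/degenerate ",
           "kernel)", call. = FALSE)
    resid <- sum(abs(y - lam * F)) / lam
    F <- y / lam
    if (resid <= tol) {
      return(structure(list(F = F, W_bar = lam,
                            wbar_j = as.numeric(colSums(K)),
                            lattice = kernel$lattice, Phi = kernel$Phi,
                            params = kernel$params,
                            include_sink = kernel$include_sink,
                            iterations = it, residual = resid),
                       class = "pf_stationary"))
    }
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (residual ", signif(resid, 3), ")", call. = FALSE)
}

#' @export
print.pf_stationary <- function(x, ...) {
  cat("<pf_stationary> N =", x$params$N, " q =", x$params$q,
      " states =", length(x$F), "\n  W_bar =", signif(x$W_bar, 6),
      " (", x$iterations, "iterations )\n")
  invisible(x)
}

#' Weighted selection of survivors without replacement
#'
#' Selects `count` distinct individuals with probability proportional to
#' their fitness, without replacement. Two schemes are provided:
#'
#' * `"pps"` (default, used by [run_agent_based()]): randomised systematic
#'   probability-proportional-to-size sampling. Each individual's *inclusion*
#'   probability is exactly `count * w_i / sum(w)` (clamped at 1, with the
#'   excess redistributed), so in the infinite-population limit the selected
#'   composition is weighted linearly by fitness — the property required for
#'   the agent-based model to approach the infinite-population eigen
#'   equation.
#' * `"successive"`: successive weighted draws without replacement
#'   (equivalently, exponential-key order statistics). Note that when a fixed
#'   *half* of the pool must be kept, successive sampling yields saturating
#'   inclusion probabilities \eqn{1 - e^{-w_i \tau}}: selection differentials
#'   are compressed and the large-population limit is *not* the eigen
#'   equation. It is kept for comparison.
#'
#' Zero-weight individuals are never selected under either scheme while
#' positive-weight candidates remain.
#'
#' @param weights Nonnegative fitness weights.
#' @param count Number of survivors; requires at least `count` strictly
#'   positive weights.
#' @param method `"pps"` or `"successive"`.
#' @return Integer vector of selected indices.
#' @export
select_half_without_replacement <- function(weights, count,
                                            method = c("pps", "successive")) {
  method <- match.arg(method)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights > 0) < count)
    stop("fewer than ", count, " individuals with positive fitness",
         call. = FALSE)
  if (method == "successive") {
    keys <- stats::rexp(length(weights)) / weights   # weight 0 -> key Inf
    return(order(keys)[seq_len(count)])
  }
  # pps: certainty-select individuals whose target inclusion probability
  # reaches 1, then randomised systematic sampling on the rest
  idx <- seq_along(weights)
  certain <- integer(0)
  repeat {
    k <- count - length(certain)
    if (k == 0L) return(certain)
    pi <- k * weights[idx] / sum(weights[idx])
    over <- idx[pi >= 1]
    if (!length(over)) break
    certain <- c(certain, over)
    idx <- setdiff(idx, over)
  }
  perm <- sample(idx)
  pi <- k * weights[perm] / sum(weights[perm])
  cum <- cumsum(pi)                     # total mass k, all pi < 1
  pts <- stats::runif(1) + 0:(k - 1L)
  sel <- perm[findInterval(pts, c(0, cum), rightmost.closed = TRUE)]
  c(certain, sel)
}

# default homogeneous starting composition: N split as evenly as possible
# across the g functional types, remainder to the lowest-index types, omega 0
default_init_composition <- function(N, g) {
  base <- N %/% g
  j <- rep.int(base, g)
  extra <- N - base * g
  if (extra > 0) j[seq_len(extra)] <- j[seq_len(extra)] + 1L
  c(j, 0L)
}

#' Agent-based Wright-Fisher protocell simulation
#'
#' Starts from `pop_size` identical protocells. Each generation every
#' protocell develops (2N samplings with replacement, with mutation to the
#' defective type) and splits into two daughters, doubling the population;
#' then `pop_size` survivors are selected without replacement with
#' probability proportional to the daughters' metabolic flux. Runs are
#' bit-reproducible under a fixed `seed`.
#'
#' @param flux A `pf_flux` fitness function or a `pf_network`.
#' @param params [lifecycle_params()].
#' @param pop_size Number of protocells `P` (even).
#' @param generations Number of life-cycle generations `G`.
#' @param init Starting composition (length `g + 1`, omega last); default:
#'   even split of N across functional types, omega 0.
#' @param seed Optional integer seed (sets R's RNG locally for the run).
#' @param record_every Thin the per-generation observable series (default 1 =
#'   record every generation).
#' @param stationary_window Fraction of final generations averaged for the
#'   stationary observables (default 0.1).
#' @param coexist_threshold Minimum copy number per functional type for a
#'   protocell to count as coexisting (default 1).
#' @return Object of class `pf_abm`: the final population matrix, the
#'   per-generation observable `series` (data.frame), time-averaged
#'   `stationary` observables, `status` (`"ok"` or `"extinct"`), and the run
#'   settings.
#' @export
run_agent_based <- function(flux, params, pop_size = 1000,
                            generations = 5000, init = NULL, seed = NULL,
                            record_every = 1L, stationary_window = 0.1,
                            coexist_threshold = 1L,
                            selection = c("pps", "successive")) {
  selection <- match.arg(selection)
  if (inherits(flux, "pf_network")) flux <- flux_function(flux)
  stopifnot(inherits(flux, "pf_flux"), inherits(params, "pf_params"))
  if (pop_size %% 2 != 0) stop("pop_size must be even", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- params$g; N <- params$N; Tn <- g + 1L
  if (is.null(init)) init <- default_init_composition(N, g)
  init <- check_composition(init, params, N)
  pop <- matrix(rep(as.integer(init), each = pop_size), pop_size, Tn)

  gens_rec <- seq(1L, generations, by = record_every)
  series <- data.frame(generation = gens_rec,
                       coexistence = NA_real_, mean_flux_pool = NA_real_,
                       mean_flux = NA_real_, defective_frequency = NA_real_)
  ri <- 1L
  status <- "ok"
  fcols <- seq_len(g)
  for (gen in seq_len(generations)) {
    p <- params$q * pop / N
    p[, Tn] <- 1 - params$q + params$q * pop[, Tn] / N
    k <- rmultinom_rows(2L * N, p)
    m1 <- rmvhyper_rows(k, N)
    pool <- rbind(m1, k - m1)
    w <- flux(pool[, fcols, drop = FALSE])
    if (sum(w > 0) < pop_size) {
      status <- "extinct"
      series <- series[seq_len(ri - 1L), , drop = FALSE]
      break
    }
    idx <- select_half_without_replacement(w, pop_size, method = selection)
    pop <- pool[idx, , drop = FALSE]
    if (ri <= length(gens_rec) && gen == gens_rec[ri]) {
      wsel <- w[idx]
      series$coexistence[ri] <-
        mean(rowSums(pop[, fcols, drop = FALSE] >= coexist_threshold) == g)
      series$mean_flux_pool[ri] <- mean(w)
      series$mean_flux[ri] <- mean(wsel)
      series$defective_frequency[ri] <- mean(pop[, Tn]) / N
      ri <- ri + 1L
    }
  }

  stationary <- NULL
  if (status == "ok") {
    nwin <- max(1L, ceiling(nrow(series) * stationary_window))
    win <- series[seq(nrow(series) - nwin + 1L, nrow(series)), , drop = FALSE]
    stationary <- list(coexistence = mean(win$coexistence),
                       mean_flux_pool = mean(win$mean_flux_pool),
                       mean_flux = mean(win$mean_flux),
                       defective_frequency = mean(win$defective_frequency),
                       window = nwin)
  }
  structure(list(population = pop, series = series, stationary = stationary,
                 status = status, params = params, pop_size = pop_size,
                 generations = generations, seed = seed, init = init,
                 coexist_threshold = coexist_threshold),
            class = "pf_abm")
}

#' @export
print.pf_abm <- function(x, ...) {
  cat("<pf_abm> P =", x$pop_size, " G =", x$generations, " status:",
      x$status, "\n")
  if (!is.null(x$stationary))
    cat("  stationary coexistence =", signif(x$stationary$coexistence, 4),
        " mean pool flux =", signif(x$stationary$mean_flux_pool, 5), "\n")
  invisible(x)
}
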