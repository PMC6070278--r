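# Steady-state flux of irreversible catalysed networks.
#
# Two evaluation modes:
#   * piecewise (delta -> 0 limit): every motif velocity is a min() of
#     incoming fluxes and the limiting velocity kcat*[E]; this is the fitness
#     used by the evolutionary model.
#   * finite delta: motif velocities solve the quadratic / cubic steady-state
#     balance including membrane leak; used as a numeric oracle.

#' Michaelis-Menten velocity
#'
#' \eqn{v = k_{cat}[E][S] / (K_m + [S])}.
#'
#' @param E,S Enzyme and substrate concentrations (nonnegative, vectorised).
#' @param kcat Catalytic constant (> 0).
#' @param Km Michaelis constant (> 0).
#' @return Reaction velocity; bounded by `kcat * E` and nondecreasing in `S`.
#' @export
mm_velocity <- function(E, S, kcat, Km) {
  if (any(E < 0) || any(S < 0) || any(kcat < 0))
    stop("concentrations and rates must be nonnegative", call. = FALSE)
  if (any(Km <= 0)) stop("Km must be positive", call. = FALSE)
  kcat * E * S / (Km + S)
}

#' Motif velocities in the piecewise-linear (zero-leak) limit
#'
#' As the membrane permeability \eqn{\delta \to 0}, the steady-state velocity
#' of a unimolecular recycling motif is `min(j, kcat*E)` and that of a
#' bimolecular motif is `min(j1, j2, kcat*E)`: the motif passes its incoming
#' substrate flux through until the enzyme pool saturates.
#'
#' @param j,j1,j2 Incoming substrate fluxes (nonnegative, vectorised).
#' @param E Enzyme count/concentration.
#' @param kcat Catalytic constant.
#' @return Motif velocity.
#' @export
motif_flux_uni <- function(j, E, kcat) {
  if (any(j < 0) || any(E < 0)) stop("negative input", call. = FALSE)
  pmin(j, kcat * E)
}

#' @rdname motif_flux_uni
#' @export
motif_flux_bi <- function(j1, j2, E, kcat) {
  if (any(j1 < 0) || any(j2 < 0) || any(E < 0))
    stop("negative input", call. = FALSE)
  pmin(j1, j2, kcat * E)
}

#' Motif velocities at finite membrane permeability
#'
#' `motif_flux_uni_delta()` returns the root of
#' \eqn{(v-j)(v-k_{cat}E) + \delta K_m v = 0} for which the implied substrate
#' concentration \eqn{[S] = (j-v)/\delta} is nonnegative (the smaller root,
#' continuous with the zero-leak limit). `motif_flux_bi_delta()` solves the
#' corresponding cubic
#' \eqn{(v-j_1)(v-j_2)(v-k_{cat}E) - ((a_1+a_2)v - a_1 j_1 - a_2 j_2)v\delta
#' + K_m v \delta^2 = 0} and selects the smallest real root with both implied
#' substrate concentrations nonnegative.
#'
#' For \eqn{\delta > 0} the velocity is strictly below the piecewise-linear
#' value near the kink: leak replaces the sharp peak by a smooth, lower one.
#'
#' @inheritParams motif_flux_uni
#' @param Km Michaelis constant.
#' @param delta Membrane permeability (> 0).
#' @param a1,a2 Bimolecular interaction constants.
#' @return Motif velocity.
#' @export
motif_flux_uni_delta <- function(j, E, kcat, Km, delta) {
  if (any(j < 0) || any(E < 0)) stop("negative input", call. = FALSE)
  if (any(delta <= 0)) stop("delta must be positive", call. = FALSE)
  kE <- kcat * E
  b <- j + kE + delta * Km
  disc <- b^2 - 4 * j * kE
  disc[disc < 0] <- 0          # guard tiny negative round-off
  # smaller quadratic root, written in the numerically stable form
  v <- 2 * j * kE / (b + sqrt(disc))
  pmin(v, j)                   # [S] = (j - v)/delta >= 0 up to round-off
}

#' @rdname motif_flux_uni_delta
#' @export
motif_flux_bi_delta <- function(j1, j2, E, kcat, Km, a1 = 1, a2 = 1, delta) {
  if (any(j1 < 0) || any(j2 < 0) || any(E < 0))
    stop("negative input", call. = FALSE)
  if (any(delta <= 0)) stop("delta must be positive", call. = FALSE)
  n <- max(length(j1), length(j2), length(E))
  j1 <- rep_len(j1, n); j2 <- rep_len(j2, n); E <- rep_len(E, n)
  vapply(seq_len(n), function(i) {
    kE <- kcat * E[i]
    jm <- min(j1[i], j2[i])
    if (jm == 0 || kE == 0) return(0)
    # expand to v^3 + c2 v^2 + c1 v + c0 = 0
    c2 <- -(j1[i] + j2[i] + kE) - delta * (a1 + a2)
    c1 <- j1[i] * j2[i] + kE * (j1[i] + j2[i]) +
      delta * (a1 * j1[i] + a2 * j2[i]) + Km * delta^2
    c0 <- -j1[i] * j2[i] * kE
    rts <- polyroot(c(c0, c1, c2, 1))
    re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
    tol <- 1e-9 * (1 + jm)
    adm <- re[re >= -tol & re <= jm + tol]
    if (!length(adm))
      stop("no admissible root of the bimolecular steady-state cubic ",
           "(internal error)", call. = FALSE)
    min(max(min(adm), 0), jm)
  }, numeric(1))
}

# ---- composition over a network --------------------------------------------

# Coerce counts to a numeric matrix with one column per catalyst, in
# declaration order. Accepts named vectors/matrices (an "omega" column is
# ignored) or unnamed input with g or g+1 columns (the extra final column is
# taken to be the defective type).
normalize_counts <- function(network, counts) {
  ids <- names(network$catalysts)
  g <- length(ids)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts)) && any(!nzchar(colnames(counts))))
    stop("counts column names must be either all present or all absent",
         call. = FALSE)
  if (!is.null(colnames(counts))) {
    extra <- setdiff(colnames(counts), c(ids, "omega"))
    if (length(extra))
      stop("unknown sequence type(s) in counts: ",
           paste(extra, collapse = ", "), call. = FALSE)
    missing <- setdiff(ids, colnames(counts))
    if (length(missing))
      stop("counts missing catalyst type(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    counts <- counts[, ids, drop = FALSE]
  } else if (ncol(counts) == g + 1L) {
    counts <- counts[, seq_len(g), drop = FALSE]  # last column = omega
    colnames(counts) <- ids
  } else if (ncol(counts) == g) {
    colnames(counts) <- ids
  } else {
    stop("counts must have ", g, " (or ", g + 1,
         ", with trailing defective type) columns", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  storage.mode(counts) <- "double"
  counts
}

#' Steady-state critical-metabolite flux of a network
#'
#' Traverses the catalysts in topological order and composes the motif
#' velocities: a saturated keystone contributes its limiting velocity
#' `kcat * count`; a unimolecular recycler contributes
#' `min(incoming waste flux, kcat * count)`; a bimolecular recycler
#' `min(j1, j2, kcat * count)`. The incoming flux of an intermediate is its
#' producer's velocity times the producing stoichiometric coefficient. The
#' returned flux \eqn{\Phi} sums, over all catalysts, the velocity times the
#' catalyst's stoichiometric coefficient onto the critical output.
#'
#' @param network A `pf_network`.
#' @param counts Sequence-type counts: a named vector, or a matrix with one
#'   row per composition (vectorised evaluation). A trailing/`"omega"` column
#'   of defective counts is ignored — the flux depends on functional counts
#'   only.
#' @param mode `"piecewise"` (the zero-leak limit; default, used as fitness)
#'   or `"finite_delta"` (leaky motif equations, using each intermediate's
#'   `permeability`, or the `delta` override).
#' @param delta Optional single permeability overriding the per-metabolite
#'   values in `finite_delta` mode.
#' @return Numeric vector of fluxes, one per composition row.
#' @examples
#' net <- network_fixture("keystone_recycler")   # kcat_beta=2, cM_beta=1.5
#' network_flux(net, c(alpha = 10, beta = 3))    # 10 + 1.5*min(10, 6)
#' @export
network_flux <- function(network, counts, mode = c("piecewise", "finite_delta"),
                         delta = NULL) {
  stopifnot(inherits(network, "pf_network"))
  mode <- match.arg(mode)
  counts <- normalize_counts(network, counts)
  nrows <- nrow(counts)
  vel <- list()                       # catalyst id -> velocity vector
  metflux <- list()                   # metabolite id -> incoming flux vector
  phi <- numeric(nrows)
  for (id in network$order) {
    ct <- network$catalysts[[id]]
    E <- unname(counts[, id])
    if (ct$saturated) {
      v <- ct$kcat * E
    } else {
      js <- lapply(ct$substrates, function(m) metflux[[m]] %||% numeric(nrows))
      if (mode == "piecewise") {
        v <- if (length(js) == 1L) pmin(js[[1]], ct$kcat * E)
             else pmin(js[[1]], js[[2]], ct$kcat * E)
      } else {
        d <- function(m) delta %||% network$metabolites[[m]]$permeability
        if (length(js) == 1L) {
          v <- motif_flux_uni_delta(js[[1]], E, ct$kcat, ct$Km,
                                    d(ct$substrates[1]))
        } else {
          # both substrates leak; the cubic assumes a common delta, so take
          # the two permeabilities (they are equal in all fixtures)
          dd <- c(d(ct$substrates[1]), d(ct$substrates[2]))
          v <- motif_flux_bi_delta(js[[1]], js[[2]], E, ct$kcat, ct$Km,
                                   ct$a1, ct$a2, mean(dd))
        }
      }
    }
    vel[[id]] <- v
    for (p in names(ct$products)) {
      contrib <- ct$products[[p]] * v
      if (p == network$critical) phi <- phi + contrib
      else metflux[[p]] <- (metflux[[p]] %||% numeric(nrows)) + contrib
    }
  }
  phi
}

#' Build a flux (fitness) function from a network
#'
#' Returns a closure mapping compositions to flux, carrying the number of
#' functional types as attribute `g`. This is the `FluxFunction` consumed by
#' [build_kernel()] and [run_agent_based()].
#'
#' @inheritParams network_flux
#' @return A function `f(counts)` of class `pf_flux`.
#' @export
flux_function <- function(network, mode = "piecewise", delta = NULL) {
  stopifnot(inherits(network, "pf_network"))
  f <- function(counts) network_flux(network, counts, mode = mode,
                                     delta = delta)
  structure(f, class = c("pf_flux", "function"),
            g = length(network$catalysts), network = network, mode = mode)
}

#' Finite-permeability steady-state flux (numeric oracle)
#'
#' Computes the stationary critical-metabolite production rate of the leaky
#' network. `method = "algebraic"` (default) solves each motif's quadratic /
#' cubic balance exactly in topological order — exact for feed-forward
#' networks. `method = "integrate"` integrates the intermediate mass-action /
#' Michaelis-Menten ODEs to stationarity with an adaptive Runge-Kutta scheme
#' and is used to cross-validate the algebraic route.
#'
#' As \eqn{\delta \to 0} the result converges to [network_flux()]
#' (`piecewise`), with O(\eqn{\delta}) error away from the kinks and a
#' strictly lower, smoothed peak at them.
#'
#' @inheritParams network_flux
#' @param delta Membrane permeability (> 0) applied to all intermediates.
#' @param method `"algebraic"` or `"integrate"`.
#' @param t_max,rtol Integration horizon and tolerance (`integrate` only).
#' @return Stationary flux (numeric vector, one per composition row).
#' @export
ode_steady_state_flux <- function(network, counts, delta,
                                  method = c("algebraic", "integrate"),
                                  t_max = 1e6, rtol = 1e-10) {
  stopifnot(inherits(network, "pf_network"))
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  method <- match.arg(method)
  if (method == "algebraic")
    return(network_flux(network, counts, mode = "finite_delta", delta = delta))
  counts <- normalize_counts(network, counts)
  vapply(seq_len(nrow(counts)), function(i)
    integrate_network_steady(network, counts[i, ], delta, t_max, rtol),
    numeric(1))
}

# Integrate d[S]/dt for the intermediate pool of one composition until
# stationarity; returns the critical-output production rate at the fixed
# point. Environmental inputs are held constant (keystones at limiting
# velocity), so the system is feed-forward and globally attracted to its
# unique steady state.
integrate_network_steady <- function(network, counts, delta, t_max, rtol) {
  kinds <- vapply(network$metabolites, `[[`, character(1), "kind")
  ints <- names(kinds)[kinds == "intermediate"]
  if (!length(ints)) {  # keystone-only network: flux is immediate
    return(network_flux(network, counts, mode = "piecewise"))
  }
  rates <- function(S) {  # S named vector of intermediate concentrations
    v <- numeric(0)
    dS <- stats::setNames(numeric(length(ints)), ints)
    phi <- 0
    for (id in network$order) {
      ct <- network$catalysts[[id]]
      E <- counts[[id]]
      if (ct$saturated) {
        vi <- ct$kcat * E
      } else if (length(ct$substrates) == 1L) {
        vi <- mm_velocity(E, S[[ct$substrates]], ct$kcat, ct$Km)
        dS[ct$substrates] <- dS[ct$substrates] - vi
      } else {
        s1 <- S[[ct$substrates[1]]]; s2 <- S[[ct$substrates[2]]]
        vi <- ct$kcat * E * s1 * s2 /
          (ct$Km + ct$a1 * s1 + ct$a2 * s2 + s1 * s2)
        dS[ct$substrates] <- dS[ct$substrates] - vi
      }
      for (p in names(ct$products)) {
        if (p == network$critical) phi <- phi + ct$products[[p]] * vi
        else if (p %in% ints) dS[p] <- dS[p] + ct$products[[p]] * vi
      }
    }
    dS <- dS - delta * S
    list(dS = dS, phi = phi)
  }
  f <- function(t, y) rates(stats::setNames(y, ints))$dS
  y <- stats::setNames(numeric(length(ints)), ints)
  # characteristic relaxation time: slowest of leak and enzymatic turnover
  t_char <- 1 / delta
  t <- 0
  repeat {
    step_to <- min(t + t_char, t_max)
    y_new <- rk45(f, y, t, step_to, rtol = rtol, atol = 1e-12)$y
    rel <- max(abs(y_new - y) / (abs(y_new) + 1e-12))
    t <- step_to
    y <- y_new
    if (rel < 1e-10) break
    if (t >= t_max)
      stop("finite-delta steady state not reached by t_max = ", t_max,
           " (last relative change ", signif(rel, 3), ")", call. = FALSE)
  }
  rates(stats::setNames(y, ints))$phi
}
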