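# Within-protocell development ODEs (validation oracle).
#
# The evolutionary model replaces explicit development with 2N samplings with
# replacement; this module exists to verify the two analytic facts justifying
# that replacement under time-scale separation (kcat >> r):
#   * the ratio of functional types stays constant during development
#     (dx/dt = 0), and
#   * after the metabolite transient, the total sequence pool grows
#     exponentially at the per-capita scaled flux phi = Phi / (total
#     sequences).
# Nothing in the life-cycle or population modules calls this code.

#' Simulate protocell development (replication coupled to metabolism)
#'
#' Integrates the full deterministic system for a leaky network: sequence
#' concentrations replicate by mass action at rate `r` per unit of critical
#' metabolite (`d[E_i]/dt = r [M] [E_i]`), the critical metabolite pool gains
#' the instantaneous network flux and is depleted by replication
#' (`d[M]/dt = Phi - r [M] sum_i [E_i]`), and intermediates follow the leaky
#' Michaelis-Menten kinetics of the metabolism module. Environmental inputs
#' are held constant.
#'
#' @param network A `pf_network`.
#' @param counts Initial sequence concentrations (named vector over the
#'   catalyst types).
#' @param r Replication rate constant (> 0, or 0 to decouple replication).
#' @param t_end Integration horizon.
#' @param delta Membrane permeability applied to all intermediates (default:
#'   each metabolite's own `permeability`).
#' @param M0 Initial critical-metabolite concentration.
#' @param n_out Number of saved trajectory points.
#' @param rtol Integrator relative tolerance (default `1e-9`).
#' @return Object of class `pf_development`: a `trajectory` data.frame with
#'   the state variables plus `total` (sum of sequences), the type fractions
#'   `x_<id>` and the scaled flux `phi`.
#' @export
simulate_development <- function(network, counts, r, t_end, delta = NULL,
                                 M0 = 0, n_out = 200, rtol = 1e-9) {
  stopifnot(inherits(network, "pf_network"))
  if (r < 0 || t_end <= 0) stop("need r >= 0 and t_end > 0", call. = FALSE)
  ids <- names(network$catalysts)
  counts <- normalize_counts(network, counts)[1, ]
  kinds <- vapply(network$metabolites, `[[`, character(1), "kind")
  ints <- names(kinds)[kinds == "intermediate"]
  dl <- function(m) delta %||% network$metabolites[[m]]$permeability

  nE <- length(ids); nI <- length(ints)
  # state vector: [sequences, M, intermediates]
  y0 <- c(counts, M0, stats::setNames(numeric(nI), ints))

  derivs <- function(t, y) {
    E <- y[seq_len(nE)]
    M <- y[nE + 1L]
    S <- y[nE + 1L + seq_len(nI)]
    names(S) <- ints
    dS <- stats::setNames(numeric(nI), ints)
    phi <- 0
    v <- stats::setNames(numeric(nE), ids)
    for (id in network$order) {
      ct <- network$catalysts[[id]]
      if (ct$saturated) {
        vi <- ct$kcat * E[[id]]
      } else if (length(ct$substrates) == 1L) {
        s <- S[[ct$substrates]]
        vi <- ct$kcat * E[[id]] * s / (ct$Km + s)
        dS[ct$substrates] <- dS[ct$substrates] - vi
      } else {
        s1 <- S[[ct$substrates[1]]]; s2 <- S[[ct$substrates[2]]]
        vi <- ct$kcat * E[[id]] * s1 * s2 /
          (ct$Km + ct$a1 * s1 + ct$a2 * s2 + s1 * s2)
        dS[ct$substrates] <- dS[ct$substrates] - vi
      }
      v[id] <- vi
      for (p in names(ct$products)) {
        if (p == network$critical) phi <- phi + ct$products[[p]] * vi
        else if (p %in% ints) dS[p] <- dS[p] + ct$products[[p]] * vi
      }
    }
    for (m in ints) dS[m] <- dS[m] - dl(m) * S[[m]]
    dE <- r * M * E
    dM <- phi - r * M * sum(E)
    c(dE, dM, dS)
  }

  save_at <- seq(0, t_end, length.out = n_out + 1L)[-1]
  sol <- rk45(derivs, y0, 0, t_end, rtol = rtol, atol = 1e-12,
              save_at = save_at)
  Y <- rbind(y0, sol$save_y)
  times <- c(0, sol$save_t)
  traj <- as.data.frame(Y)
  names(traj) <- c(ids, "M", ints)
  total <- rowSums(traj[, ids, drop = FALSE])
  traj <- cbind(time = times, traj, total = total)
  for (id in ids) traj[[paste0("x_", id)]] <- traj[[id]] / total
  # instantaneous scaled flux from the network state
  traj$phi <- vapply(seq_len(nrow(traj)), function(i) {
    E <- as.numeric(traj[i, ids]); names(E) <- ids
    S <- as.numeric(traj[i, ints, drop = FALSE])
    inst_flux(network, E, S, ints, dl) / total[i]
  }, numeric(1))
  structure(list(trajectory = traj, network = network, r = r,
                 delta = delta), class = "pf_development")
}

# instantaneous Phi given sequence and intermediate concentrations
inst_flux <- function(network, E, S, ints, dl) {
  names(S) <- ints
  phi <- 0
  for (id in network$order) {
    ct <- network$catalysts[[id]]
    if (ct$saturated) {
      vi <- ct$kcat * E[[id]]
    } else if (length(ct$substrates) == 1L) {
      s <- S[[ct$substrates]]
      vi <- ct$kcat * E[[id]] * s / (ct$Km + s)
    } else {
      s1 <- S[[ct$substrates[1]]]; s2 <- S[[ct$substrates[2]]]
      vi <- ct$kcat * E[[id]] * s1 * s2 /
        (ct$Km + ct$a1 * s1 + ct$a2 * s2 + s1 * s2)
    }
    if (network$critical %in% names(ct$products))
      phi <- phi + ct$products[[network$critical]] * vi
  }
  phi
}

#' @export
print.pf_development <- function(x, ...) {
  tr <- x$trajectory
  cat("<pf_development>", nrow(tr), "saved points to t =",
      max(tr$time), "; final total =", signif(tr$total[nrow(tr)], 6), "\n")
  invisible(x)
}
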