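# Summary observables of stationary protocell populations.
#
# All observables accept either the exact solver output (pf_stationary: a
# frequency vector over the composition lattice) or an agent-based run
# (pf_abm: stationary time averages over the final window).

#' Coexistence fraction
#'
#' Fraction of the population whose protocells carry at least `threshold`
#' copies of *every* functional type (the defective type is irrelevant).
#'
#' @param x A `pf_stationary` or `pf_abm` object.
#' @param threshold Minimum copy number per functional type (default 1).
#' @param ... Unused.
#' @return A fraction in \[0, 1\].
#' @export
coexistence_fraction <- function(x, ...) UseMethod("coexistence_fraction")

#' @rdname coexistence_fraction
#' @export
coexistence_fraction.pf_stationary <- function(x, threshold = 1L, ...) {
  g <- x$params$g
  ok <- rowSums(x$lattice[, seq_len(g), drop = FALSE] >= threshold) == g
  sum(x$F[ok])
}

#' @rdname coexistence_fraction
#' @export
coexistence_fraction.pf_abm <- function(x, ...) {
  if (is.null(x$stationary))
    stop("run ended in extinction; no stationary observables", call. = FALSE)
  x$stationary$coexistence
}

#' Mean metabolic flux of the stationary population
#'
#' For the exact solver this is the stationary *mean fitness*: the expected
#' flux of the developed offspring pool, \eqn{\sum_j \bar w(j) F(j)} with
#' \eqn{\bar w(j) = \sum_m \Phi(m) P_{WF}(m|j)}, which equals the leading
#' eigenvalue \eqn{\bar W} of the life-cycle kernel. (The flux averaged over
#' the post-selection survivors is a different, selection-biased quantity;
#' see `attr(, "survivor_flux")`.) For an agent-based run it is the
#' time-averaged mean flux of the pre-selection daughter pool.
#'
#' @param x A `pf_stationary` or `pf_abm` object.
#' @param ... Unused.
#' @return Mean flux (same units as the network flux).
#' @export
mean_flux <- function(x, ...) UseMethod("mean_flux")

#' @rdname mean_flux
#' @export
mean_flux.pf_stationary <- function(x, ...) {
  out <- sum(x$wbar_j * x$F)
  attr(out, "survivor_flux") <- sum(x$Phi * x$F)
  out
}

#' @rdname mean_flux
#' @export
mean_flux.pf_abm <- function(x, ...) {
  if (is.null(x$stationary))
    stop("run ended in extinction; no stationary observables", call. = FALSE)
  out <- x$stationary$mean_flux_pool
  attr(out, "survivor_flux") <- x$stationary$mean_flux
  out
}

#' Mean defective-type frequency
#'
#' Expected fraction of defective (omega) sequences per protocell,
#' \eqn{E[m_\omega]/N}, in the stationary population.
#'
#' @inheritParams coexistence_fraction
#' @return A fraction in \[0, 1\].
#' @export
defective_frequency <- function(x, ...) UseMethod("defective_frequency")

#' @rdname defective_frequency
#' @export
defective_frequency.pf_stationary <- function(x, ...) {
  if (!x$include_sink) return(0)
  g <- x$params$g
  sum(x$F * x$lattice[, g + 1L]) / x$params$N
}

#' @rdname defective_frequency
#' @export
defective_frequency.pf_abm <- function(x, ...) {
  if (is.null(x$stationary))
    stop("run ended in extinction; no stationary observables", call. = FALSE)
  x$stationary$defective_frequency
}

#' Ternary (simplex) projection of a stationary distribution
#'
#' Projects each composition onto the simplex spanned by three selected type
#' axes: the three counts renormalised to sum to one, weighted by the
#' composition's stationary mass. Compositions with all three selected
#' counts zero carry undefined coordinates; they are flagged and their mass
#' is reported but excluded from plotting coordinates.
#'
#' @param x A `pf_stationary` or `pf_abm` object.
#' @param types Indices or names of exactly three type axes (default: first
#'   three columns, i.e. the functional types for g = 3, or the two
#'   functional types plus omega for g = 2).
#' @param ... Unused.
#' @return A data.frame with columns `f1`, `f2`, `f3`, `weight`, `defined`.
#' @export
ternary_projection <- function(x, types = NULL, ...)
  UseMethod("ternary_projection")

ternary_project_counts <- function(counts, weight, cols) {
  if (length(cols) != 3L)
    stop("exactly three type axes must be selected", call. = FALSE)
  sel <- counts[, cols, drop = FALSE]
  tot <- rowSums(sel)
  defined <- tot > 0
  f <- sel / ifelse(tot > 0, tot, 1)
  f[!defined, ] <- NA_real_
  data.frame(f1 = f[, 1], f2 = f[, 2], f3 = f[, 3],
             weight = weight, defined = defined)
}

resolve_type_cols <- function(ncols, g, types) {
  if (is.null(types)) return(seq_len(min(3L, ncols)))
  if (is.character(types)) return(types)   # resolved by caller's colnames
  as.integer(types)
}

#' @rdname ternary_projection
#' @export
ternary_projection.pf_stationary <- function(x, types = NULL, ...) {
  cols <- resolve_type_cols(ncol(x$lattice), x$params$g, types)
  ternary_project_counts(x$lattice, x$F, cols)
}

#' @rdname ternary_projection
#' @export
ternary_projection.pf_abm <- function(x, types = NULL, ...) {
  pop <- x$population
  cols <- resolve_type_cols(ncol(pop), x$params$g, types)
  ternary_project_counts(pop, rep(1 / nrow(pop), nrow(pop)), cols)
}

# ---- parameter scans -------------------------------------------------------

#' Scan observables over ploidy and replication-accuracy grids
#'
#' Runs the exact solver and/or the agent-based simulator at every (N, q)
#' grid point and collects the stationary observables in a tidy table. For
#' the agent-based solver each replicate gets its own seed derived from
#' `seed` by a fixed affine scheme, so reruns are bit-identical. Failures at
#' individual points are recorded in the `status` column and the scan
#' continues.
#'
#' @param network A `pf_network` (or fixture name for convenience).
#' @param N_values,q_values Grids of ploidy and replication accuracy.
#' @param solver `"exact"`, `"abm"`, or `"both"`.
#' @param pop_size,generations Agent-based run size.
#' @param replicates Agent-based replicates per grid point.
#' @param seed Master seed for the agent-based replicates.
#' @param coexist_threshold Passed to the coexistence observable.
#' @param cap Exact-solver lattice cap.
#' @param cache_dir Optional directory; per-point results are stored as JSON
#'   keyed by (network, solver, N, q, replicate, seed) and reused on rerun.
#' @return data.frame with one row per grid point (and replicate), columns
#'   `network`, `solver`, `N`, `q`, `replicate`, `seed`, `coexistence`,
#'   `mean_flux`, `defective_frequency`, `W_bar`, `status`.
#' @export
scan_observables <- function(network, N_values, q_values = 1,
                             solver = c("exact", "abm", "both"),
                             pop_size = 1000, generations = 5000,
                             replicates = 1, seed = 1,
                             coexist_threshold = 1L, cap = 1e5,
                             cache_dir = NULL) {
  if (is.character(network)) network <- network_fixture(network)
  stopifnot(inherits(network, "pf_network"))
  solver <- match.arg(solver)
  solvers <- if (solver == "both") c("exact", "abm") else solver
  flux <- flux_function(network)
  g <- length(network$catalysts)
  rows <- list()
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)

  point_row <- function(slv, N, q, rep_i, seed_i) {
    key <- sprintf("%s_%s_N%d_q%s_r%d_s%d", network$name, slv, N,
                   gsub("\\.", "p", format(q)), rep_i, seed_i)
    if (!is.null(cache_dir)) {
      cf <- file.path(cache_dir, paste0(key, ".json"))
      if (file.exists(cf))
        return(as.data.frame(jsonlite::read_json(cf, simplifyVector = TRUE),
                             stringsAsFactors = FALSE))
    }
    row <- data.frame(network = network$name, solver = slv, N = N, q = q,
                      replicate = rep_i, seed = seed_i,
                      coexistence = NA_real_, mean_flux = NA_real_,
                      defective_frequency = NA_real_, W_bar = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      params <- lifecycle_params(N = N, q = q, g = g)
      if (slv == "exact") {
        st <- stationary_distribution(build_kernel(flux, params, cap = cap))
        list(coex = coexistence_fraction(st, threshold = coexist_threshold),
             mf = as.numeric(mean_flux(st)),
             df = defective_frequency(st), wb = st$W_bar)
      } else {
        ab <- run_agent_based(flux, params, pop_size = pop_size,
                              generations = generations, seed = seed_i,
                              coexist_threshold = coexist_threshold)
        if (ab$status != "ok") stop("population extinct")
        list(coex = coexistence_fraction(ab),
             mf = as.numeric(mean_flux(ab)),
             df = defective_frequency(ab), wb = NA_real_)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- conditionMessage(res)
    } else {
      row$coexistence <- res$coex
      row$mean_flux <- res$mf
      row$defective_frequency <- res$df
      row$W_bar <- res$wb
    }
    if (!is.null(cache_dir))
      jsonlite::write_json(row, file.path(cache_dir, paste0(key, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    row
  }

  for (slv in solvers) {
    for (N in N_values) for (q in q_values) {
      nrep <- if (slv == "abm") replicates else 1L
      for (rep_i in seq_len(nrep)) {
        seed_i <- derive_seed(seed, N, q, rep_i)
        rows[[length(rows) + 1L]] <- point_row(slv, N, q, rep_i, seed_i)
      }
    }
  }
  do.call(rbind, rows)
}

# replicate seeds derived from the master seed; kept below 2^31
derive_seed <- function(seed, N, q, rep_i) {
  as.integer((seed * 7919 + N * 104729 + round(q * 1e4) * 31 +
                rep_i * 65537) %% .Machine$integer.max)
}
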