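# The protocell life-cycle.
#
# Development: 2N independent samplings with replacement from the initial
# contents, each draw copying functional type i with probability q*j_i/N and
# producing the defective type omega with probability 1 - q + q*j_omega/N
# (mutation acts per draw; omega is an irreversible sink).
# Assortment: the 2N sequences split uniformly into two daughters of N each
# (multivariate hypergeometric).
#
# Compositions are integer vectors over the g functional types plus omega,
# with omega always the last entry.

#' Life-cycle parameters
#'
#' @param N Ploidy: total sequence count at the start of the life-cycle.
#' @param q Replication accuracy in \[0, 1\]; alternatively derive it from a
#'   per-base error probability `mu` and sequence length `L` as
#'   `q = (1 - mu)^L`.
#' @param g Number of functional sequence types (the defective type omega is
#'   implicit and always last).
#' @param mu,L Optional per-base error probability and sequence length.
#' @return Object of class `pf_params`.
#' @export
lifecycle_params <- function(N, q = NULL, g, mu = NULL, L = NULL) {
  if (is.null(q)) {
    if (is.null(mu) || is.null(L))
      stop("supply q, or both mu and L", call. = FALSE)
    q <- (1 - mu)^L
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
    stop("q must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g < 1 || g != round(g))
    stop("g must be a positive integer", call. = FALSE)
  structure(list(N = as.integer(N), q = as.numeric(q), g = as.integer(g)),
            class = "pf_params")
}

check_composition <- function(j, params, total) {
  if (length(j) != params$g + 1L)
    stop("composition must have g + 1 = ", params$g + 1L,
         " entries (defective type last)", call. = FALSE)
  if (any(j < 0) || any(j != round(j)))
    stop("composition counts must be nonnegative integers", call. = FALSE)
  if (sum(j) != total)
    stop("composition must sum to ", total, ", got ", sum(j), call. = FALSE)
  as.numeric(j)
}

# Per-draw replication probabilities (Wright-Fisher with mutation to omega).
# j: matrix with g+1 columns (omega last), rows summing to N.
draw_probs <- function(j, params) {
  if (is.null(dim(j))) j <- matrix(j, nrow = 1)
  p <- params$q * j / params$N
  p[, params$g + 1L] <- 1 - params$q + params$q * j[, params$g + 1L] / params$N
  p
}

# log multinomial pmf for count rows M, probability rows P (same dim)
log_dmultinom_rows <- function(M, P, size) {
  lp <- log(P)
  term <- M * lp
  term[M == 0] <- 0                      # 0 * log(0) := 0
  lgamma(size + 1) - rowSums(lgamma(M + 1)) + rowSums(term)
}

new_distribution <- function(counts, prob, total) {
  structure(list(counts = counts, prob = prob, total = total),
            class = "pf_distribution")
}

#' @export
print.pf_distribution <- function(x, ...) {
  cat("<pf_distribution> over", nrow(x$counts), "compositions of total",
      x$total, "\n")
  invisible(x)
}

#' Exact development distribution
#'
#' Distribution of the post-development composition `k` (total `2N`) given
#' the initial composition `j` (total `N`): a multinomial over 2N draws with
#' the per-draw mutation-aware probabilities.
#'
#' @param j Integer composition of length `g + 1` (defective type last),
#'   summing to `N`.
#' @param params A [lifecycle_params()] object.
#' @return A `pf_distribution`: a matrix of compositions (rows, total `2N`)
#'   and their probabilities (summing to 1).
#' @export
development_distribution <- function(j, params) {
  j <- check_composition(j, params, params$N)
  K <- enumerate_compositions(2L * params$N, params$g, include_sink = TRUE)
  p <- draw_probs(j, params)
  P <- matrix(p, nrow = nrow(K), ncol = length(p), byrow = TRUE)
  prob <- exp(log_dmultinom_rows(K, P, 2 * params$N))
  prob[rowSums(K[, p == 0, drop = FALSE]) > 0] <- 0   # impossible outcomes
  new_distribution(K, prob, 2L * params$N)
}

#' Exact assortment distribution
#'
#' Distribution of one daughter composition `m` (total `N`) when a developed
#' protocell of composition `k` (total `2N`) splits in half uniformly at
#' random: multivariate hypergeometric,
#' \eqn{P(m|k) = \prod_i C(k_i, m_i) / C(2N, N)}. The second daughter is
#' `k - m`; the law is symmetric under swapping daughters.
#'
#' @param k Integer composition of length `g + 1` summing to `2N`.
#' @param N Ploidy of each daughter.
#' @return A `pf_distribution` over daughter compositions.
#' @export
assortment_distribution <- function(k, N) {
  if (any(k < 0) || sum(k) != 2 * N)
    stop("k must be nonnegative and sum to 2N", call. = FALSE)
  g1 <- length(k)
  M <- enumerate_compositions(N, g1 - 1L, include_sink = TRUE)
  ok <- rep(TRUE, nrow(M))
  for (i in seq_len(g1)) ok <- ok & M[, i] <= k[i]
  M <- M[ok, , drop = FALSE]
  logp <- rowSums(matrix(lchoose(rep(k, each = nrow(M)), M), nrow = nrow(M))) -
    lchoose(2 * N, N)
  new_distribution(M, exp(logp), N)
}

#' Marginal law of one daughter over the whole life-cycle
#'
#' The composed development-then-assortment process factorises: each daughter
#' is marginally a multinomial over `N` draws with the same per-draw
#' probabilities as development (a Wright-Fisher step). This function returns
#' that marginal exactly; it equals the brute-force marginalisation of
#' [development_distribution()] composed with [assortment_distribution()].
#'
#' @inheritParams development_distribution
#' @return A `pf_distribution` over daughter compositions (total `N`).
#' @export
lifecycle_offspring_marginal <- function(j, params) {
  j <- check_composition(j, params, params$N)
  M <- enumerate_compositions(params$N, params$g, include_sink = TRUE)
  p <- draw_probs(j, params)
  P <- matrix(p, nrow = nrow(M), ncol = length(p), byrow = TRUE)
  prob <- exp(log_dmultinom_rows(M, P, params$N))
  prob[rowSums(M[, p == 0, drop = FALSE]) > 0] <- 0
  new_distribution(M, prob, params$N)
}

# ---- vectorised samplers ---------------------------------------------------

# Multinomial rows: one draw of `size` balls per row of probability matrix P
# (rows need not be exactly normalised; they are renormalised defensively).
rmultinom_rows <- function(size, P) {
  R <- nrow(P); Tn <- ncol(P)
  P <- P / rowSums(P)
  out <- matrix(0L, R, Tn)
  remaining <- rep.int(size, R)
  cumrem <- rep(1, R)
  for (t in seq_len(Tn - 1L)) {
    p <- ifelse(cumrem > 0, pmin(pmax(P[, t] / cumrem, 0), 1), 0)
    out[, t] <- stats::rbinom(R, remaining, p)
    remaining <- remaining - out[, t]
    cumrem <- cumrem - P[, t]
  }
  out[, Tn] <- remaining
  out
}

# Multivariate hypergeometric rows: draw `n` of the rowSums(K) items without
# replacement, categories = columns.
rmvhyper_rows <- function(K, n) {
  R <- nrow(K); Tn <- ncol(K)
  out <- matrix(0L, R, Tn)
  need <- rep.int(n, R)
  tot <- rowSums(K)
  for (t in seq_len(Tn - 1L)) {
    out[, t] <- stats::rhyper(R, K[, t], tot - K[, t], need)
    need <- need - out[, t]
    tot <- tot - K[, t]
  }
  out[, Tn] <- need
  out
}

#' Sample one protocell life-cycle
#'
#' Draws the developed composition `k ~ Multinomial(2N, p(j))`, splits it by
#' multivariate hypergeometric assortment, and returns both daughters. Note
#' the daughters are exchangeable and marginally Wright-Fisher, but *not*
#' independent given `j` (they share the realised `k`).
#'
#' @inheritParams development_distribution
#' @param n Number of independent life-cycles to sample.
#' @return A list with integer matrices `daughter1`, `daughter2`, `developed`
#'   (`n` rows each); daughters sum row-wise to `developed`.
#' @export
sample_lifecycle <- function(j, params, n = 1) {
  j <- check_composition(j, params, params$N)
  p <- draw_probs(j, params)
  P <- matrix(p, nrow = n, ncol = length(p), byrow = TRUE)
  k <- rmultinom_rows(2L * params$N, P)
  m <- rmvhyper_rows(k, params$N)
  list(daughter1 = m, daughter2 = k - m, developed = k)
}

#' Export a distribution as a tidy table
#'
#' @param x A `pf_distribution`.
#' @param types Optional type names for the count columns.
#' @return A data.frame with one count column per type plus `prob`.
#' @export
as.data.frame.pf_distribution <- function(x, row.names = NULL,
                                          optional = FALSE, types = NULL, ...) {
  d <- as.data.frame(x$counts)
  names(d) <- types %||% c(paste0("type", seq_len(ncol(x$counts) - 1L)),
                           "omega")
  d$prob <- x$prob
  d
}
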