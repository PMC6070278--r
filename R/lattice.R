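# Enumeration of the composition lattice.

#' Enumerate all compositions of N sequences over the type set
#'
#' Lists every composition of `N` over `g` functional types (plus, by
#' default, the defective type omega as a trailing column), in deterministic
#' lexicographic order (first coordinate descending). The lattice size is
#' `choose(N + T - 1, T - 1)` for `T` columns.
#'
#' @param N Ploidy.
#' @param g Number of functional types.
#' @param include_sink Include the defective-type column (default `TRUE`).
#' @param cap Refuse to enumerate lattices larger than this (default `1e5`);
#'   larger problems should use the agent-based solver.
#' @return Integer matrix, one composition per row; rows sum to `N`.
#' @export
enumerate_compositions <- function(N, g, include_sink = TRUE, cap = 1e5) {
  stopifnot(N >= 0, g >= 1)
  Tn <- g + as.integer(include_sink)
  size <- choose(N + Tn - 1, Tn - 1)
  if (size > cap)
    stop("composition lattice has ", format(size, big.mark = ","),
         " states (> cap ", format(cap, big.mark = ","),
         "); use the agent-based solver for this problem size",
         call. = FALSE)
  rec <- function(n, k) {
    if (k == 1L) return(matrix(n))
    do.call(rbind, lapply(n:0, function(f) cbind(f, rec(n - f, k - 1L))))
  }
  m <- rec(N, Tn)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# index of composition rows within a lattice (both matrices, same columns)
composition_index <- function(lattice, m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  key <- function(x) apply(x, 1, paste, collapse = ",")
  match(key(m), key(lattice))
}
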