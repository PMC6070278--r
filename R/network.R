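# Catalysed reaction networks: metabolites, catalysts, wiring and validation.
#
# Networks are irreversible and feed-forward: environmental inputs are held
# constant, intermediates are produced by exactly one catalyst and consumed by
# at most one (non-competing reactions), and a single critical output
# metabolite collects the fitness-defining flux.

#' Declare a metabolite
#'
#' @param id Metabolite name (single non-empty string).
#' @param kind One of `"intermediate"`, `"environmental_input"`,
#'   `"critical_output"`. Exactly one metabolite per network may be the
#'   critical output.
#' @param permeability Nonnegative leak/decay rate \eqn{\delta} (per time) of
#'   an intermediate through the vesicle membrane. Leaked intermediates are
#'   assumed degraded outside and never return. Ignored for environmental
#'   inputs and the critical output.
#' @return An object of class `pf_metabolite`.
#' @seealso [catalyst()], [network_spec()]
#' @export
metabolite <- function(id,
                       kind = c("intermediate", "environmental_input",
                                "critical_output"),
                       permeability = 0) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("metabolite id must be a single non-empty string", call. = FALSE)
  if (!is.numeric(permeability) || length(permeability) != 1L ||
      is.na(permeability) || permeability < 0)
    stop("permeability must be a single nonnegative number", call. = FALSE)
  structure(list(id = id, kind = kind, permeability = as.numeric(permeability)),
            class = "pf_metabolite")
}

#' Declare a catalyst (one sequence type catalysing one reaction)
#'
#' A catalyst converts one or two substrate metabolites into products with
#' fixed stoichiometry. A *saturated* catalyst (a keystone) consumes a
#' plentiful environmental input and runs at its limiting velocity
#' \eqn{k_{cat} [E]}; all other catalysts follow Michaelis-Menten kinetics in
#' their intermediate substrate(s).
#'
#' @param id Catalyst name (single string), e.g. `"alpha"`.
#' @param kcat Catalytic constant (per time), strictly positive.
#' @param substrates Character vector of 1 or 2 metabolite ids.
#' @param products Named numeric vector: product metabolite id -> positive
#'   stoichiometric coefficient (this is where the `c_M` and `c_W`
#'   coefficients live).
#' @param Km Michaelis constant (concentration). Only used at finite
#'   permeability; it drops out of the piecewise-linear limit. Default 1.
#' @param saturated Logical; `TRUE` for keystones. Requires a single
#'   environmental-input substrate.
#' @param a1,a2 Bimolecular interaction constants of the two-substrate rate
#'   law (finite-permeability only). Must be given iff `substrates` has
#'   length 2; default 1 corresponds to the non-interacting reference case.
#' @return An object of class `pf_catalyst`.
#' @export
catalyst <- function(id, kcat, substrates, products, Km = 1,
                     saturated = FALSE, a1 = NULL, a2 = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("catalyst id must be a single non-empty string", call. = FALSE)
  if (!is.numeric(kcat) || length(kcat) != 1L || is.na(kcat) || kcat <= 0)
    stop("kcat must be a single positive number", call. = FALSE)
  if (!is.numeric(Km) || length(Km) != 1L || is.na(Km) || Km <= 0)
    stop("Km must be a single positive number", call. = FALSE)
  if (!is.character(substrates) || !(length(substrates) %in% c(1L, 2L)))
    stop("a catalyst takes 1 or 2 substrate metabolite ids", call. = FALSE)
  if (length(products) < 1L || is.null(names(products)) ||
      any(!nzchar(names(products))) || !is.numeric(products))
    stop("products must be a named numeric vector", call. = FALSE)
  if (any(is.na(products)) || any(products <= 0))
    stop("stoichiometric coefficients must be positive", call. = FALSE)
  bimol <- length(substrates) == 2L
  if (bimol) {
    if (is.null(a1)) a1 <- 1
    if (is.null(a2)) a2 <- 1
    if (!is.numeric(a1) || !is.numeric(a2) || a1 < 0 || a2 < 0)
      stop("a1 and a2 must be nonnegative numbers", call. = FALSE)
  } else if (!is.null(a1) || !is.null(a2)) {
    stop("a1/a2 are only meaningful for bimolecular catalysts", call. = FALSE)
  }
  structure(list(id = id, kcat = as.numeric(kcat), Km = as.numeric(Km),
                 substrates = substrates,
                 products = vapply(products, as.numeric, numeric(1)),
                 saturated = isTRUE(saturated),
                 a1 = if (bimol) as.numeric(a1) else NULL,
                 a2 = if (bimol) as.numeric(a2) else NULL),
            class = "pf_catalyst")
}

#' Assemble and validate a catalysed reaction network
#'
#' Performs full structural validation: unique ids, known metabolite
#' references, exactly one critical output, environmental inputs never
#' produced, every consumed intermediate produced by exactly one upstream
#' catalyst and consumed by at most one catalyst (non-competing reactions),
#' acyclicity of the intermediate digraph, at least one saturated keystone,
#' and the saturation/substrate-kind constraints. The topological order of
#' the catalysts is computed once and stored.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param catalysts List of [catalyst()] objects.
#' @param name Label for the network.
#' @return An object of class `pf_network` with fields `name`, `metabolites`
#'   (named list), `catalysts` (named list), `order` (catalyst ids in
#'   topological order), `critical` (id of the critical output).
#' @export
network_spec <- function(metabolites, catalysts, name = "network") {
  if (inherits(metabolites, "pf_metabolite")) metabolites <- list(metabolites)
  if (inherits(catalysts, "pf_catalyst")) catalysts <- list(catalysts)
  stopifnot(length(metabolites) >= 2L, length(catalysts) >= 1L)
  mids <- vapply(metabolites, `[[`, character(1), "id")
  cids <- vapply(catalysts, `[[`, character(1), "id")
  if (anyDuplicated(mids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(cids)) stop("duplicate catalyst ids", call. = FALSE)
  if (length(intersect(mids, cids)))
    stop("metabolite and catalyst ids must be disjoint", call. = FALSE)
  names(metabolites) <- mids
  names(catalysts) <- cids

  kinds <- vapply(metabolites, `[[`, character(1), "kind")
  crit <- mids[kinds == "critical_output"]
  if (length(crit) != 1L)
    stop("network must contain exactly one critical_output metabolite",
         call. = FALSE)

  # wiring maps
  producer <- consumer <- stats::setNames(vector("list", length(mids)), mids)
  for (ct in catalysts) {
    unknown <- setdiff(c(ct$substrates, names(ct$products)), mids)
    if (length(unknown))
      stop("catalyst '", ct$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (s in ct$substrates) consumer[[s]] <- c(consumer[[s]], ct$id)
    for (p in names(ct$products)) producer[[p]] <- c(producer[[p]], ct$id)
  }

  for (m in mids) {
    k <- kinds[[m]]
    if (k == "environmental_input" && length(producer[[m]]))
      stop("environmental input '", m, "' must not be produced inside the ",
           "network", call. = FALSE)
    if (k == "critical_output" && length(consumer[[m]]))
      stop("the critical output must not be consumed by a catalyst",
           call. = FALSE)
    if (k == "intermediate" && length(consumer[[m]])) {
      if (length(consumer[[m]]) > 1L)
        stop("intermediate '", m, "' is consumed by more than one catalyst; ",
             "competing reactions are not modelled (build networks with ",
             "non-competing waste streams)", call. = FALSE)
      if (length(producer[[m]]) != 1L)
        stop("consumed intermediate '", m, "' must be produced by exactly ",
             "one upstream catalyst", call. = FALSE)
    }
  }

  for (ct in catalysts) {
    skinds <- kinds[ct$substrates]
    if (ct$saturated) {
      if (length(ct$substrates) != 1L || skinds != "environmental_input")
        stop("saturated catalyst '", ct$id, "' must take a single ",
             "environmental_input substrate", call. = FALSE)
    } else if (any(skinds != "intermediate")) {
      stop("unsaturated catalyst '", ct$id, "' may only consume ",
           "intermediates", call. = FALSE)
    }
  }
  if (!any(vapply(catalysts, `[[`, logical(1), "saturated")))
    stop("network needs at least one saturated (keystone) catalyst",
         call. = FALSE)

  # topological order via Kahn's algorithm on the catalyst dependency graph:
  # a catalyst depends on the producer of each of its intermediate substrates.
  deps <- lapply(catalysts, function(ct) {
    ints <- ct$substrates[kinds[ct$substrates] == "intermediate"]
    unique(unlist(lapply(ints, function(m) producer[[m]])))
  })
  order <- character(0)
  remaining <- cids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id)
      all(deps[[id]] %in% order), logical(1))]
    if (!length(ready))
      stop("the intermediate digraph contains a cycle; only irreversible ",
           "feed-forward networks are supported", call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  structure(list(name = name, metabolites = metabolites,
                 catalysts = catalysts, order = order, critical = crit),
            class = "pf_network")
}

#' @export
print.pf_network <- function(x, ...) {
  cat("<pf_network> ", x$name, ": ", length(x$catalysts), " catalysts, ",
      length(x$metabolites), " metabolites, critical output '", x$critical,
      "'\n", sep = "")
  for (id in x$order) {
    ct <- x$catalysts[[id]]
    cat("  ", id, if (ct$saturated) " [keystone]" else "", ": ",
        paste(ct$substrates, collapse = " + "), " -> ",
        paste(sprintf("%g %s", ct$products, names(ct$products)),
              collapse = " + "),
        "  (kcat=", ct$kcat, ")\n", sep = "")
  }
  invisible(x)
}

#' Functional sequence types of a network
#'
#' @param network A `pf_network`.
#' @return Character vector of catalyst ids in topological order; the number
#'   of functional types `g` is its length.
#' @export
functional_types <- function(network) {
  stopifnot(inherits(network, "pf_network"))
  network$order
}

# ---- serialization ---------------------------------------------------------

as_network_list <- function(network) {
  list(
    name = network$name,
    metabolites = lapply(unname(network$metabolites), function(m)
      list(id = m$id, kind = m$kind, permeability = m$permeability)),
    catalysts = lapply(unname(network$catalysts), function(ct) {
      out <- list(id = ct$id, kcat = ct$kcat, Km = ct$Km,
                  substrates = as.list(ct$substrates),
                  products = as.list(ct$products),
                  saturated = ct$saturated)
      if (!is.null(ct$a1)) { out$a1 <- ct$a1; out$a2 <- ct$a2 }
      out
    })
  )
}

network_from_list <- function(lst) {
  mets <- lapply(lst$metabolites, function(m)
    metabolite(m$id, m$kind, m$permeability %||% 0))
  cats <- lapply(lst$catalysts, function(ct)
    catalyst(ct$id, ct$kcat,
             substrates = as.character(unlist(ct$substrates)),
             products = unlist(ct$products),
             Km = ct$Km %||% 1,
             saturated = isTRUE(ct$saturated),
             a1 = ct$a1, a2 = ct$a2))
  network_spec(mets, cats, name = lst$name %||% "network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a network document (JSON)
#'
#' The on-disk format mirrors the network specification: a JSON object with
#' `name`, `metabolites` and `catalysts`. Reading validates the document.
#'
#' @param path File path.
#' @param network A `pf_network`.
#' @return `read_network_json()` returns a validated `pf_network`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
read_network_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  network_from_list(lst)
}

#' @rdname read_network_json
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "pf_network"))
  jsonlite::write_json(as_network_list(network), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
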