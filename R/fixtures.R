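# Built-in network fixtures.
#
# Default kinetic/stoichiometric parameters are the ones used for the
# published coexistence-transition experiments; every default can be
# overridden through `...` of network_fixture().

fixture_builders <- list(

  # alpha: A -> M + cw_alpha W ; beta: W -> cM_beta M
  keystone_recycler = function(kcat_alpha = 1, cw_alpha = 1,
                               kcat_beta = 2, cM_beta = 1.5,
                               delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A",
                    c(M = 1, W = cw_alpha), saturated = TRUE),
           catalyst("beta", kcat_beta, "W", c(M = cM_beta), Km = Km)),
      name = "keystone_recycler")
  },

  # chain alpha -> beta -> gamma, unit waste stoichiometry
  serial3 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                     cM_beta = 4, cM_gamma = 4, delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A", c(M = 1, W1 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "W1", c(M = cM_beta, W2 = 1), Km = Km),
           catalyst("gamma", kcat_gamma, "W2", c(M = cM_gamma), Km = Km)),
      name = "serial3")
  },

  # alpha feeds two independent waste streams recycled in parallel
  parallel3 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                       cM_beta = 4, cM_gamma = 4, delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A", c(M = 1, W1 = 1, W2 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "W1", c(M = cM_beta), Km = Km),
           catalyst("gamma", kcat_gamma, "W2", c(M = cM_gamma), Km = Km)),
      name = "parallel3")
  },

  # two keystones whose wastes are joined by a bimolecular recycler
  bimolecular3 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                          cM_alpha = 2.5, cM_beta = 2.5, cM_gamma = 4,
                          a1 = 1, a2 = 1, delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A1", "environmental_input"),
           metabolite("A2", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A1", c(M = cM_alpha, W1 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "A2", c(M = cM_beta, W2 = 1),
                    saturated = TRUE),
           catalyst("gamma", kcat_gamma, c("W1", "W2"), c(M = cM_gamma),
                    Km = Km, a1 = a1, a2 = a2)),
      name = "bimolecular3")
  },

  # four-catalyst chain
  serial4 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                     kcat_theta = 1, cM_beta = 6, cM_gamma = 6, cM_theta = 6,
                     delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta),
           metabolite("W3", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A", c(M = 1, W1 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "W1", c(M = cM_beta, W2 = 1), Km = Km),
           catalyst("gamma", kcat_gamma, "W2", c(M = cM_gamma, W3 = 1),
                    Km = Km),
           catalyst("theta", kcat_theta, "W3", c(M = cM_theta), Km = Km)),
      name = "serial4")
  },

  # three parallel recyclers off one keystone
  parallel4 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                       kcat_theta = 1, cM_beta = 6, cM_gamma = 6,
                       cM_theta = 6, delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta),
           metabolite("W3", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A", c(M = 1, W1 = 1, W2 = 1, W3 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "W1", c(M = cM_beta), Km = Km),
           catalyst("gamma", kcat_gamma, "W2", c(M = cM_gamma), Km = Km),
           catalyst("theta", kcat_theta, "W3", c(M = cM_theta), Km = Km)),
      name = "parallel4")
  },

  # parallel pair whose secondary wastes feed a terminal bimolecular recycler
  bimolecular4 = function(kcat_alpha = 1, kcat_beta = 1, kcat_gamma = 1,
                          kcat_theta = 1, cM_beta = 6, cM_gamma = 6,
                          cM_theta = 6, a1 = 1, a2 = 1,
                          delta = 0.01, Km = 1) {
    network_spec(
      list(metabolite("A", "environmental_input"),
           metabolite("M", "critical_output"),
           metabolite("W1", "intermediate", permeability = delta),
           metabolite("W2", "intermediate", permeability = delta),
           metabolite("V1", "intermediate", permeability = delta),
           metabolite("V2", "intermediate", permeability = delta)),
      list(catalyst("alpha", kcat_alpha, "A", c(M = 1, W1 = 1, W2 = 1),
                    saturated = TRUE),
           catalyst("beta", kcat_beta, "W1", c(M = cM_beta, V1 = 1), Km = Km),
           catalyst("gamma", kcat_gamma, "W2", c(M = cM_gamma, V2 = 1),
                    Km = Km),
           catalyst("theta", kcat_theta, c("V1", "V2"), c(M = cM_theta),
                    Km = Km, a1 = a1, a2 = a2)),
      name = "bimolecular4")
  }
)

fixture_notes <- c(
  keystone_recycler = paste(
    "Two-catalyst keystone/recycler chain. Default = near-boundary kinetics",
    "(kcat_beta=2, cM_beta=1.5); far-boundary variant: cw_alpha=2,",
    "kcat_beta=1, cM_beta=2 (same maximum flux, peak at beta frequency 2/3)."),
  serial3 = "Serial recycler chain; all kcat=1, cM_beta=cM_gamma=4.",
  parallel3 = "Parallel recyclers; all kcat=1, cM_beta=cM_gamma=4.",
  bimolecular3 = paste(
    "Two keystones joined by a bimolecular recycler; all kcat=1,",
    "cM_alpha=cM_beta=2.5, cM_gamma=4."),
  serial4 = "Four-catalyst chain; cM_beta=cM_gamma=cM_theta=6 (equal benefit).",
  parallel4 = "Three parallel recyclers; cM_beta=cM_gamma=cM_theta=6.",
  bimolecular4 = paste(
    "Parallel pair with a terminal bimolecular recycler; equal-benefit",
    "default cM_theta=6, high-benefit variant cM_theta=10.")
)

#' Built-in network fixtures
#'
#' `network_fixture()` instantiates one of the seven built-in networks, with
#' any kinetic or stoichiometric parameter overridden through `...`.
#' `list_fixtures()` summarises the available fixtures and their defaults.
#'
#' Fixtures: `keystone_recycler`, `serial3`, `parallel3`, `bimolecular3`,
#' `serial4`, `parallel4`, `bimolecular4`.
#'
#' @param name Fixture name.
#' @param ... Parameter overrides, e.g. `cw_alpha = 2` or `cM_theta = 10`.
#' @return `network_fixture()`: a validated `pf_network`. `list_fixtures()`:
#'   a data.frame with columns `name`, `defaults`, `note`.
#' @examples
#' net <- network_fixture("keystone_recycler", cw_alpha = 2,
#'                        kcat_beta = 1, cM_beta = 2)
#' network_flux(net, c(alpha = 10, beta = 20))
#' @export
network_fixture <- function(name, ...) {
  if (!name %in% names(fixture_builders))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixture_builders), collapse = ", "), call. = FALSE)
  builder <- fixture_builders[[name]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(formals(builder)))
  if (length(unknown))
    stop("unknown parameter(s) for fixture '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(builder, dots)
}

#' @rdname network_fixture
#' @export
list_fixtures <- function() {
  data.frame(
    name = names(fixture_builders),
    defaults = vapply(names(fixture_builders), function(nm) {
      fm <- formals(fixture_builders[[nm]])
      paste(sprintf("%s=%s", names(fm), vapply(fm, deparse, character(1))),
            collapse = ", ")
    }, character(1)),
    note = unname(fixture_notes[names(fixture_builders)]),
    row.names = NULL, stringsAsFactors = FALSE)
}
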