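# synthetic_data: stand-in for the SANDALS measurements. Generates target
# F(Q) contrast sets from a known "truth" potential (seed force field plus an
# imposed Gaussian perturbation) with additive Gaussian noise, so refinement
# and analysis are testable end to end without any measured data.

#' The five glycine isotopologue contrasts
#'
#' Gly-H5 (natural glycine), Gly-D2 (deuterated methylene group), Gly-D3
#' (deuterated amino group), Gly-50/50 (50% mixture of natural and fully
#' deuterated glycine) and Gly-D5 (fully deuterated glycine). The solvent
#' pairing is not part of the measured-sample description and is a shipped
#' assumption: each solute labeling sits in matching water (H2O for H5/D2,
#' D2O for D3/D5, 1:1 for the 50/50 mixture), so exchangeable amino
#' hydrogens keep the isotopic identity of their labeling.
#'
#' @param system The glycine [system_spec()] the contrasts refer to
#'   (default the full printed box; pass a scaled system for reduced runs).
#' @return List of five [contrast_definition()]s.
#' @export
glycine_contrast_suite <- function(system = load_builtin_system("glycine")) {
  schemes <- list(
    contrast_scheme("Gly-H5", water_d = 0),
    contrast_scheme("Gly-D2", solute_d = c(M = 1), water_d = 0),
    contrast_scheme("Gly-D3", solute_d = c(H = 1), water_d = 1),
    contrast_scheme("Gly-50/50", solute_d = c(M = 0.5, H = 0.5),
                    water_d = 0.5),
    contrast_scheme("Gly-D5", solute_d = c(M = 1, H = 1), water_d = 1))
  lapply(schemes, function(s) contrast_definition(system, s))
}

#' Specification of a synthetic "truth" measurement
#'
#' @param base Built-in system name (default "glycine").
#' @param scale System scale factor (see [load_builtin_system()]).
#' @param pair Site pair carrying the imposed perturbation (default
#'   `c("O", "Hw")`, the hydrogen-bond pair the analysis fingerprints).
#' @param depth Gaussian well depth, kJ/mol (default -1.5, a
#'   shell-strengthening well; |depth| must not exceed `cap`).
#' @param center Well center, Angstrom (default 1.8, the O...Hw
#'   hydrogen-bond distance).
#' @param width Gaussian sigma, Angstrom (default 0.25).
#' @param noise_frac Noise sigma as a fraction of max|F| per contrast
#'   (default 0.01).
#' @param cap Perturbation amplitude cap, kJ/mol.
#' @param seed RNG seed for the truth simulation and the noise.
#' @param mc [mc_settings()] for the truth simulation.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(base = "glycine", scale = 1, pair = c("O", "Hw"),
                       depth = -1.5, center = 1.8, width = 0.25,
                       noise_frac = 0.01, cap = 2.5, seed = 1,
                       mc = mc_settings(n_equilibration = 1000,
                                        n_production = 10000,
                                        sample_every = 10)) {
  stopifnot(width > 0, abs(depth) <= cap)
  structure(list(base = base, scale = scale, pair = pair, depth = depth,
                 center = center, width = width, noise_frac = noise_frac,
                 cap = cap, seed = seed, mc = mc), class = "truth_spec")
}

#' Generate a synthetic target F(Q) contrast set from a known truth
#'
#' Simulates the truth system (seed force field plus the imposed Gaussian
#' perturbation), computes the partial structure factors, weighs them into
#' each contrast's F(Q) and adds i.i.d. Gaussian noise. The truth g(r)
#' curves and the truth perturbation are archived for recovery scoring.
#' Fully seeded: a fixed seed reproduces the targets exactly.
#'
#' @param truth A [truth_spec()].
#' @param contrasts Optional list of [contrast_definition()]s; default the
#'   five glycine contrasts for the (scaled) truth system.
#' @param Q Q grid.
#' @param dr RDF bin width for the partials.
#' @param window Transform window.
#' @return A list of class `synthetic_targets`: `targets` (noisy
#'   `total_fq_set`), `clean` (noise-free set), `sigma` (per-contrast noise
#'   sigma), `truth_rdfs` (archive of all truth pair RDFs), `truth_pert`,
#'   `system`, `contrasts`, `truth` (the generating truth_spec).
#' @export
generate_target_fq <- function(truth, contrasts = NULL,
                               Q = seq(0.3, 12, by = 0.05), dr = 0.05,
                               window = "lorch") {
  stopifnot(inherits(truth, "truth_spec"))
  set.seed(truth$seed)
  system <- load_builtin_system(truth$base, scale = truth$scale)
  if (is.null(contrasts)) {
    if (truth$base != "glycine") {
      .stopf("pass `contrasts` explicitly for base '%s'", truth$base)
    }
    contrasts <- glycine_contrast_suite(system)
  }
  pert <- perturbation_potential(.system_pairs(system),
                                 rmax = truth$mc$cutoff, dr = 0.05,
                                 cap = truth$cap)
  pert <- pert_add_gaussian(pert, truth$pair, truth$depth, truth$center,
                            truth$width)
  ens <- run_simulation(system, truth$mc, perturbation = pert)
  clean <- ensemble_total_fq(ens, contrasts, Q, dr = dr, window = window)
  sigma <- truth$noise_frac * apply(abs(clean$F), 2, max)
  noisy <- clean
  for (k in seq_len(ncol(noisy$F))) {
    noisy$F[, k] <- noisy$F[, k] + rnorm(length(Q), 0, sigma[k])
  }
  noisy$partials <- NULL
  noisy$sigma <- sigma        # stated per-contrast uncertainty of the targets
  structure(list(targets = noisy, clean = clean, sigma = sigma,
                 truth_rdfs = clean$partials$rdfs, truth_pert = pert,
                 ensemble = ens, system = system, contrasts = contrasts,
                 truth = truth), class = "synthetic_targets")
}

# Build a simulation_box by hand from explicit molecule placements.
.manual_box <- function(system, centers, quats) {
  topologies <- lapply(system$components, function(cc) cc$topology)
  counts <- vapply(system$components, function(cc) cc$count, integer(1))
  inst_topo <- rep(seq_along(topologies), counts)
  templates <- lapply(topologies, function(tp) {
    unname(as.matrix(tp$atoms[, c("x", "y", "z")]))
  })
  natoms <- vapply(topologies, function(tp) nrow(tp$atoms), integer(1))
  mol_natoms <- natoms[inst_topo]
  M <- length(inst_topo)
  mol_first <- cumsum(c(0L, mol_natoms[-M]))
  atoms <- do.call(rbind, lapply(seq_len(M), function(m) {
    tp <- topologies[[inst_topo[m]]]
    data.frame(mol = m, topology = tp$name, label = tp$atoms$label,
               element = tp$sites$element[match(tp$atoms$label,
                                                tp$sites$label)],
               stringsAsFactors = FALSE)
  }))
  types <- .box_types(system)
  structure(list(L = system_box_length(system), centers = centers,
                 quats = quats, topo_of_mol = inst_topo,
                 topologies = topologies, templates = templates,
                 atoms = atoms, mol_first = as.integer(mol_first),
                 mol_natoms = as.integer(mol_natoms),
                 type_id = match(atoms$label, types$label), types = types,
                 system = system), class = "simulation_box")
}

#' Deterministic toy fixtures
#'
#' Small printed configurations reused across examples and tests:
#' \describe{
#'   \item{dimer}{A [build_box()]-compatible box of two SPC/E waters in a
#'     20 A cube, parallel orientations, oxygen-oxygen separation 2.8 A.}
#'   \item{debye10}{A 10-atom, two-species static configuration (labels
#'     "X", "Y") in an 80 A cube, every atom its own molecule; for direct
#'     Debye-sum cross-checks.}
#'   \item{angle180}{One glycine molecule plus one water whose oxygen lies
#'     on the Co-O axis, 2.5 A beyond the first carboxyl oxygen (alpha =
#'     180 degrees).}
#'   \item{angle90}{As angle180 but with the water oxygen perpendicular to
#'     the Co-O bond at the oxygen (alpha = 90 degrees).}
#' }
#'
#' @param name Fixture name.
#' @return A `simulation_box` ("dimer") or `mc_ensemble` (others).
#' @export
toy_fixture <- function(name = c("dimer", "debye10", "angle180", "angle90")) {
  name <- match.arg(name)
  if (name == "dimer") {
    n_at <- 6
    sys <- system_spec(c(water = 2), rho = n_at / 20^3)
    centers <- rbind(c(8, 10, 10), c(10.8, 10, 10))
    quats <- rbind(.quat_identity, .quat_identity)
    return(.manual_box(sys, centers, quats))
  }
  if (name == "debye10") {
    coords <- matrix(c(
      40.0, 40.0, 40.0,
      41.1, 40.3, 39.8,
      39.2, 41.0, 40.6,
      40.5, 38.9, 41.2,
      42.0, 41.5, 40.9,
      38.6, 39.4, 39.1,
      41.6, 38.8, 38.5,
      39.9, 42.1, 38.9,
      42.4, 39.7, 42.0,
      38.2, 41.8, 42.3), ncol = 3, byrow = TRUE)
    labels <- c(rep("X", 6), rep("Y", 4))
    return(static_ensemble(coords, labels, mol = 1:10, L = 80))
  }
  # angle fixtures: one glycine + one water, alpha at the first carboxyl O
  tp <- builtin_topology("glycine")
  X <- as.matrix(tp$atoms[, c("x", "y", "z")])
  co <- X[tp$carboxyl$carbon, ]
  o1 <- X[tp$carboxyl$oxygens[1], ]
  u <- .unitv(o1 - co)
  dir <- if (name == "angle180") u else {
    p <- c(0, 0, 1)
    .unitv(p - sum(p * u) * u)
  }
  ow <- o1 + 2.5 * dir
  hw1 <- ow + c(0.8165, 0.5774, 0)
  hw2 <- ow + c(-0.8165, 0.5774, 0)
  coords <- rbind(X, ow, hw1, hw2)
  coords <- sweep(coords, 2, c(25, 25, 25), "+")
  labels <- c(tp$atoms$label, "Ow", "Hw", "Hw")
  mol <- c(rep(1, nrow(X)), rep(2, 3))
  static_ensemble(coords, labels, mol, L = 50, topology = tp,
                  mol_topology = c("glycine", "water"))
}
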