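# forcefield_topology: molecular models, site parameters, rigid geometries
# and box compositions for the built-in aqueous systems.

#' Create a force-field site (parameter record for one site type)
#'
#' @param label Short site label, unique within a molecule (e.g. "O", "Co",
#'   "Oh", "M").
#' @param epsilon Lennard-Jones well depth, kJ/mol (>= 0).
#' @param sigma Lennard-Jones diameter, Angstrom (>= 0). Sites with
#'   `epsilon = sigma = 0` contribute no Lennard-Jones energy.
#' @param charge Fractional charge, elementary charge units.
#' @param element Chemical element symbol ("H", "C", "N", "O", "Cl").
#' @param exchangeable Logical; `TRUE` for hydrogens that exchange with the
#'   solvent (their neutron scattering length follows the solvent H/D ratio).
#' @return A list of class `forcefield_site`.
#' @export
forcefield_site <- function(label, epsilon, sigma, charge, element,
                            exchangeable = FALSE) {
  stopifnot(is.character(label), nchar(label) > 0,
            epsilon >= 0, sigma >= 0, is.logical(exchangeable))
  structure(list(label = label, epsilon = epsilon, sigma = sigma,
                 charge = charge, element = element,
                 exchangeable = exchangeable),
            class = "forcefield_site")
}

.sites_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(s) {
    data.frame(label = s[[1]], epsilon = s[[2]], sigma = s[[3]],
               charge = s[[4]], element = s[[5]], exchangeable = s[[6]],
               stringsAsFactors = FALSE)
  }))
}

#' Create a rigid molecule topology
#'
#' A topology couples a table of site types (Lennard-Jones and charge
#' parameters) with an ordered list of atoms carrying fixed local Cartesian
#' coordinates (the molecule is treated as a rigid body), plus an optional
#' carboxyl-group designation used by the hydration analysis.
#'
#' @param name Molecule name.
#' @param sites data.frame with columns label, epsilon, sigma, charge,
#'   element, exchangeable; labels must be unique.
#' @param atoms data.frame with columns label (referencing `sites$label`),
#'   x, y, z (Angstrom, local frame).
#' @param carboxyl `NULL`, or `list(carbon =, oxygens =)` with the atom
#'   indices (into `atoms`) of the carboxyl carbon and its one or two
#'   oxygens.
#' @param net_charge Net formal charge (e); the atom charges must sum to it
#'   within 1e-6 e.
#' @return A list of class `molecule_topology`. Local coordinates are
#'   re-centered on the molecular centroid.
#' @export
molecule_topology <- function(name, sites, atoms, carboxyl = NULL,
                              net_charge = 0) {
  stopifnot(is.data.frame(sites), is.data.frame(atoms))
  if (anyDuplicated(sites$label)) .stopf("duplicate site labels in %s", name)
  if (!all(atoms$label %in% sites$label)) {
    .stopf("atoms reference unknown site labels in %s", name)
  }
  if (any(sites$epsilon < 0) || any(sites$sigma < 0)) {
    .stopf("negative epsilon or sigma in %s", name)
  }
  q <- sites$charge[match(atoms$label, sites$label)]
  if (abs(sum(q) - net_charge) > 1e-6) {
    .stopf("%s: atom charges sum to %.8f, declared net charge %.8f",
           name, sum(q), net_charge)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 0.5) .stopf("%s: two sites closer than 0.5 Angstrom", name)
  }
  # center local frame on the centroid so rotations act about the center
  xyz <- sweep(xyz, 2, colMeans(xyz))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  if (!is.null(carboxyl)) {
    idx <- c(carboxyl$carbon, carboxyl$oxygens)
    if (any(idx < 1 | idx > nrow(atoms))) {
      .stopf("%s: carboxyl designation references missing atoms", name)
    }
  }
  structure(list(name = name, sites = sites, atoms = atoms,
                 carboxyl = carboxyl, net_charge = net_charge),
            class = "molecule_topology")
}

#' Net charge of a molecule
#'
#' Sum of the site charges over all atoms (with multiplicities).
#'
#' @param topology A [molecule_topology()].
#' @return Net charge in elementary charge units.
#' @export
molecule_net_charge <- function(topology) {
  q <- topology$sites$charge[match(topology$atoms$label,
                                   topology$sites$label)]
  sum(q)
}

#' Lennard-Jones cross parameters by geometric-mean combination
#'
#' Geometric mean for both epsilon and sigma (the OPLS convention the solute
#' reference potentials descend from). Symmetric in its arguments; any site
#' with `epsilon = sigma = 0` yields a zero cross interaction.
#'
#' @param site_a,site_b [forcefield_site()] objects or one-row data.frames
#'   with epsilon/sigma entries.
#' @return `list(epsilon =, sigma =)` in kJ/mol and Angstrom.
#' @export
combine_lj <- function(site_a, site_b) {
  list(epsilon = sqrt(site_a$epsilon * site_b$epsilon),
       sigma = sqrt(site_a$sigma * site_b$sigma))
}

# ---------------------------------------------------------------------------
# Built-in topologies. Site parameters are the reference-potential values of
# the solute models (OPLS-adapted) and SPC/E water; geometries are idealized
# standard geometries (carboxylate C-O 1.25 A, O-C-O 126 deg, C-C 1.53 A,
# tetrahedral sp3 centers) stored as explicit local coordinates so they are
# inspectable and overridable.

.carboxylate_oxy <- function(co, bisector, perp, half_angle = 63) {
  # two oxygens at 1.25 A from the carboxylate carbon, O-C-O = 126 deg,
  # symmetric about `bisector` in the plane spanned by bisector and perp
  b <- .unitv(bisector); p <- .unitv(perp)
  ca <- cos(half_angle * .deg2rad); sa <- sin(half_angle * .deg2rad)
  list(o1 = co + 1.25 * (ca * b + sa * p),
       o2 = co + 1.25 * (ca * b - sa * p))
}

.atom_rows <- function(labels, coords) {
  data.frame(label = labels, x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

.build_glycine <- function() {
  sites <- .sites_df(
    list("N",  0.71128, 3.25, -0.30, "N", FALSE),
    list("Ch", 0.41420, 3.80,  0.21, "C", FALSE),
    list("Co", 0.43932, 3.75,  0.70, "C", FALSE),
    list("O",  0.87864, 2.96, -0.80, "O", FALSE),
    list("H",  0,       0,     0.33, "H", TRUE),   # amino H, exchangeable
    list("M",  0,       0,     0,    "H", FALSE))  # methylene H
  co <- c(0, 0, 0)
  oxy <- .carboxylate_oxy(co, c(1, 0, 0), c(0, 1, 0))
  ch <- c(-1.53, 0, 0)
  td <- .tetra_dirs(c(1, 0, 0))          # substituents of Ch (bond Ch->Co)
  n <- ch + 1.49 * td[1, ]
  m1 <- ch + 1.09 * td[2, ]
  m2 <- ch + 1.09 * td[3, ]
  th <- .tetra_dirs(.unitv(ch - n), phi0 = 60)
  h1 <- n + 1.03 * th[1, ]; h2 <- n + 1.03 * th[2, ]; h3 <- n + 1.03 * th[3, ]
  atoms <- .atom_rows(
    c("N", "Ch", "Co", "O", "O", "H", "H", "H", "M", "M"),
    rbind(n, ch, co, oxy$o1, oxy$o2, h1, h2, h3, m1, m2))
  molecule_topology("glycine", sites, atoms,
                    carboxyl = list(carbon = 3, oxygens = c(4, 5)),
                    net_charge = 0)
}

.build_betaine <- function() {
  sites <- .sites_df(
    list("N",  0.71128, 3.25, -0.30, "N", FALSE),
    list("C",  0.41420, 3.80,  0.60, "C", FALSE),
    list("Cm", 0.71145, 3.80,  0.20, "C", FALSE),
    list("Co", 0.43932, 3.75,  0.70, "C", FALSE),
    list("O",  0.87864, 2.96, -0.80, "O", FALSE),
    list("M",  0,       0,     0,    "H", FALSE))
  co <- c(0, 0, 0)
  oxy <- .carboxylate_oxy(co, c(1, 0, 0), c(0, 1, 0))
  cc <- c(-1.53, 0, 0)
  td <- .tetra_dirs(c(1, 0, 0))
  n <- cc + 1.51 * td[1, ]
  mc1 <- cc + 1.09 * td[2, ]
  mc2 <- cc + 1.09 * td[3, ]
  tn <- .tetra_dirs(.unitv(cc - n), phi0 = 60)
  labels <- c("Co", "O", "O", "C", "N", "M", "M")
  coords <- rbind(co, oxy$o1, oxy$o2, cc, n, mc1, mc2)
  for (i in 1:3) {
    cm <- n + 1.50 * tn[i, ]
    labels <- c(labels, "Cm")
    coords <- rbind(coords, cm)
    tm <- .tetra_dirs(.unitv(n - cm), phi0 = 30)
    for (j in 1:3) {
      labels <- c(labels, "M")
      coords <- rbind(coords, cm + 1.09 * tm[j, ])
    }
  }
  atoms <- .atom_rows(labels, coords)
  molecule_topology("betaine", sites, atoms,
                    carboxyl = list(carbon = 1, oxygens = c(2, 3)),
                    net_charge = 0)
}

# Ectoine: 2-methyl-1,4,5,6-tetrahydropyrimidine-4-carboxylate zwitterion.
# Ring modeled as an idealized planar hexagon (bond 1.45 A): C2 (amidine C,
# bearing the methyl), N3h/N1 (protonated nitrogens Nh/N), C4 (bearing the
# carboxylate), C5, C6. The multiset of site multiplicities (4 x C, 1 each of
# Hn1/Hn2) is the unique choice that makes the zwitterion electroneutral with
# the reference charges. The double-bonded carboxylate oxygen is labeled O
# (some parameter listings call the same site Oc); the single-bonded one Oh.
.build_ectoine <- function() {
  sites <- .sites_df(
    list("Oh",  0.71128, 3.00, -0.58, "O", FALSE),
    list("O",   0.87864, 2.96, -0.50, "O", FALSE),
    list("N",   0.83700, 3.70, -0.70, "N", FALSE),
    list("Nh",  0.83700, 3.70, -0.70, "N", FALSE),
    list("Co",  0.43932, 3.75,  0.55, "C", FALSE),
    list("C",   0.31400, 3.80,  0.27, "C", FALSE),
    list("Cm",  0.08370, 4.55,  0.05, "C", FALSE),
    list("Hn1", 0,       0,     0.575, "H", TRUE),
    list("Hn2", 0,       0,     0.225, "H", TRUE),
    list("Mc",  0,       0,     0,    "H", FALSE))
  rring <- 1.45
  ang <- c(C2 = 90, Nh3 = 30, C4 = -30, C5 = -90, C6 = -150, N1 = 150)
  pos <- lapply(ang, function(a) rring * c(cos(a * .deg2rad),
                                           sin(a * .deg2rad), 0))
  radial <- lapply(pos, .unitv)
  zhat <- c(0, 0, 1)
  cm <- pos$C2 + 1.50 * radial$C2
  co <- pos$C4 + 1.53 * radial$C4
  oxy <- .carboxylate_oxy(co, radial$C4, zhat)
  labels <- c("C", "Nh", "C", "C", "C", "N", "Cm", "Co", "O", "Oh",
              "Hn1", "Hn2")
  coords <- rbind(pos$C2, pos$Nh3, pos$C4, pos$C5, pos$C6, pos$N1,
                  cm, co, oxy$o1, oxy$o2,
                  pos$Nh3 + 1.01 * radial$Nh3,     # Hn1 on Nh
                  pos$N1 + 1.01 * radial$N1)       # Hn2 on N
  # ring hydrogens: one on C4 (anti to the carboxylate), two each on C5/C6
  labels <- c(labels, "Mc")
  coords <- rbind(coords, pos$C4 + 1.09 * .unitv(-0.35 * radial$C4 - zhat))
  for (at in c("C5", "C6")) {
    for (s in c(1, -1)) {
      labels <- c(labels, "Mc")
      coords <- rbind(coords,
                      pos[[at]] + 1.09 * .unitv(0.55 * radial[[at]] + s * zhat))
    }
  }
  tm <- .tetra_dirs(.unitv(pos$C2 - cm), phi0 = 0)
  for (j in 1:3) {
    labels <- c(labels, "Mc")
    coords <- rbind(coords, cm + 1.09 * tm[j, ])
  }
  atoms <- .atom_rows(labels, coords)
  molecule_topology("ectoine", sites, atoms,
                    carboxyl = list(carbon = 8, oxygens = c(9, 10)),
                    net_charge = 0)
}

# Trigonelline: N-methylpyridinium-3-carboxylate zwitterion. Planar hexagonal
# ring (bond 1.39 A); C is the ring carbon bearing the carboxylate, the four
# remaining ring carbons are Cr (the unique multiplicity that gives net
# charge zero with the reference charges); carboxylate plane perpendicular
# to the ring.
.build_trigonelline <- function() {
  sites <- .sites_df(
    list("Oh", 0.71128, 3.00, -0.58,  "O", FALSE),
    list("O",  0.87864, 2.96, -0.50,  "O", FALSE),
    list("Co", 0.43932, 3.75,  0.55,  "C", FALSE),
    list("Cr", 0.31400, 3.80, -0.146, "C", FALSE),
    list("C",  0.31400, 3.80, -0.146, "C", FALSE),
    list("Cm", 0.08370, 4.55,  0.36,  "C", FALSE),
    list("N",  0.83700, 4.55,  0.90,  "N", FALSE),
    list("M",  0,       0,     0,     "H", FALSE))
  rring <- 1.39
  ang <- c(N1 = 90, C2 = 30, C3 = -30, C4 = -90, C5 = -150, C6 = 150)
  pos <- lapply(ang, function(a) rring * c(cos(a * .deg2rad),
                                           sin(a * .deg2rad), 0))
  radial <- lapply(pos, .unitv)
  zhat <- c(0, 0, 1)
  cm <- pos$N1 + 1.47 * radial$N1
  co <- pos$C3 + 1.50 * radial$C3
  oxy <- .carboxylate_oxy(co, radial$C3, zhat)
  labels <- c("N", "Cr", "C", "Cr", "Cr", "Cr", "Cm", "Co", "O", "Oh")
  coords <- rbind(pos$N1, pos$C2, pos$C3, pos$C4, pos$C5, pos$C6,
                  cm, co, oxy$o1, oxy$o2)
  for (at in c("C2", "C4", "C5", "C6")) {  # ring hydrogens
    labels <- c(labels, "M")
    coords <- rbind(coords, pos[[at]] + 1.08 * radial[[at]])
  }
  tm <- .tetra_dirs(.unitv(pos$N1 - cm), phi0 = 0)
  for (j in 1:3) {
    labels <- c(labels, "M")
    coords <- rbind(coords, cm + 1.09 * tm[j, ])
  }
  atoms <- .atom_rows(labels, coords)
  molecule_topology("trigonelline", sites, atoms,
                    carboxyl = list(carbon = 8, oxygens = c(9, 10)),
                    net_charge = 0)
}

.build_water <- function() {
  # SPC/E: O-H 1.0 A, H-O-H 109.47 deg
  sites <- .sites_df(
    list("Ow", 0.650, 3.166, -0.8476, "O", FALSE),
    list("Hw", 0,     0,      0.4238, "H", TRUE))
  s <- sin(0.5 * 109.47 * .deg2rad); cz <- cos(0.5 * 109.47 * .deg2rad)
  atoms <- .atom_rows(c("Ow", "Hw", "Hw"),
                      rbind(c(0, 0, 0), c(s, cz, 0), c(-s, cz, 0)))
  molecule_topology("water", sites, atoms, net_charge = 0)
}

.build_chloride <- function() {
  # standard OPLS chloride ion
  sites <- .sites_df(list("Cl", 0.492833, 4.41724, -1, "Cl", FALSE))
  atoms <- .atom_rows("Cl", rbind(c(0, 0, 0)))
  molecule_topology("chloride", sites, atoms, net_charge = -1)
}

.build_proton <- function() {
  # free H+ modeled as a charged LJ-less site
  sites <- .sites_df(list("Hp", 0, 0, 1, "H", TRUE))
  atoms <- .atom_rows("Hp", rbind(c(0, 0, 0)))
  molecule_topology("proton", sites, atoms, net_charge = 1)
}

.builtin_builders <- list(
  glycine = .build_glycine, betaine = .build_betaine,
  ectoine = .build_ectoine, trigonelline = .build_trigonelline,
  water = .build_water, chloride = .build_chloride, proton = .build_proton)

#' Built-in molecule topology
#'
#' @param name One of "glycine", "betaine", "ectoine", "trigonelline",
#'   "water" (SPC/E), "chloride", "proton".
#' @return A [molecule_topology()].
#' @export
builtin_topology <- function(name) {
  if (!name %in% names(.builtin_builders)) {
    .stopf("unknown topology '%s'; available: %s", name,
           paste(names(.builtin_builders), collapse = ", "))
  }
  .builtin_builders[[name]]()
}

# ---------------------------------------------------------------------------
# System specifications (box compositions)

.builtin_compositions <- list(
  glycine = list(glycine = 30, water = 900),
  betaine = list(betaine = 30, water = 900),
  ectoine = list(ectoine = 30, water = 900),
  trigonelline = list(trigonelline = 60, chloride = 60, proton = 60,
                      water = 3000),
  water = list(water = 900))

#' Create a system specification
#'
#' @param components Named list/vector of molecule counts; names must be
#'   built-in topology names, or supply `topologies` for custom molecules.
#' @param rho Atomic number density, atoms per cubic Angstrom (default 0.1,
#'   the ambient aqueous convention).
#' @param temperature Temperature in K (default 298.15, ambient).
#' @param topologies Optional named list of [molecule_topology()] objects
#'   overriding/augmenting the built-ins.
#' @return A list of class `system_spec` with fields `components`
#'   (list of `list(topology, count)`), `rho`, `temperature`.
#' @export
system_spec <- function(components, rho = 0.1, temperature = 298.15,
                        topologies = NULL) {
  stopifnot(rho > 0, temperature > 0, length(components) > 0)
  comp <- lapply(names(components), function(nm) {
    topo <- if (!is.null(topologies) && nm %in% names(topologies)) {
      topologies[[nm]]
    } else builtin_topology(nm)
    list(topology = topo, count = as.integer(components[[nm]]))
  })
  names(comp) <- names(components)
  total_q <- sum(vapply(comp, function(cc) {
    cc$count * molecule_net_charge(cc$topology)
  }, numeric(1)))
  if (abs(total_q) > 1e-6) {
    .stopf("system is not electroneutral: total charge %.8f e", total_q)
  }
  structure(list(components = comp, rho = rho, temperature = temperature),
            class = "system_spec")
}

#' Load a built-in system (box composition and force field)
#'
#' Compositions follow the printed box contents: glycine/betaine/ectoine are
#' 30 solutes + 900 waters; trigonelline is 60 solutes + 60 Cl- + 60 H+ +
#' 3000 waters; "water" is a pure SPC/E box.
#'
#' @param name One of "glycine", "betaine", "ectoine", "trigonelline",
#'   "water".
#' @param scale Optional factor (0 < scale <= 1) shrinking all counts
#'   proportionally (rounded, at least 1 per species), preserving the
#'   water:solute ratio.
#' @param rho,temperature See [system_spec()].
#' @return A `system_spec`.
#' @export
#' @examples
#' sys <- load_builtin_system("glycine", scale = 1 / 6)  # 5 glycine + 150 water
load_builtin_system <- function(name, scale = 1, rho = 0.1,
                                temperature = 298.15) {
  if (!name %in% names(.builtin_compositions)) {
    .stopf("unknown system '%s'; available: %s", name,
           paste(names(.builtin_compositions), collapse = ", "))
  }
  stopifnot(scale > 0, scale <= 1)
  counts <- lapply(.builtin_compositions[[name]], function(n) {
    max(1L, as.integer(round(n * scale)))
  })
  system_spec(counts, rho = rho, temperature = temperature)
}

#' Total system charge
#' @param system A [system_spec()].
#' @return Net charge in e (0 for all built-ins).
#' @export
system_net_charge <- function(system) {
  sum(vapply(system$components, function(cc) {
    cc$count * molecule_net_charge(cc$topology)
  }, numeric(1)))
}

.system_n_atoms <- function(system) {
  sum(vapply(system$components, function(cc) {
    cc$count * nrow(cc$topology$atoms)
  }, numeric(1)))
}

#' Box edge length implied by a system's density
#' @param system A [system_spec()].
#' @return Cubic box edge in Angstrom.
#' @export
system_box_length <- function(system) {
  (.system_n_atoms(system) / system$rho)^(1 / 3)
}

# ---------------------------------------------------------------------------
# TOML-dialect serialization of topologies and systems

.topology_to_config <- function(topo) {
  s <- topo$sites
  cfg <- list(
    net_charge = topo$net_charge,
    site_labels = s$label, epsilon = s$epsilon, sigma = s$sigma,
    charge = s$charge, element = s$element, exchangeable = s$exchangeable,
    atom_labels = topo$atoms$label,
    x = topo$atoms$x, y = topo$atoms$y, z = topo$atoms$z)
  if (!is.null(topo$carboxyl)) {
    cfg$carboxyl_carbon <- topo$carboxyl$carbon
    cfg$carboxyl_oxygens <- topo$carboxyl$oxygens
  }
  cfg
}

.topology_from_config <- function(name, cfg) {
  sites <- data.frame(label = cfg$site_labels, epsilon = cfg$epsilon,
                      sigma = cfg$sigma, charge = cfg$charge,
                      element = cfg$element,
                      exchangeable = as.logical(cfg$exchangeable),
                      stringsAsFactors = FALSE)
  atoms <- data.frame(label = cfg$atom_labels, x = cfg$x, y = cfg$y,
                      z = cfg$z, stringsAsFactors = FALSE)
  carboxyl <- NULL
  if (!is.null(cfg$carboxyl_carbon)) {
    carboxyl <- list(carbon = as.integer(cfg$carboxyl_carbon),
                     oxygens = as.integer(cfg$carboxyl_oxygens))
  }
  molecule_topology(name, sites, atoms, carboxyl = carboxyl,
                    net_charge = cfg$net_charge)
}

#' Write a system specification to a TOML-dialect config file
#'
#' One `[molecule]` table per topology with label/epsilon/sigma/charge/
#' element/exchangeable/coordinate arrays; counts, density and temperature
#' at top level. Roundtrips bit-exactly through [read_system_config()].
#'
#' @param system A [system_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(system, path) {
  cfg <- list(
    molecules = names(system$components),
    counts = vapply(system$components, function(cc) cc$count, integer(1)),
    rho = system$rho,
    temperature = system$temperature)
  for (nm in names(system$components)) {
    cfg[[nm]] <- .topology_to_config(system$components[[nm]]$topology)
  }
  write_toml(cfg, path)
}

#' Read a system specification from a TOML-dialect config file
#' @param path File written by [write_system_config()].
#' @return A `system_spec`.
#' @export
read_system_config <- function(path) {
  cfg <- read_toml(path)
  topos <- lapply(cfg$molecules, function(nm) {
    .topology_from_config(nm, cfg[[nm]])
  })
  names(topos) <- cfg$molecules
  counts <- as.list(as.integer(cfg$counts))
  names(counts) <- cfg$molecules
  system_spec(counts, rho = cfg$rho, temperature = cfg$temperature,
              topologies = topos)
}
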