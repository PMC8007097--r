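# SimulationBox: periodic cubic cell of rigid molecule instances
# (center + unit quaternion per molecule), with the force-field tables the
# C++ kernel consumes.

# Merge the site-type tables of all topologies in a system; labels must be
# unique across topologies (or identical in parameters where shared).
.box_types <- function(system) {
  all <- do.call(rbind, lapply(system$components, function(cc) cc$topology$sites))
  out <- all[!duplicated(all$label), , drop = FALSE]
  for (lab in unique(all$label)) {
    rows <- all[all$label == lab, c("epsilon", "sigma", "charge"), drop = FALSE]
    if (nrow(unique(rows)) > 1) {
      .stopf("site label '%s' used with different parameters by two topologies", lab)
    }
  }
  rownames(out) <- NULL
  out
}

# Pairwise Lennard-Jones / Coulomb tables (geometric-mean combination).
.ff_tables <- function(types) {
  nt <- nrow(types)
  eps <- sqrt(outer(types$epsilon, types$epsilon))
  sig <- sqrt(outer(types$sigma, types$sigma))
  A <- 4 * eps * sig^12
  B <- 4 * eps * sig^6
  QQ <- .kCOUL * outer(types$charge, types$charge)
  rmin2 <- (0.8 * sig)^2          # soft-core clamp radius for warm-up
  rmin2[sig == 0] <- 0
  list(A = A, B = B, QQ = QQ, rmin2 = rmin2, nt = nt, labels = types$label)
}

# Tabulated perturbation -> (U matrix, index matrix) in the kernel layout.
.pert_tables <- function(perturbation, types) {
  nt <- nrow(types)
  idx <- matrix(-1L, nt, nt)
  if (is.null(perturbation)) {
    return(list(U = NULL, idx = idx, dr = 1))
  }
  stopifnot(inherits(perturbation, "perturbation_potential"))
  labs <- types$label
  for (p in seq_len(nrow(perturbation$pairs))) {
    i <- match(perturbation$pairs$a[p], labs)
    j <- match(perturbation$pairs$b[p], labs)
    if (is.na(i) || is.na(j)) {
      .stopf("perturbation pair (%s, %s) references unknown site labels",
             perturbation$pairs$a[p], perturbation$pairs$b[p])
    }
    idx[i, j] <- p - 1L
    idx[j, i] <- p - 1L
  }
  dr <- perturbation$r[2] - perturbation$r[1]
  list(U = perturbation$U, idx = idx, dr = dr)
}

#' Build a simulation box by random insertion
#'
#' Places each molecule at a uniformly random center with a uniformly random
#' orientation, rejecting insertions that put any intermolecular atom pair
#' closer than 1.8 Angstrom (1.2 Angstrom if either atom is a hydrogen),
#' with bounded retries. Uses the current R random number generator state.
#'
#' @param system A [system_spec()].
#' @param max_tries Insertion attempts per molecule before a full restart.
#' @param max_restarts Full restarts before giving up.
#' @return A list of class `simulation_box`.
#' @export
build_box <- function(system, max_tries = 2000, max_restarts = 10) {
  L <- system_box_length(system)
  topo_names <- names(system$components)
  topologies <- lapply(system$components, function(cc) cc$topology)
  counts <- vapply(system$components, function(cc) cc$count, integer(1))
  # expand molecule instances, larger molecules first (easier packing)
  inst_topo <- rep(seq_along(topo_names), counts)
  natoms_of <- vapply(topologies, function(tp) nrow(tp$atoms), integer(1))
  inst_topo <- inst_topo[order(-natoms_of[inst_topo])]
  M <- length(inst_topo)
  templates <- lapply(topologies, function(tp) {
    unname(as.matrix(tp$atoms[, c("x", "y", "z")]))
  })
  is_h <- lapply(topologies, function(tp) {
    tp$sites$element[match(tp$atoms$label, tp$sites$label)] == "H"
  })

  for (restart in seq_len(max_restarts)) {
    centers <- matrix(0, M, 3)
    quats <- matrix(0, M, 4)
    placed <- NULL         # growing matrix of placed atom coordinates
    placed_h <- logical(0)
    ok <- TRUE
    for (m in seq_len(M)) {
      t <- inst_topo[m]
      success <- FALSE
      for (try in seq_len(max_tries)) {
        ctr <- runif(3) * L
        q <- .quat_random()
        xyz <- sweep(.rotate_coords(templates[[t]], q), 2, ctr, "+")
        if (!is.null(placed)) {
          dmin_req <- ifelse(outer(is_h[[t]], placed_h, "|"), 1.2, 1.8)
          dx <- outer(xyz[, 1], placed[, 1], "-"); dx <- dx - L * round(dx / L)
          dy <- outer(xyz[, 2], placed[, 2], "-"); dy <- dy - L * round(dy / L)
          dz <- outer(xyz[, 3], placed[, 3], "-"); dz <- dz - L * round(dz / L)
          if (any(dx * dx + dy * dy + dz * dz < dmin_req^2)) next
        }
        centers[m, ] <- ctr
        quats[m, ] <- q
        placed <- rbind(placed, xyz)
        placed_h <- c(placed_h, is_h[[t]])
        success <- TRUE
        break
      }
      if (!success) { ok <- FALSE; break }
    }
    if (ok) {
      atoms <- do.call(rbind, lapply(seq_len(M), function(m) {
        tp <- topologies[[inst_topo[m]]]
        data.frame(mol = m, topology = tp$name, label = tp$atoms$label,
                   element = tp$sites$element[match(tp$atoms$label,
                                                    tp$sites$label)],
                   stringsAsFactors = FALSE)
      }))
      mol_natoms <- natoms_of[inst_topo]
      mol_first <- cumsum(c(0L, mol_natoms[-M]))
      types <- .box_types(system)
      return(structure(list(
        L = L, centers = centers, quats = quats,
        topo_of_mol = inst_topo, topologies = topologies,
        templates = templates, atoms = atoms,
        mol_first = as.integer(mol_first),
        mol_natoms = as.integer(mol_natoms),
        type_id = match(atoms$label, types$label),
        types = types, system = system), class = "simulation_box"))
    }
  }
  .stopf("failed to place molecules without overlap after %d restarts",
         max_restarts)
}

#' Atom coordinates of a simulation box
#'
#' Derived deterministically from molecule centers, orientations and the
#' rigid templates.
#'
#' @param box A [build_box()] result.
#' @return N x 3 matrix of coordinates (Angstrom).
#' @export
box_coords <- function(box) {
  out <- matrix(0, sum(box$mol_natoms), 3)
  for (m in seq_along(box$topo_of_mol)) {
    t <- box$topo_of_mol[m]
    xyz <- sweep(.rotate_coords(box$templates[[t]], box$quats[m, ]), 2,
                 box$centers[m, ], "+")
    out[box$mol_first[m] + seq_len(box$mol_natoms[m]), ] <- xyz
  }
  out
}

.effective_cutoff <- function(box, cutoff) {
  min(cutoff, box$L / 2 * (1 - 1e-9))
}

#' Total potential energy of a box
#'
#' Sum over intermolecular site pairs of Lennard-Jones (truncated) +
#' shifted-force Coulomb + tabulated perturbation terms under the
#' minimum-image convention; intramolecular pairs are excluded (rigid
#' bodies).
#'
#' @param box A [build_box()] result.
#' @param perturbation Optional [perturbation_potential()].
#' @param cutoff Interaction cutoff in Angstrom (capped at L/2).
#' @param coords Optional explicit N x 3 coordinates (defaults to
#'   [box_coords()]).
#' @return Energy in kJ/mol. Overlapping charged sites (r < 1e-6 A) signal
#'   a singular-configuration error.
#' @export
total_energy <- function(box, perturbation = NULL, cutoff = 9,
                         coords = NULL) {
  ff <- .ff_tables(box$types)
  pt <- .pert_tables(perturbation, box$types)
  if (is.null(coords)) coords <- box_coords(box)
  .energy_total_cpp(coords, as.integer(box$atoms$mol) - 1L,
                    as.integer(box$type_id) - 1L, ff$A, ff$B, ff$QQ,
                    ff$rmin2, box$L, .effective_cutoff(box, cutoff),
                    pt$U, pt$idx, pt$dr, FALSE)
}
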