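# mc_engine: NVT Metropolis Monte Carlo of rigid molecules under the seed
# potential plus an optional tabulated perturbation potential.

#' Monte Carlo run settings
#'
#' One iteration ("sweep") is one attempted move per molecule. Moves are a
#' 50/50 mixture of translations and rotations (single-site molecules only
#' translate); step sizes are auto-tuned toward the target acceptance during
#' equilibration and frozen during production.
#'
#' @param n_equilibration Equilibration sweeps (discarded).
#' @param n_production Production sweeps.
#' @param sample_every Sampling interval in sweeps.
#' @param max_translation Initial maximum translation, Angstrom.
#' @param max_rotation Initial maximum rotation, rad.
#' @param cutoff Interaction cutoff, Angstrom (capped at L/2 at run time).
#' @param target_acceptance Acceptance ratio targeted by step-size tuning.
#' @param warmup_sweeps Soft-core warm-up sweeps used to relax the random
#'   initial packing before equilibration.
#' @param seed Optional integer seed; if given, `run_simulation` seeds the R
#'   RNG so runs are reproducible.
#' @return A list of class `mc_settings`.
#' @export
mc_settings <- function(n_equilibration = 1000, n_production = 10000,
                        sample_every = 20, max_translation = 0.25,
                        max_rotation = 0.25, cutoff = 9,
                        target_acceptance = 0.4, warmup_sweeps = 150,
                        seed = NULL) {
  stopifnot(n_equilibration >= 0, n_production > 0, sample_every > 0,
            max_translation > 0, max_rotation > 0, cutoff > 0,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(n_equilibration = n_equilibration,
                 n_production = n_production, sample_every = sample_every,
                 max_translation = max_translation,
                 max_rotation = max_rotation, cutoff = cutoff,
                 target_acceptance = target_acceptance,
                 warmup_sweeps = warmup_sweeps, seed = seed),
            class = "mc_settings")
}

#' Metropolis acceptance rule
#'
#' Accept with probability min(1, exp(-dU / kT)), consuming one uniform
#' variate from the R RNG for uphill moves.
#'
#' @param dU Energy change, kJ/mol (may be `Inf` for hard overlaps).
#' @param kT Thermal energy, kJ/mol.
#' @return Logical.
#' @export
metropolis_accept <- function(dU, kT) {
  if (!is.finite(dU)) return(dU < 0)
  if (dU <= 0) return(TRUE)
  runif(1) < exp(-dU / kT)
}

.mc_call_args <- function(box, perturbation, cutoff) {
  ff <- .ff_tables(box$types)
  pt <- .pert_tables(perturbation, box$types)
  list(ff = ff, pt = pt, rc = .effective_cutoff(box, cutoff),
       mol0 = as.integer(box$atoms$mol) - 1L,
       type0 = as.integer(box$type_id) - 1L,
       topo0 = as.integer(box$topo_of_mol) - 1L)
}

#' One Metropolis step
#'
#' Attempts a random translation or rotation of one random molecule and
#' accepts with the Metropolis criterion. Intended for inspection and
#' testing; production runs use [run_simulation()], which performs whole
#' sweeps in compiled code with the identical energy model.
#'
#' @param box A [build_box()] result.
#' @param temperature Temperature, K.
#' @param settings An [mc_settings()] (step sizes and cutoff are used).
#' @param perturbation Optional [perturbation_potential()].
#' @return `list(box =, accepted =, dU =)`; a rejected move returns the
#'   input box unchanged.
#' @export
metropolis_step <- function(box, temperature, settings = mc_settings(),
                            perturbation = NULL) {
  stopifnot(temperature > 0)
  kT <- .kB * temperature
  a <- .mc_call_args(box, perturbation, settings$cutoff)
  coords <- box_coords(box)
  M <- length(box$topo_of_mol)
  m <- sample.int(M, 1)
  nat <- box$mol_natoms[m]
  sel <- box$mol_first[m] + seq_len(nat)
  new_box <- box
  if (nat > 1 && runif(1) < 0.5) {
    dq <- .quat_from_axis_angle(rnorm(3), (runif(1) - 0.5) * 2 *
                                  settings$max_rotation)
    q <- .quat_mul(dq, box$quats[m, ])
    new_box$quats[m, ] <- q / sqrt(sum(q^2))
  } else {
    d <- (runif(3) - 0.5) * 2 * settings$max_translation
    ctr <- box$centers[m, ] + d
    shift <- box$L * floor(ctr / box$L)
    new_box$centers[m, ] <- ctr - shift
  }
  new_coords <- coords
  t <- box$topo_of_mol[m]
  new_coords[sel, ] <- sweep(.rotate_coords(box$templates[[t]],
                                            new_box$quats[m, ]), 2,
                             new_box$centers[m, ], "+")
  e_old <- .mol_energy_cpp(coords, a$mol0, a$type0, m - 1L, a$ff$A, a$ff$B,
                           a$ff$QQ, a$ff$rmin2, box$L, a$rc, a$pt$U,
                           a$pt$idx, a$pt$dr, FALSE)
  e_new <- .mol_energy_cpp(new_coords, a$mol0, a$type0, m - 1L, a$ff$A,
                           a$ff$B, a$ff$QQ, a$ff$rmin2, box$L, a$rc, a$pt$U,
                           a$pt$idx, a$pt$dr, FALSE)
  dU <- e_new - e_old
  accepted <- metropolis_accept(dU, kT)
  list(box = if (accepted) new_box else box, accepted = accepted, dU = dU)
}

.run_phase <- function(box, a, kT, nsweeps, sample_every, maxtrans, maxrot,
                       tune, target_acc, softcore) {
  .run_mc_cpp(box$centers, box$quats, box$templates, a$topo0, a$type0,
              a$mol0, box$mol_first, box$mol_natoms, a$ff$A, a$ff$B, a$ff$QQ,
              a$ff$rmin2, box$L, a$rc, kT, a$pt$U, a$pt$idx, a$pt$dr,
              as.integer(nsweeps), as.integer(sample_every), maxtrans,
              maxrot, tune, target_acc, softcore)
}

#' Run an NVT Monte Carlo simulation
#'
#' Builds a box (random insertion), relaxes it with soft-core warm-up
#' sweeps, equilibrates with step-size tuning, then samples configurations
#' during a production phase with frozen step sizes. Deterministic given
#' `settings$seed` (or the current RNG state when `seed` is NULL).
#'
#' @param system A [system_spec()].
#' @param settings An [mc_settings()].
#' @param perturbation Optional [perturbation_potential()] added to the seed
#'   potential.
#' @param box Optional pre-built/equilibrated [build_box()] to continue from
#'   (skips insertion and warm-up).
#' @return A list of class `mc_ensemble`: sampled coordinate frames, the
#'   final box state, acceptance statistics and the running-energy trace.
#' @export
run_simulation <- function(system, settings = mc_settings(),
                           perturbation = NULL, box = NULL) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  fresh <- is.null(box)
  if (fresh) box <- build_box(system)
  a <- .mc_call_args(box, perturbation, settings$cutoff)
  kT <- .kB * system$temperature
  maxtrans <- settings$max_translation
  maxrot <- settings$max_rotation

  if (fresh && settings$warmup_sweeps > 0) {
    res <- .run_phase(box, a, kT, settings$warmup_sweeps, 0, maxtrans,
                      maxrot, TRUE, settings$target_acceptance, TRUE)
    box$centers <- res$centers; box$quats <- res$quats
    maxtrans <- res$maxtrans; maxrot <- res$maxrot
  }
  if (settings$n_equilibration > 0) {
    res <- .run_phase(box, a, kT, settings$n_equilibration, 0, maxtrans,
                      maxrot, TRUE, settings$target_acceptance, FALSE)
    box$centers <- res$centers; box$quats <- res$quats
    maxtrans <- res$maxtrans; maxrot <- res$maxrot
  }
  res <- .run_phase(box, a, kT, settings$n_production,
                    settings$sample_every, maxtrans, maxrot, FALSE,
                    settings$target_acceptance, FALSE)
  box$centers <- res$centers; box$quats <- res$quats

  structure(list(
    frames = res$frames,
    box = box,
    L = box$L,
    volume = box$L^3,
    atoms = box$atoms,
    type_id = box$type_id,
    types = box$types,
    system = system,
    settings = settings,
    perturbation = perturbation,
    acceptance = list(ratio = res$acc_ratio, translation = res$acc_trans,
                      rotation = res$acc_rot, n_attempted = res$n_attempted,
                      n_accepted = res$n_accepted,
                      max_translation = res$maxtrans,
                      max_rotation = res$maxrot),
    energy_trace = res$energy_trace,
    running_energy = res$energy,
    seed = settings$seed), class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf(
    "mc_ensemble: %d frames, %d molecules (%d atoms), L = %.3f A\n",
    length(x$frames), length(x$box$topo_of_mol), nrow(x$atoms), x$L))
  cat(sprintf("  acceptance %.3f (trans %.3f, rot %.3f)\n",
              x$acceptance$ratio, x$acceptance$translation,
              x$acceptance$rotation))
  invisible(x)
}

# Atom indices (1-based) of a site label within an ensemble or box.
.site_indices <- function(ensemble, label) {
  which(ensemble$atoms$label == label)
}

#' Export an ensemble as multi-frame extended XYZ
#'
#' @param ensemble An [run_simulation()] result.
#' @param path Output path.
#' @param frames Frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_ensemble_xyz <- function(ensemble, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(ensemble$frames)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(ensemble$atoms)
  for (f in frames) {
    X <- ensemble$frames[[f]]
    writeLines(sprintf("%d", n), con)
    writeLines(sprintf(
      'Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f" Properties=species:S:1:pos:R:3:label:S:1:mol:I:1:topo:S:1 frame=%d',
      ensemble$L, ensemble$L, ensemble$L, f), con)
    writeLines(sprintf("%-2s %16.10f %16.10f %16.10f %-4s %d %s",
                       ensemble$atoms$element, X[, 1], X[, 2], X[, 3],
                       ensemble$atoms$label, ensemble$atoms$mol,
                       ensemble$atoms$topology), con)
  }
  invisible(path)
}

#' Export one configuration as PDB
#'
#' @param ensemble An [run_simulation()] result (or any object with
#'   `$frames`, `$atoms`, `$L`).
#' @param path Output path.
#' @param frame Frame index (default last).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, frame = length(ensemble$frames)) {
  X <- ensemble$frames[[frame]]
  at <- ensemble$atoms
  lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     ensemble$L, ensemble$L, ensemble$L))
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i %% 100000, substr(at$label[i], 1, 4),
      substr(toupper(at$topology[i]), 1, 3), at$mol[i] %% 10000,
      X[i, 1], X[i, 2], X[i, 3], at$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export a molecule template geometry as extended XYZ (local frame)
#' @param topology A [molecule_topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_xyz <- function(topology, path) {
  at <- topology$atoms
  el <- topology$sites$element[match(at$label, topology$sites$label)]
  writeLines(c(sprintf("%d", nrow(at)),
               sprintf("Properties=species:S:1:pos:R:3:label:S:1 molecule=%s",
                       topology$name),
               sprintf("%-2s %14.8f %14.8f %14.8f %-4s", el, at$x, at$y,
                       at$z, at$label)), path)
  invisible(path)
}
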