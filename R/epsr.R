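# epsr_refinement: iteratively perturb the seed potential so simulated F(Q)
# curves approach target (measured or synthetic) curves, then sample a
# production ensemble under the frozen perturbation.

#' Create a (zero) perturbation potential
#'
#' Tabulated pair potentials U_ep(r) on a uniform r grid starting at 0, one
#' column per unordered site pair. The tabulated values are added to the
#' seed potential by linear interpolation during simulation. Invariants:
#' |U| <= cap and U(rmax) = 0 (updates are tapered to zero at the grid end).
#'
#' @param pairs data.frame with columns a, b (site labels, unordered pairs).
#' @param rmax Grid extent, Angstrom (should equal the interaction cutoff).
#' @param dr Grid spacing, Angstrom.
#' @param U Optional initial matrix (length(r) x nrow(pairs)); default zero.
#' @param cap Amplitude cap, kJ/mol.
#' @return A list of class `perturbation_potential`.
#' @export
perturbation_potential <- function(pairs, rmax = 9, dr = 0.05, U = NULL,
                                   cap = 2.5) {
  r <- seq(0, rmax, by = dr)
  if (is.null(U)) U <- matrix(0, length(r), nrow(pairs))
  stopifnot(nrow(U) == length(r), ncol(U) == nrow(pairs), cap > 0)
  if (any(abs(U) > cap + 1e-12)) .stopf("perturbation exceeds the amplitude cap")
  if (any(abs(U[length(r), ]) > 1e-12)) .stopf("perturbation must vanish at rmax")
  colnames(U) <- paste(pairs$a, pairs$b, sep = "-")
  structure(list(r = r, U = U, pairs = pairs, cap = cap),
            class = "perturbation_potential")
}

# all unordered pairs of the site labels of a system
.system_pairs <- function(system) {
  labs <- sort(unique(unlist(lapply(system$components, function(cc) {
    cc$topology$sites$label
  }))))
  do.call(rbind, lapply(seq_along(labs), function(i) {
    data.frame(a = labs[i], b = labs[i:length(labs)], stringsAsFactors = FALSE)
  }))
}

#' Add a Gaussian well/bump to one pair of a perturbation potential
#'
#' @param pert A [perturbation_potential()].
#' @param pair Character vector c(a, b).
#' @param depth Well depth, kJ/mol (negative = attractive).
#' @param center Center, Angstrom.
#' @param width Gaussian sigma, Angstrom.
#' @return The modified perturbation (clamped to the cap, tapered at rmax).
#' @export
pert_add_gaussian <- function(pert, pair, depth, center, width) {
  stopifnot(width > 0)
  key <- paste(sort(pair), collapse = "-")
  keys <- paste(pmin(pert$pairs$a, pert$pairs$b),
                pmax(pert$pairs$a, pert$pairs$b), sep = "-")
  p <- match(key, keys)
  if (is.na(p)) .stopf("pair %s not tabulated in the perturbation", key)
  add <- depth * exp(-(pert$r - center)^2 / (2 * width^2)) *
    .pert_taper(pert$r)
  pert$U[, p] <- pmin(pert$cap, pmax(-pert$cap, pert$U[, p] + add))
  pert$U[length(pert$r), p] <- 0
  pert
}

# smooth taper to zero over the last 10% of the grid
.pert_taper <- function(r) {
  rmax <- max(r)
  r0 <- 0.9 * rmax
  w <- rep(1, length(r))
  sel <- r > r0
  w[sel] <- 0.5 * (1 + cos(pi * (r[sel] - r0) / (rmax - r0)))
  w[r >= rmax] <- 0
  w
}

#' Total F(Q) curve set of an ensemble under a set of contrasts
#'
#' Computes all partial structure factors once and weighs them into one
#' F(Q) per contrast.
#'
#' @param ensemble An [run_simulation()] result.
#' @param contrasts List of [contrast_definition()]s.
#' @param Q Q grid.
#' @param dr RDF bin width for the partials.
#' @param window Transform window.
#' @return A list of class `total_fq_set`: Q, F (nQ x K matrix), contrasts,
#'   partials.
#' @export
ensemble_total_fq <- function(ensemble, contrasts, Q, dr = 0.05,
                              window = "lorch") {
  partials <- partial_structure_factors(ensemble, Q, dr = dr, window = window)
  FF <- vapply(contrasts, function(cc) weigh_total_fq(partials, cc)$F,
               numeric(length(Q)))
  colnames(FF) <- vapply(contrasts, function(cc) cc$name, "")
  structure(list(Q = Q, F = FF, contrasts = contrasts, partials = partials),
            class = "total_fq_set")
}

#' Weighted squared misfit between model and target F(Q) sets
#'
#' total = sum_k w_k int DeltaF_k(Q)^2 dQ with DeltaF = model - target; the
#' target is resampled onto the model Q grid by linear interpolation
#' (extrapolation is an error).
#'
#' @param model,target `total_fq_set`-like lists (Q, F matrix with contrast
#'   columns).
#' @param weights Per-contrast weights, default 1; named by contrast or in
#'   column order.
#' @return `list(total =, per_contrast =, residuals =)`; residuals is the
#'   nQ x K matrix of DeltaF curves on the model grid.
#' @export
fq_misfit <- function(model, target, weights = NULL) {
  K <- ncol(model$F)
  if (is.null(weights)) weights <- rep(1, K)
  if (!is.null(names(weights))) weights <- weights[colnames(model$F)]
  Q <- model$Q
  if (min(target$Q) > min(Q) + 1e-9 || max(target$Q) < max(Q) - 1e-9) {
    .stopf("target Q range [%.3f, %.3f] does not cover the model grid",
           min(target$Q), max(target$Q))
  }
  dQ <- Q[2] - Q[1]
  res <- matrix(NA_real_, length(Q), K, dimnames = list(NULL, colnames(model$F)))
  for (k in colnames(model$F)) {
    if (!k %in% colnames(target$F)) .stopf("target lacks contrast '%s'", k)
    tk <- approx(target$Q, target$F[, k], xout = Q)$y
    res[, k] <- model$F[, k] - tk
  }
  per <- colSums(res^2) * dQ
  list(total = sum(weights * per), per_contrast = per, residuals = res,
       weights = weights)
}

#' Propose an updated perturbation potential from F(Q) residuals
#'
#' The residual of each contrast is back-transformed to r-space (the inverse
#' of the forward g -> S transform), the r-space discrepancy is attributed
#' to site pairs by least squares on the contrast weight matrix
#' W[k, (a,b)] = (2 - delta) c_a c_b b_a b_b (Moore-Penrose pseudo-inverse;
#' under-determined pairs are flagged), and the perturbation is incremented
#' by gain * kT * attributed discrepancy, clamped to the cap and tapered
#' smoothly to zero at the grid end.
#'
#' @param residuals nQ x K matrix of model - target curves (from
#'   [fq_misfit()]).
#' @param Q The model Q grid.
#' @param contrasts List of [contrast_definition()]s (column order of
#'   `residuals`).
#' @param rho Total atomic number density, atoms/A^3.
#' @param current The current [perturbation_potential()].
#' @param gain Dimensionless update gain.
#' @param kT Thermal energy, kJ/mol.
#' @param cap Amplitude cap, kJ/mol (default `current$cap`).
#' @return An updated `perturbation_potential`; attribute "determination"
#'   holds the per-pair determination score (diag of the row-space
#'   projector) and "underdetermined" the pairs scoring < 0.5.
#' @export
update_perturbation <- function(residuals, Q, contrasts, rho, current, gain,
                                kT, cap = current$cap) {
  W <- .contrast_weight_matrix(contrasts, current$pairs)
  # r-space residual per contrast on the perturbation grid. The inverse
  # transform weights the integrand by Q^2, so white measurement noise at
  # high Q would dominate the update; a Lorch window in Q (the mirror image
  # of the forward-transform window in r) suppresses it while leaving the
  # smooth low-Q structural signal intact.
  wQ <- .lorch(Q, max(Q))
  dfr <- vapply(seq_len(ncol(residuals)), function(k) {
    .fq_backtransform(Q, residuals[, k] * wQ, rho, current$r)
  }, numeric(length(current$r)))
  Winv <- MASS::ginv(W)                    # P x K pseudo-inverse
  dg <- dfr %*% t(Winv)                    # nr x P attributed discrepancy
  sv <- svd(W)
  keep <- sv$d > max(sv$d) * 1e-10
  proj <- sv$v[, keep, drop = FALSE] %*% t(sv$v[, keep, drop = FALSE])
  determination <- diag(proj)
  names(determination) <- colnames(W)
  # light smoothing of the increment along r damps bin-level noise chasing
  dg <- apply(dg, 2, function(col) {
    n <- length(col)
    c(col[1], (col[-c(1, 2)] + col[-c(1, n)] + col[-c(n - 1, n)]) / 3,
      col[n])
  })
  increment <- gain * kT * dg * .pert_taper(current$r)
  out <- current
  out$U <- pmax(pmin(current$U + increment, cap), -cap)
  out$U[length(current$r), ] <- 0
  out$cap <- cap
  attr(out, "determination") <- determination
  attr(out, "underdetermined") <- names(determination)[determination < 0.5]
  out
}

#' Refinement loop settings
#'
#' @param gain Initial update gain (halved whenever a proposed update does
#'   not reduce the misfit).
#' @param cap Perturbation amplitude cap, kJ/mol.
#' @param tol Relative-improvement tolerance; the loop stops after
#'   `stall_iters` consecutive iterations below it.
#' @param stall_iters See `tol`.
#' @param max_iter Maximum refinement iterations.
#' @param initial_equilibration Equilibration sweeps for the very first
#'   model simulation (subsequent iterations continue from the evolving box
#'   with `mc_iter$n_equilibration` sweeps); a long initial relaxation keeps
#'   slowly-converging structure out of the initial-misfit baseline.
#' @param Q Q grid for the model/target comparison.
#' @param dr RDF bin width for the model partials.
#' @param window Transform window.
#' @param weights Per-contrast misfit weights (default 1).
#' @param mc_iter [mc_settings()] for the per-iteration model simulations.
#' @param mc_production [mc_settings()] for the final production run.
#' @return A list of class `refine_settings`.
#' @export
refine_settings <- function(gain = 0.3, cap = 2.5, tol = 1e-3,
                            stall_iters = 3, max_iter = 12,
                            initial_equilibration = 2000,
                            Q = seq(0.3, 12, by = 0.05), dr = 0.05,
                            pert_dr = 0.1, window = "lorch", weights = NULL,
                            mc_iter = mc_settings(n_equilibration = 200,
                                                  n_production = 2000,
                                                  sample_every = 10),
                            mc_production = mc_settings(
                              n_equilibration = 200, n_production = 6000,
                              sample_every = 10)) {
  structure(list(gain = gain, cap = cap, tol = tol,
                 stall_iters = stall_iters, max_iter = max_iter,
                 initial_equilibration = initial_equilibration, Q = Q,
                 dr = dr, pert_dr = pert_dr, window = window,
                 weights = weights, mc_iter = mc_iter,
                 mc_production = mc_production),
            class = "refine_settings")
}

#' Empirical-potential refinement against target F(Q) curves
#'
#' EPSR-inspired loop: simulate under the current (seed + perturbation)
#' potential, compare the model F(Q) set with the targets, back-transform
#' the residuals into a proposed perturbation update, and keep the update
#' only if the misfit decreases (otherwise halve the gain; the gain
#' recovers by 25% per acceptance). Because the misfit of a finite Monte
#' Carlo run is itself noisy, each iteration re-evaluates the incumbent
#' potential alongside the proposal (paired comparison) instead of trusting
#' a remembered minimum. The trace's `total` column is the best evaluated
#' misfit so far (non-increasing by construction); `eval_current` /
#' `eval_proposal` are the iteration's paired evaluations. Stops when the
#' relative improvement stays below `tol` for `stall_iters` consecutive
#' iterations (rejections count only once the gain has collapsed) or at
#' `max_iter`; then runs production sampling with the frozen perturbation.
#'
#' @param targets A `total_fq_set` (e.g. from [generate_target_fq()] or
#'   [read_fq_set()]).
#' @param system The [system_spec()] to simulate (same composition/density
#'   as the sample behind the targets).
#' @param contrasts List of [contrast_definition()]s matching the target
#'   columns.
#' @param settings A [refine_settings()].
#' @param seed Optional RNG seed for the whole refinement.
#' @return A list of class `epsr_refinement`: `ensemble` (production run
#'   under the refined potential), `perturbation`, `trace` (one row per
#'   iteration: misfits, acceptance, gain), `initial_misfit`,
#'   `final_misfit`.
#' @export
refine_potential <- function(targets, system, contrasts,
                             settings = refine_settings(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kT <- .kB * system$temperature
  rc <- settings$mc_iter$cutoff
  weights <- settings$weights
  if (is.null(weights) && !is.null(targets$sigma)) {
    # inverse-variance weighting when the targets state their uncertainty
    weights <- 1 / targets$sigma^2
    names(weights) <- colnames(targets$F)
  }
  pert <- perturbation_potential(.system_pairs(system),
                                 rmax = rc, dr = settings$pert_dr,
                                 cap = settings$cap)
  evaluate <- function(p, box, mc = settings$mc_iter) {
    sim <- run_simulation(system, mc, perturbation = p, box = box)
    modelF <- ensemble_total_fq(sim, contrasts, settings$Q,
                                dr = settings$dr, window = settings$window)
    list(sim = sim, mis = fq_misfit(modelF, targets, weights))
  }
  mc0 <- settings$mc_iter
  mc0$n_equilibration <- max(mc0$n_equilibration,
                             settings$initial_equilibration)
  cur <- evaluate(pert, box = NULL, mc = mc0)
  rho <- nrow(cur$sim$atoms) / cur$sim$volume
  gain <- settings$gain
  initial_misfit <- cur$mis$total
  best_total <- cur$mis$total
  trace <- cbind(data.frame(iteration = 0, total = best_total,
                            eval_current = cur$mis$total,
                            eval_proposal = NA_real_, accepted = TRUE,
                            gain = gain),
                 t(cur$mis$per_contrast))
  state_box <- cur$sim$box
  ens <- cur$sim
  stall <- 0
  for (it in seq_len(settings$max_iter)) {
    # paired evaluation: the incumbent is re-evaluated alongside every
    # proposal so that a remembered lucky draw cannot freeze the loop
    cur <- evaluate(pert, state_box)
    prop <- update_perturbation(cur$mis$residuals, settings$Q, contrasts,
                                rho, pert, gain, kT)
    cand <- evaluate(prop, cur$sim$box)
    accepted <- cand$mis$total < cur$mis$total
    if (accepted) {
      pert <- prop
      state_box <- cand$sim$box
      ens <- cand$sim
      last <- cand$mis
      gain <- min(settings$gain, gain * 1.25)
    } else {
      state_box <- cur$sim$box
      ens <- cur$sim
      last <- cur$mis
      # a rejection under evaluation noise is ambiguous: halve the gain and
      # retry; it only counts toward the stall once the gain has collapsed
      gain <- gain / 2
    }
    prev_best <- best_total
    best_total <- min(best_total, last$total)
    rel <- (prev_best - best_total) / prev_best
    if (accepted) {
      stall <- if (rel < settings$tol) stall + 1 else 0
    } else if (gain < settings$gain / 64) stall <- stall + 1
    trace <- rbind(trace,
                   cbind(data.frame(iteration = it, total = best_total,
                                    eval_current = cur$mis$total,
                                    eval_proposal = cand$mis$total,
                                    accepted = accepted, gain = gain),
                         t(last$per_contrast)))
    if (stall >= settings$stall_iters) break
  }
  production <- run_simulation(system, settings$mc_production,
                               perturbation = pert, box = state_box)
  structure(list(ensemble = production, perturbation = pert,
                 trace = trace, initial_misfit = initial_misfit,
                 final_misfit = best_total, contrasts = contrasts,
                 settings = settings), class = "epsr_refinement")
}
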