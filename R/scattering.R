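# neutron_scattering: from sampled ensembles to site-site radial
# distribution functions, Faber-Ziman partial structure factors and
# isotope-contrast-weighted total interference cross sections F(Q).

#' Wrap fixed coordinates as a single- or multi-frame ensemble
#'
#' Convenience for toy fixtures and tests: builds the minimal object that
#' [compute_rdf()] and the hydration analysis accept.
#'
#' @param coords One N x 3 matrix or a list of them (frames).
#' @param labels Site label per atom.
#' @param mol Molecule id per atom (intramolecular pairs are excluded from
#'   RDFs).
#' @param L Box edge, Angstrom.
#' @param elements Optional element per atom (defaults to labels).
#' @param topology Optional [molecule_topology()] carried along for the
#'   carboxyl-frame analysis.
#' @param mol_topology Optional topology name per molecule (in order of the
#'   unique molecule ids); defaults to `topology$name` (or "fixture") for
#'   all molecules.
#' @return A list of class `mc_ensemble`.
#' @export
static_ensemble <- function(coords, labels, mol, L, elements = labels,
                            topology = NULL, mol_topology = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  if (is.null(mol_topology)) {
    mol_topology <- rep(if (is.null(topology)) "fixture" else topology$name,
                        length(unique(mol)))
  }
  atoms <- data.frame(mol = mol,
                      topology = mol_topology[match(mol, unique(mol))],
                      label = labels, element = elements,
                      stringsAsFactors = FALSE)
  structure(list(frames = coords, L = L, volume = L^3, atoms = atoms,
                 system = NULL, topology = topology),
            class = "mc_ensemble")
}

#' Site-site radial distribution function
#'
#' Histogram of minimum-image distances between two site species over all
#' frames, normalized by ideal-gas shell counts (exact shell volumes) and
#' the partner number density. Intramolecular pairs are excluded.
#'
#' @param ensemble An [run_simulation()] result (or [static_ensemble()]).
#' @param pair Character vector of two site labels, e.g. `c("O", "Hw")`.
#' @param dr Bin width, Angstrom.
#' @param rmax Histogram range; must not exceed L/2 (minimum-image
#'   validity). Default L/2.
#' @return A list of class `pair_rdf` with fields r (bin centers), g, pair,
#'   dr, rho_partner (partner atoms per A^3), n_origin, volume, nframes.
#' @export
compute_rdf <- function(ensemble, pair, dr = 0.03, rmax = NULL) {
  stopifnot(length(pair) == 2, length(ensemble$frames) >= 1)
  L <- ensemble$L
  if (is.null(rmax)) rmax <- L / 2
  if (rmax > L / 2 + 1e-9) {
    .stopf("rmax = %.3f exceeds L/2 = %.3f (minimum image not valid)",
           rmax, L / 2)
  }
  ia <- .site_indices(ensemble, pair[1])
  ib <- .site_indices(ensemble, pair[2])
  if (length(ia) == 0 || length(ib) == 0) {
    .stopf("no atoms with label '%s' in the ensemble",
           pair[c(length(ia) == 0, length(ib) == 0)][1])
  }
  nbins <- floor(rmax / dr)
  counts <- .rdf_hist_cpp(ensemble$frames, ia - 1L, ib - 1L,
                          as.integer(ensemble$atoms$mol) - 1L, L, dr,
                          as.integer(nbins))
  edges <- dr * (0:nbins)
  shell <- 4 / 3 * pi * diff(edges^3)
  rho_b <- length(ib) / ensemble$volume
  nf <- length(ensemble$frames)
  g <- counts / (nf * length(ia) * shell * rho_b)
  structure(list(r = edges[-1] - dr / 2, g = g, pair = pair, dr = dr,
                 rho_partner = rho_b, n_origin = length(ia),
                 volume = ensemble$volume, nframes = nf),
            class = "pair_rdf")
}

.lorch <- function(r, rmax) {
  x <- pi * r / rmax
  w <- ifelse(r == 0, 1, sin(x) / x)
  w[r >= rmax] <- 0
  w
}

.sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

#' Fourier transform of a pair RDF to a partial structure factor
#'
#' Faber-Ziman convention:
#' S(Q) - 1 = 4 pi rho int r^2 (g(r) - 1) sinc(Qr) w(r) dr,
#' with rho the TOTAL atomic number density of the sample and w(r) an
#' optional modification window; quadrature on the rdf grid. The Q = 0
#' point uses the analytic sinc limit.
#'
#' @param rdf A [compute_rdf()] result, or `list(r =, g =)`.
#' @param rho Total atomic number density, atoms/A^3.
#' @param Q Q grid, 1/Angstrom.
#' @param window "lorch" (default) or "none".
#' @return `list(Q =, S =, window =)`.
#' @export
rdf_to_partial_sq <- function(rdf, rho, Q, window = c("lorch", "none")) {
  window <- match.arg(window)
  r <- rdf$r
  dr <- if (length(r) > 1) r[2] - r[1] else rdf$dr
  w <- if (window == "lorch") .lorch(r, max(r) + dr / 2) else rep(1, length(r))
  integrand <- r^2 * (rdf$g - 1) * w          # midpoint rule on the rdf bins
  # S at each Q: 1 + 4 pi rho sum_r integrand * sinc(Qr) * dr
  sincmat <- outer(r, Q, function(rr, qq) .sinc(qq * rr))
  S <- 1 + 4 * pi * rho * as.vector(crossprod(sincmat, integrand)) * dr
  list(Q = Q, S = S, window = window)
}

#' Inverse transform: partial structure factor back to g(r)
#'
#' g(r) - 1 = 1 / (2 pi^2 rho) int Q^2 (S(Q) - 1) sinc(Qr) dQ, the exact
#' inverse of [rdf_to_partial_sq()] in the infinite-range limit.
#'
#' @param sq `list(Q =, S =)`.
#' @param rho Total atomic number density, atoms/A^3.
#' @param r Output r grid, Angstrom.
#' @return `list(r =, g =)`.
#' @export
partial_sq_to_rdf <- function(sq, rho, r) {
  Q <- sq$Q
  dQ <- Q[2] - Q[1]
  integrand <- Q^2 * (sq$S - 1)
  sincmat <- outer(Q, r, function(qq, rr) .sinc(qq * rr))
  g <- 1 + as.vector(crossprod(sincmat, integrand)) * dQ / (2 * pi^2 * rho)
  list(r = r, g = g)
}

# Back-transform of a residual Delta F(Q) to its r-space counterpart (no +1
# baseline); used by the refinement update.
.fq_backtransform <- function(Q, dF, rho, r) {
  dQ <- Q[2] - Q[1]
  integrand <- Q^2 * dF
  sincmat <- outer(Q, r, function(qq, rr) .sinc(qq * rr))
  as.vector(crossprod(sincmat, integrand)) * dQ / (2 * pi^2 * rho)
}

# ---------------------------------------------------------------------------
# Isotopic contrasts

#' Define an isotopic labeling scheme (one sample contrast)
#'
#' @param name Contrast name, e.g. "Gly-D2".
#' @param solute_d Named numeric vector: fraction of deuterium on each
#'   non-exchangeable (or nominally labeled) solute hydrogen site, e.g.
#'   `c(M = 1)` for a deuterated methylene group. Unlisted sites are 0
#'   (natural).
#' @param water_d Deuterium fraction of the solvent (0 = H2O, 1 = D2O);
#'   exchangeable hydrogens follow this fraction.
#' @return A list of class `contrast_scheme`.
#' @export
contrast_scheme <- function(name, solute_d = numeric(0), water_d = 0) {
  stopifnot(water_d >= 0, water_d <= 1)
  if (length(solute_d)) stopifnot(!is.null(names(solute_d)),
                                  all(solute_d >= 0 & solute_d <= 1))
  structure(list(name = name, solute_d = solute_d, water_d = water_d),
            class = "contrast_scheme")
}

#' Effective coherent scattering length of a site under a labeling scheme
#'
#' Non-exchangeable hydrogens take the isotopic identity given by the solute
#' labeling; exchangeable hydrogens take the population-weighted mean of
#' b(H) and b(D) at the solvent H/D ratio; non-hydrogen sites return their
#' natural-abundance scattering length. Mixtures are treated at the
#' coherent-average level.
#'
#' @param site One-row data.frame (or list) with `label`, `element`,
#'   `exchangeable`.
#' @param labeling A [contrast_scheme()].
#' @param water_deuteration Solvent D fraction; defaults to
#'   `labeling$water_d`.
#' @param exchange_model "solvent" (exchangeable H follow the solvent) or
#'   "none" (exchange switched off; all H follow the solute labeling).
#' @return Scattering length in fm.
#' @export
effective_b <- function(site, labeling,
                        water_deuteration = labeling$water_d,
                        exchange_model = c("solvent", "none")) {
  exchange_model <- match.arg(exchange_model)
  btab <- scattering_lengths()
  el <- site$element
  if (el != "H") {
    if (!el %in% names(btab)) .stopf("no scattering length for element '%s'", el)
    return(unname(btab[el]))
  }
  f <- if (isTRUE(site$exchangeable) && exchange_model == "solvent") {
    water_deuteration
  } else if (!is.null(labeling$solute_d) &&
             site$label %in% names(labeling$solute_d)) {
    unname(labeling$solute_d[[site$label]])
  } else 0
  (1 - f) * btab[["H"]] + f * btab[["D"]]
}

#' Contrast definition for a system under a labeling scheme
#'
#' Per-site atomic fractions c_alpha (over all sites in the sample, summing
#' to 1) and effective scattering lengths b_alpha.
#'
#' @param system A [system_spec()].
#' @param labeling A [contrast_scheme()].
#' @param exchange_model See [effective_b()].
#' @return A list of class `contrast_definition` with `name` and a `sites`
#'   data.frame (label, element, count, c, b).
#' @export
contrast_definition <- function(system, labeling,
                                exchange_model = "solvent") {
  counts <- list()
  sites <- list()
  for (cc in system$components) {
    tp <- cc$topology
    tab <- table(tp$atoms$label)
    for (lab in names(tab)) {
      counts[[lab]] <- (if (is.null(counts[[lab]])) 0 else counts[[lab]]) +
        cc$count * as.integer(tab[[lab]])
      sites[[lab]] <- tp$sites[tp$sites$label == lab, ]
    }
  }
  labs <- names(counts)
  n <- unlist(counts)
  b <- vapply(labs, function(lab) {
    effective_b(sites[[lab]], labeling, exchange_model = exchange_model)
  }, numeric(1))
  df <- data.frame(label = labs, count = n,
                   element = vapply(labs, function(l) sites[[l]]$element, ""),
                   c = n / sum(n), b = b, stringsAsFactors = FALSE,
                   row.names = NULL)
  structure(list(name = labeling$name, sites = df,
                 water_d = labeling$water_d, labeling = labeling),
            class = "contrast_definition")
}

# ---------------------------------------------------------------------------
# Partial structure factor sets and total F(Q)

#' All partial structure factors of an ensemble
#'
#' Computes the RDF of every unordered site-type pair present and Fourier
#' transforms each to S_alphabeta(Q).
#'
#' @param ensemble An [run_simulation()] result.
#' @param Q Q grid, 1/Angstrom.
#' @param dr RDF bin width.
#' @param window Transform window, see [rdf_to_partial_sq()].
#' @param rmax RDF range (default L/2).
#' @return A list of class `partial_sq_set`: Q, S (nQ x npairs matrix),
#'   pairs (data.frame a, b), rho (total atomic density), rdfs (the
#'   underlying `pair_rdf` objects), window.
#' @export
partial_structure_factors <- function(ensemble, Q, dr = 0.05,
                                      window = "lorch", rmax = NULL) {
  labs <- sort(unique(ensemble$atoms$label))
  pairs <- do.call(rbind, lapply(seq_along(labs), function(i) {
    data.frame(a = labs[i], b = labs[i:length(labs)],
               stringsAsFactors = FALSE)
  }))
  rho <- nrow(ensemble$atoms) / ensemble$volume
  rdfs <- vector("list", nrow(pairs))
  S <- matrix(NA_real_, length(Q), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    rdfs[[p]] <- compute_rdf(ensemble, c(pairs$a[p], pairs$b[p]), dr = dr,
                             rmax = rmax)
    S[, p] <- rdf_to_partial_sq(rdfs[[p]], rho, Q, window = window)$S
  }
  colnames(S) <- paste(pairs$a, pairs$b, sep = "-")
  structure(list(Q = Q, S = S, pairs = pairs, rho = rho, rdfs = rdfs,
                 window = window), class = "partial_sq_set")
}

#' Contrast-weighted total interference cross section F(Q)
#'
#' F(Q) = sum over unordered site pairs (alpha <= beta) of
#' (2 - delta_alphabeta) c_alpha c_beta b_alpha b_beta
#' (S_alphabeta(Q) - 1), the Faber-Ziman interference form. Units fm^2 per
#' atom (b in fm).
#'
#' @param partials A [partial_structure_factors()] result.
#' @param contrast A [contrast_definition()].
#' @return A list of class `total_fq`: Q, F, contrast name.
#' @export
weigh_total_fq <- function(partials, contrast) {
  cs <- contrast$sites
  FQ <- numeric(length(partials$Q))
  have <- paste(pmin(partials$pairs$a, partials$pairs$b),
                pmax(partials$pairs$a, partials$pairs$b))
  active <- cs$label[cs$c > 0]
  missing <- character(0)
  for (i in seq_along(active)) {
    for (j in i:length(active)) {
      key <- paste(min(active[i], active[j]), max(active[i], active[j]))
      if (!key %in% have) missing <- c(missing, gsub(" ", "-", key))
    }
  }
  if (length(missing)) {
    .stopf("partial structure factors missing for pairs: %s",
           paste(missing, collapse = ", "))
  }
  for (p in seq_len(nrow(partials$pairs))) {
    a <- partials$pairs$a[p]; b <- partials$pairs$b[p]
    ia <- match(a, cs$label); ib <- match(b, cs$label)
    if (is.na(ia) || is.na(ib)) next
    w <- (2 - (a == b)) * cs$c[ia] * cs$c[ib] * cs$b[ia] * cs$b[ib]
    FQ <- FQ + w * (partials$S[, p] - 1)
  }
  structure(list(Q = partials$Q, F = FQ, contrast = contrast$name),
            class = "total_fq")
}

#' Fixed-geometry intramolecular Debye term
#'
#' Total F(Q) as computed by [weigh_total_fq()] contains only the distinct
#' intermolecular part; this helper returns the optional rigid-geometry
#' intramolecular contribution of one molecular species,
#' (n_mol / N_atoms) sum_{i != j in molecule} b_i b_j sinc(Q r_ij),
#' to be added when comparing against data that retain the molecular form
#' factor.
#'
#' @param topology A [molecule_topology()].
#' @param contrast A [contrast_definition()] providing per-site b values.
#' @param Q Q grid, 1/Angstrom.
#' @param n_fraction Molecules of this species per atom of sample
#'   (count_molecules / total_atoms).
#' @return Numeric vector, fm^2 per atom.
#' @export
intramolecular_fq <- function(topology, contrast, Q, n_fraction) {
  at <- topology$atoms
  b <- contrast$sites$b[match(at$label, contrast$sites$label)]
  if (anyNA(b)) .stopf("contrast lacks b values for some sites of %s",
                       topology$name)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  out <- numeric(length(Q))
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      out <- out + 2 * b[i] * b[j] * .sinc(Q * rij)
    }
  }
  out * n_fraction
}

# Contrast weight matrix W[k, p] = (2 - delta) c_a c_b b_a^(k) b_b^(k); the
# linear map from (S_p - 1) curves to F_k curves, reused by the refinement.
.contrast_weight_matrix <- function(contrasts, pairs) {
  W <- matrix(0, length(contrasts), nrow(pairs))
  for (k in seq_along(contrasts)) {
    cs <- contrasts[[k]]$sites
    for (p in seq_len(nrow(pairs))) {
      ia <- match(pairs$a[p], cs$label); ib <- match(pairs$b[p], cs$label)
      if (is.na(ia) || is.na(ib)) next
      W[k, p] <- (2 - (pairs$a[p] == pairs$b[p])) * cs$c[ia] * cs$c[ib] *
        cs$b[ia] * cs$b[ib]
    }
  }
  rownames(W) <- vapply(contrasts, function(cc) cc$name, "")
  colnames(W) <- paste(pairs$a, pairs$b, sep = "-")
  W
}

#' Coordination number from a pair RDF
#'
#' n(r_cut) = 4 pi rho_partner int_0^{r_cut} g(r) r^2 dr, by quadrature on
#' the rdf bins (the last partial bin is pro-rated).
#'
#' @param rdf A [compute_rdf()] result.
#' @param r_cut Integration limit, Angstrom (within the rdf grid).
#' @return Mean number of partner atoms within r_cut of an origin site.
#' @export
coordination_number <- function(rdf, r_cut) {
  dr <- rdf$dr
  edges_lo <- rdf$r - dr / 2
  edges_hi <- rdf$r + dr / 2
  if (r_cut > max(edges_hi) + 1e-9) .stopf("r_cut beyond the rdf grid")
  hi <- pmin(edges_hi, r_cut)
  frac_vol <- pmax(hi^3 - edges_lo^3, 0) * 4 / 3 * pi
  sum(rdf$g * frac_vol) * rdf$rho_partner
}
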