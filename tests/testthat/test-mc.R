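# Monte Carlo engine: energy model, Metropolis rule, determinism,
# bookkeeping and low-density limits.

# Independent direct-sum energy oracle: Lennard-Jones (truncated) +
# shifted-force Coulomb over all intermolecular site pairs, written from the
# model definition without reusing package internals.
.oracle_energy <- function(coords, eps, sig, q, mol, L, rc) {
  ke <- 1389.35457644382
  n <- nrow(coords)
  e <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (mol[i] == mol[j]) next
      d <- coords[i, ] - coords[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r >= rc) next
      epsij <- sqrt(eps[i] * eps[j]); sigij <- sqrt(sig[i] * sig[j])
      if (epsij > 0) e <- e + 4 * epsij * ((sigij / r)^12 - (sigij / r)^6)
      qq <- q[i] * q[j]
      if (qq != 0) e <- e + ke * qq * (1 / r + r / rc^2 - 2 / rc)
    }
  }
  e
}

.spce <- function() list(eps = c(0.650, 0, 0), sig = c(3.166, 0, 0),
                         q = c(-0.8476, 0.4238, 0.4238))

test_that("two-water dimer energy matches a direct pairwise-sum oracle", {
  box <- toy_fixture("dimer")
  coords <- box_coords(box)
  w <- .spce()
  expected <- .oracle_energy(coords, rep(w$eps, 2), rep(w$sig, 2),
                             rep(w$q, 2), mol = rep(1:2, each = 3), L = 20,
                             rc = 9)
  expect_equal(total_energy(box, cutoff = 9), expected, tolerance = 1e-12)
})

test_that("zero-parameter sites contribute zero energy", {
  sites <- data.frame(label = "Z", epsilon = 0, sigma = 0, charge = 0,
                      element = "H", exchangeable = FALSE)
  atoms <- data.frame(label = "Z", x = 0, y = 0, z = 0)
  ztop <- molecule_topology("ghost", sites, atoms)
  sys <- system_spec(c(ghost = 2), rho = 2 / 8000, topologies = list(ghost = ztop))
  set.seed(1)
  box <- build_box(sys)
  expect_identical(total_energy(box, cutoff = 9), 0)
})

test_that("energy is invariant under uniform translation of all molecules", {
  box <- toy_fixture("dimer")
  e0 <- total_energy(box, cutoff = 9)
  box2 <- box
  box2$centers <- sweep(box$centers, 2, c(3.123, -7.5, 12.0), "+")
  expect_equal(total_energy(box2, cutoff = 9), e0, tolerance = 1e-10)
})

test_that("overlapping charged sites signal a singular configuration", {
  box <- toy_fixture("dimer")
  box$centers[2, ] <- box$centers[1, ]   # identical orientations: exact overlap
  expect_error(total_energy(box, cutoff = 9), "singular")
})

test_that("Metropolis rule: downhill always accepted, overlap rejected, e^-1 at dU = kT", {
  expect_true(metropolis_accept(-5, 1))
  expect_true(metropolis_accept(0, 1))
  expect_false(metropolis_accept(Inf, 1))
  set.seed(42)
  kT <- 2.4789
  acc <- mean(replicate(20000, metropolis_accept(kT, kT)))
  # binomial 4-sigma band around exp(-1)
  p <- exp(-1)
  expect_lt(abs(acc - p), 4 * sqrt(p * (1 - p) / 20000))
})

test_that("a two-state chain driven by the acceptance rule reaches Boltzmann weights", {
  set.seed(7)
  kT <- 1
  dE <- 0.8
  state <- 0L
  nsteps <- 30000
  visits <- 0L
  for (i in seq_len(nsteps)) {
    dU <- if (state == 0L) dE else -dE
    if (metropolis_accept(dU, kT)) state <- 1L - state
    visits <- visits + state
  }
  p1 <- exp(-dE / kT) / (1 + exp(-dE / kT))
  expect_lt(abs(visits / nsteps - p1), 4 * sqrt(p1 * (1 - p1) / nsteps))
})

test_that("metropolis_step either applies or exactly restores the configuration", {
  set.seed(3)
  sys <- load_builtin_system("water", scale = 1 / 45)  # 20 waters
  box <- build_box(sys)
  st <- mc_settings(cutoff = 8)
  for (i in 1:30) {
    out <- metropolis_step(box, 298.15, st)
    if (!out$accepted) {
      expect_identical(out$box$centers, box$centers)
      expect_identical(out$box$quats, box$quats)
    } else {
      expect_false(identical(out$box$centers, box$centers) &&
                     identical(out$box$quats, box$quats))
    }
    box <- out$box
    # quaternions stay unit-norm
    expect_equal(max(abs(rowSums(box$quats^2) - 1)), 0, tolerance = 1e-9)
  }
})

test_that("runs are deterministic given a seed", {
  sys <- load_builtin_system("water", scale = 1 / 30)
  st <- mc_settings(n_equilibration = 50, n_production = 100,
                    sample_every = 20, cutoff = 8, warmup_sweeps = 20,
                    seed = 99)
  e1 <- run_simulation(sys, st)
  e2 <- run_simulation(sys, st)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$running_energy, e2$running_energy)
})

test_that("incremental energy bookkeeping matches a full recomputation", {
  sys <- load_builtin_system("water", scale = 1 / 30)
  st <- mc_settings(n_equilibration = 100, n_production = 300,
                    sample_every = 50, cutoff = 8, seed = 13)
  ens <- run_simulation(sys, st)
  recomputed <- total_energy(ens$box, cutoff = 8)
  expect_equal(ens$running_energy, recomputed,
               tolerance = 1e-6 * max(1, abs(recomputed)))
})

test_that("a dilute LJ gas reproduces the low-density RDF limit exp(-U/kT)", {
  sites <- data.frame(label = "X", epsilon = 0.65, sigma = 3.166,
                      charge = 0, element = "O", exchangeable = FALSE)
  atoms <- data.frame(label = "X", x = 0, y = 0, z = 0)
  xtop <- molecule_topology("ljatom", sites, atoms)
  sys <- system_spec(c(ljatom = 50), rho = 50 / 42^3, temperature = 298.15,
                     topologies = list(ljatom = xtop))
  ens <- run_simulation(sys, mc_settings(n_equilibration = 500,
                                         n_production = 6000,
                                         sample_every = 10, cutoff = 9,
                                         max_translation = 3, seed = 21))
  rdf <- compute_rdf(ens, c("X", "X"), dr = 0.1, rmax = 12)
  kT <- 0.0083144621 * 298.15
  u <- 4 * 0.65 * ((3.166 / rdf$r)^12 - (3.166 / rdf$r)^6)
  gref <- exp(-u / kT)
  sel <- rdf$r > 2.8 & rdf$r < 10
  expect_lt(sqrt(mean((rdf$g[sel] - gref[sel])^2)), 0.12)
})

test_that("glycine O-site RDFs are invariant under relabeling the two equivalent oxygens", {
  tp <- builtin_topology("glycine")
  sites2 <- tp$sites
  # split the O type into two identically parameterized labels
  o2 <- sites2[sites2$label == "O", ]; o2$label <- "O2"
  sites2 <- rbind(sites2, o2)
  atoms2 <- tp$atoms
  atoms2$label[tp$carboxyl$oxygens[2]] <- "O2"
  tp2 <- molecule_topology("glycine", sites2, atoms2,
                           carboxyl = tp$carboxyl, net_charge = 0)
  sys <- system_spec(c(glycine = 3, water = 90),
                     topologies = list(glycine = tp2))
  ens <- run_simulation(sys, mc_settings(n_equilibration = 400,
                                         n_production = 2500,
                                         sample_every = 10, seed = 31))
  rA <- compute_rdf(ens, c("O", "Hw"), dr = 0.05)
  rB <- compute_rdf(ens, c("O2", "Hw"), dr = 0.05)
  pA <- first_peak_position(rA)$position
  pB <- first_peak_position(rB)$position
  expect_lt(abs(pA - pB), 0.1)
  sel <- rA$r < 6
  expect_lt(mean(abs(rA$g[sel] - rB$g[sel])), 0.15)
})

test_that("ensemble export roundtrips through extended XYZ", {
  sys <- load_builtin_system("water", scale = 1 / 60)
  ens <- run_simulation(sys, mc_settings(n_equilibration = 20,
                                         n_production = 40,
                                         sample_every = 20, cutoff = 7,
                                         warmup_sweeps = 10, seed = 2))
  path <- tempfile(fileext = ".xyz")
  write_ensemble_xyz(ens, path)
  back <- read_ensemble_xyz(path)
  expect_equal(length(back$frames), length(ens$frames))
  expect_equal(back$L, ens$L, tolerance = 1e-7)
  expect_equal(back$frames[[1]], unname(ens$frames[[1]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$atoms$label, ens$atoms$label)
})
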