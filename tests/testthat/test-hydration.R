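# Hydration-shell fingerprints: angle distributions, local frames, spatial
# density maps, isolevels, peak and shell-cutoff estimators.

test_that("hand-placed waters give all angle mass at 180 and 90 degrees", {
  e180 <- toy_fixture("angle180")
  a180 <- angle_distribution(e180, "O", "Ow", shell_cutoff = 3.0, bins = 90)
  expect_equal(a180$n_pairs, 1)
  expect_equal(a180$theta[which.max(a180$density)], 179)
  expect_equal(sum(a180$density) * 2, 1, tolerance = 1e-9)  # unit integral

  e90 <- toy_fixture("angle90")
  a90 <- angle_distribution(e90, "O", "Ow", shell_cutoff = 3.0, bins = 90)
  # exactly 90 deg falls on a bin edge; the mass must sit in an adjacent bin
  expect_lte(abs(a90$theta[which.max(a90$density)] - 90), 1)
})

test_that("an empty shell is reported with advice", {
  e <- toy_fixture("angle180")
  expect_error(angle_distribution(e, "O", "Ow", shell_cutoff = 1.0),
               "empty shell")
})

test_that("the carboxyl local frame bisects, is orthonormal and equivariant", {
  tp <- builtin_topology("glycine")
  X <- as.matrix(tp$atoms[, c("x", "y", "z")])
  fr <- carboxyl_local_frame(X, tp)
  co <- X[tp$carboxyl$carbon, ]
  u1 <- (X[tp$carboxyl$oxygens[1], ] - co)
  u2 <- (X[tp$carboxyl$oxygens[2], ] - co)
  u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
  bis <- (u1 + u2); bis <- bis / sqrt(sum(bis^2))
  expect_equal(unname(fr$axes["z", ]), unname(bis), tolerance = 1e-9)
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  expect_gt(sum(fr$axes["x", ] * u1), 0)    # x leans toward the first oxygen
  # equivariance under a rigid rotation + translation
  set.seed(4)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] - q[1] * q[2]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
              3, 3, byrow = TRUE)
  X2 <- X %*% t(R) + matrix(c(3, -1, 7), nrow(X), 3, byrow = TRUE)
  fr2 <- carboxyl_local_frame(X2, tp)
  expect_equal(fr2$axes, fr$axes %*% t(R), tolerance = 1e-9)
  expect_equal(fr2$origin, as.vector(R %*% co + c(3, -1, 7)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("collinear O-C-O geometry raises a degenerate-frame error", {
  sites <- data.frame(label = c("Co", "O"), epsilon = c(0.4, 0.9),
                      sigma = c(3.7, 3), charge = c(0.5, -0.25),
                      element = c("C", "O"), exchangeable = FALSE)
  atoms <- data.frame(label = c("Co", "O", "O"),
                      x = c(0, 1.25, -1.25), y = 0, z = 0)
  tp <- molecule_topology("lin", sites, atoms,
                          carboxyl = list(carbon = 1, oxygens = c(2, 3)))
  X <- as.matrix(tp$atoms[, c("x", "y", "z")])
  expect_error(carboxyl_local_frame(X, tp), "degenerate")
})

test_that("a water at a fixed local-frame position maps to one voxel", {
  e <- toy_fixture("angle180")
  e$frames <- rep(e$frames, 4)    # identical frames
  sdf <- compute_sdf(e, r_cut = 4.5, resolution = 0.5)
  expect_equal(sum(sdf$density > 0), 1)
  expect_equal(sdf$mean_shell_count, 1)
  expect_equal(sum(sdf$density) * 0.5^3, 1, tolerance = 1e-9)
})

test_that("SDF map integral inside the shell equals the coordination number", {
  ens <- mini_glycine()
  sdf <- compute_sdf(ens, r_cut = 4.26)
  integral <- sum(sdf$density[sdf$in_shell]) * sdf$resolution^3
  expect_equal(integral, sdf$mean_shell_count, tolerance = 1e-9)
  rdfc <- compute_rdf(ens, c("Co", "Ow"), dr = 0.03)
  cn <- coordination_number(rdfc, 4.26)
  expect_lt(abs(integral - cn) / cn, 0.02)
})

test_that("SDF guards: coarse resolution and small grids are rejected", {
  ens <- toy_fixture("angle180")
  expect_error(compute_sdf(ens, r_cut = 4, resolution = 1.5), "resolution")
  expect_error(compute_sdf(ens, r_cut = 4, grid_edge = 6), "grid_edge")
})

# a synthetic map object for isolevel tests
.fake_map <- function(density, resolution = 0.5, r_cut = 3) {
  n <- dim(density)[1]
  ax <- (seq_len(n) - 0.5) * resolution - n * resolution / 2
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  structure(list(density = density, axis = ax,
                 in_shell = rr <= r_cut + sqrt(3) / 2 * resolution,
                 r_cut = r_cut, resolution = resolution),
            class = "spatial_density_map")
}

test_that("isodensity level on a uniform map covers the requested voxel fraction", {
  n <- 16
  d <- array(1, dim = c(n, n, n))
  map <- .fake_map(d)
  iso <- isodensity_level(map, 0.35)
  nshell <- sum(map$in_shell)
  expect_lte(abs(sum(iso$mask) - 0.35 * nshell), 1)
  expect_equal(iso$level, 1)
})

test_that("a one-voxel point mass is its own isolevel mask", {
  n <- 12
  d <- array(0, dim = c(n, n, n))
  d[6, 6, 6] <- 7
  map <- .fake_map(d)
  for (f in c(0.1, 0.5, 0.9)) {
    iso <- isodensity_level(map, f)
    expect_equal(sum(iso$mask), 1)
    expect_equal(iso$level, 7)
    expect_equal(iso$enclosed_fraction, 1)
  }
})

test_that("Gaussian-cloud isolevels match a brute-force sort and stay within 2%", {
  set.seed(9)
  n <- 24; res <- 0.25
  ax <- (seq_len(n) - 0.5) * res - n * res / 2
  gg <- expand.grid(x = ax, y = ax, z = ax)
  dens <- array(exp(-(gg$x^2 + (gg$y - 0.4)^2 + gg$z^2) / (2 * 0.6^2)) +
                  0.3 * exp(-((gg$x - 0.8)^2 + gg$y^2 + gg$z^2) / (2 * 0.4^2)),
                dim = c(n, n, n))
  map <- .fake_map(dens, resolution = res, r_cut = 2.5)
  for (f in c(0.2, 0.35, 0.6)) {
    iso <- isodensity_level(map, f)
    # brute-force oracle: cumulative fraction of the sorted in-shell voxels
    v <- sort(map$density[map$in_shell], decreasing = TRUE)
    k <- which(cumsum(v) / sum(v) >= f)[1]
    expect_equal(iso$level, v[k])
    expect_lt(abs(iso$enclosed_fraction - f), 0.02)
    expect_equal(sum(iso$mask), k)
  }
  # monotonicity: higher fraction -> lower (or equal) threshold
  expect_gte(isodensity_level(map, 0.2)$level,
             isodensity_level(map, 0.35)$level)
})

test_that("first_shell_cutoff recovers the analytic minimum of a Gaussian mixture", {
  dr <- 0.02
  r <- seq(dr / 2, 8, by = dr)
  f <- function(x) 1 + 1.5 * exp(-(x - 3)^2 / (2 * 0.25^2)) -
    0.4 * exp(-(x - 4.3)^2 / (2 * 0.25^2))
  rdf <- list(r = r, g = f(r), dr = dr)
  truth <- optimize(f, c(3.5, 5))$minimum
  est <- first_shell_cutoff(rdf, smooth_bins = 5)
  expect_lt(abs(est$position - truth), dr)
})

test_that("a hard-shell toy puts the cutoff immediately after the shell", {
  dr <- 0.1
  r <- seq(dr / 2, 6, by = dr)
  g <- ifelse(r < 2, 0, ifelse(r < 2.2, 3, ifelse(r < 2.6, 0.7, 1)))
  est <- first_shell_cutoff(list(r = r, g = g, dr = dr), smooth_bins = 1)
  expect_gt(est$position, 2.2)
  expect_lt(est$position, 2.7)
  expect_error(first_shell_cutoff(list(r = r, g = rep(1, length(r)),
                                       dr = dr)), "no resolved first peak")
})

test_that("peak_position: triangle apex, off-grid Gaussian, boundary flag", {
  x <- seq(0, 10, by = 0.5)
  tri <- pmax(0, 3 - abs(x - 4))
  pk <- peak_position(x, tri)
  expect_equal(pk$position, 4)
  expect_false(pk$at_boundary)
  center <- 5.17
  gy <- exp(-(x - center)^2 / (2 * 1.3^2))
  expect_lt(abs(peak_position(x, gy)$position - center), 0.25 * 0.5)
  flat <- rep(1, length(x))
  expect_true(peak_position(x, flat)$at_boundary)
})

test_that("angle distributions at the two equivalent glycine oxygens agree", {
  ens <- reduced_run("glycine", seed = 11)   # the long shared run
  tp <- builtin_topology("glycine")
  # split the carboxyl designation: analyze each oxygen separately
  one <- tp; one$carboxyl$oxygens <- tp$carboxyl$oxygens[1]
  two <- tp; two$carboxyl$oxygens <- tp$carboxyl$oxygens[2]
  a1 <- angle_distribution(ens, "O", "Ow", shell_cutoff = 3.3, bins = 36,
                           topology = one)
  a2 <- angle_distribution(ens, "O", "Ow", shell_cutoff = 3.3, bins = 36,
                           topology = two)
  expect_lt(abs(distribution_mode(a1) - distribution_mode(a2)), 15)
  # mean angles agree closely; bin-level shape decorrelates far more slowly
  # than this run, so the comparison is on the coarse statistics
  mean1 <- sum(a1$theta * a1$density) * (a1$theta[2] - a1$theta[1])
  mean2 <- sum(a2$theta * a2$density) * (a2$theta[2] - a2$theta[1])
  expect_lt(abs(mean1 - mean2), 5)
})

test_that("O and Oh of ectoine are analyzed independently, never pooled", {
  tp <- builtin_topology("ectoine")
  oxys <- tp$atoms$label[tp$carboxyl$oxygens]
  expect_setequal(oxys, c("O", "Oh"))
  # one water near the Oh site only
  X <- as.matrix(tp$atoms[, c("x", "y", "z")])
  oh <- X[tp$carboxyl$oxygens[which(oxys == "Oh")], ]
  co <- X[tp$carboxyl$carbon, ]
  u <- (oh - co); u <- u / sqrt(sum(u^2))
  wat <- rbind(oh + 2.6 * u, oh + 2.6 * u + c(0.8, 0.6, 0),
               oh + 2.6 * u + c(-0.8, 0.6, 0))
  coords <- sweep(rbind(X, wat), 2, c(25, 25, 25), "+")
  ens <- static_ensemble(coords, c(tp$atoms$label, "Ow", "Hw", "Hw"),
                         mol = c(rep(1, nrow(X)), rep(2, 3)), L = 50,
                         topology = tp, mol_topology = c("ectoine", "water"))
  aOh <- angle_distribution(ens, "Oh", "Ow", shell_cutoff = 3.0, bins = 36)
  expect_equal(aOh$n_pairs, 1)
  expect_error(angle_distribution(ens, "O", "Ow", shell_cutoff = 3.0,
                                  bins = 36), "empty shell")
  expect_error(angle_distribution(ens, "Ow", "Ow"), "not part of")
})

test_that("SDF export formats are written and consistent", {
  e <- toy_fixture("angle180")
  sdf <- compute_sdf(e, r_cut = 4.5, resolution = 0.6)
  p1 <- tempfile(fileext = ".cube"); p2 <- tempfile(fileext = ".csv")
  write_sdf(sdf, p1, "cube")
  iso <- isodensity_level(sdf, 0.5)
  write_sdf(sdf, p2, "csv", mask = iso$mask)
  expect_true(file.exists(p1))
  df <- read.csv(p2)
  expect_equal(nrow(df), length(sdf$density))
  expect_equal(sum(df$in_mask), sum(iso$mask))
  expect_equal(sum(df$density) * sdf$resolution^3, 1, tolerance = 1e-6)
})
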