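# RDFs, structure-factor transforms, isotopic contrasts and F(Q) weighting.

test_that("two atoms at a fixed separation give a single nonzero RDF bin", {
  coords <- rbind(c(5, 5, 5), c(10, 5, 5))
  ens <- static_ensemble(coords, labels = c("A", "B"), mol = 1:2, L = 30)
  rdf <- compute_rdf(ens, c("A", "B"), dr = 0.1)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1)
  expect_lt(abs(rdf$r[nz] - 5), 0.05 + 1e-12)
  # normalization: one count against the ideal-gas shell expectation
  shell <- 4 / 3 * pi * ((rdf$r[nz] + 0.05)^3 - (rdf$r[nz] - 0.05)^3)
  expect_equal(rdf$g[nz], 1 / (shell * (1 / 30^3)), tolerance = 1e-9)
})

test_that("independently placed ideal-gas points give g close to 1 everywhere", {
  set.seed(5)
  frames <- lapply(1:40, function(i) matrix(runif(3 * 400, 0, 25), ncol = 3))
  ens <- static_ensemble(frames, labels = rep("A", 400), mol = 1:400, L = 25)
  rdf <- compute_rdf(ens, c("A", "A"), dr = 0.25)
  sel <- rdf$r > 1
  expect_lt(max(abs(rdf$g[sel] - 1)), 0.12)
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.01)
  # liquid-normalization invariant: tail mean within 1 +/- 0.05
  tail_sel <- rdf$r >= 0.9 * max(rdf$r)
  expect_lt(abs(mean(rdf$g[tail_sel]) - 1), 0.05)
})

test_that("RDF of a cubic lattice matches brute-force neighbor counting", {
  sp <- 2.0; n1 <- 4; L <- sp * n1
  gr <- as.matrix(expand.grid(x = 0:(n1 - 1), y = 0:(n1 - 1),
                              z = 0:(n1 - 1))) * sp
  ens <- static_ensemble(gr, labels = rep("A", nrow(gr)),
                         mol = seq_len(nrow(gr)), L = L)
  dr <- 0.05
  rdf <- compute_rdf(ens, c("A", "A"), dr = dr)
  # brute force: all ordered minimum-image pairs, independent histogram
  nb <- floor((L / 2) / dr)
  counts <- numeric(nb)
  for (i in seq_len(nrow(gr))) {
    for (j in seq_len(nrow(gr))) {
      if (i == j) next
      d <- gr[i, ] - gr[j, ]; d <- d - L * round(d / L)
      b <- floor(sqrt(sum(d^2)) / dr) + 1
      if (b <= nb) counts[b] <- counts[b] + 1
    }
  }
  shell <- 4 / 3 * pi * diff((dr * (0:nb))^3)
  gref <- counts / (nrow(gr) * shell * (nrow(gr) / L^3))
  expect_equal(rdf$g, gref, tolerance = 1e-9)
})

test_that("g identically 1 transforms to S identically 1, and F to 0", {
  r <- seq(0.025, 10, by = 0.05)
  rdf <- list(r = r, g = rep(1, length(r)), dr = 0.05)
  Q <- seq(0.2, 15, by = 0.1)
  sq <- rdf_to_partial_sq(rdf, rho = 0.1, Q = Q)
  expect_equal(sq$S, rep(1, length(Q)))
  partials <- list(Q = Q, S = matrix(1, length(Q), 1),
                   pairs = data.frame(a = "A", b = "A"), rho = 0.1)
  contrast <- list(name = "x", sites = data.frame(label = "A", c = 1, b = 5))
  fq <- weigh_total_fq(partials, contrast)
  expect_equal(fq$F, rep(0, length(Q)))
})

test_that("a narrow Gaussian bump transforms to the closed-form damped sinusoid", {
  dr <- 0.01
  r <- seq(dr / 2, 20, by = dr)
  a <- 0.2; r0 <- 3; w <- 0.1; rho <- 0.05
  rdf <- list(r = r, g = 1 + a * exp(-(r - r0)^2 / (2 * w^2)), dr = dr)
  Q <- seq(0.5, 10, by = 0.1)
  sq <- rdf_to_partial_sq(rdf, rho = rho, Q = Q, window = "none")
  # int_0^inf r^2 e^{-(r-r0)^2/2w^2} sinc(Qr) dr
  #   = sqrt(2 pi) w / Q * exp(-Q^2 w^2 / 2) * (r0 sin(Q r0) + Q w^2 cos(Q r0))
  Sref <- 1 + 4 * pi * rho * a * sqrt(2 * pi) * w / Q *
    exp(-Q^2 * w^2 / 2) * (r0 * sin(Q * r0) + Q * w^2 * cos(Q * r0))
  expect_lt(sqrt(mean((sq$S - Sref)^2)) / sqrt(mean((Sref - 1)^2)), 0.01)
})

test_that("forward then inverse transform recovers g within 1% RMS on the interior", {
  dr <- 0.02
  r <- seq(dr / 2, 12, by = dr)
  g <- 1 + 0.8 * exp(-(r - 2.8)^2 / (2 * 0.3^2)) -
    0.3 * exp(-(r - 4.5)^2 / (2 * 0.5^2))
  rho <- 0.08
  Q <- seq(0.02, 40, by = 0.02)
  sq <- rdf_to_partial_sq(list(r = r, g = g, dr = dr), rho, Q,
                          window = "none")
  back <- partial_sq_to_rdf(sq, rho, r)
  sel <- r > 1 & r < 10
  expect_lt(sqrt(mean((back$g[sel] - g[sel])^2)), 0.01)
})

test_that("effective scattering lengths follow labeling, exchange and mixtures", {
  bH <- -3.739; bD <- 6.671
  suite <- glycine_contrast_suite()
  names(suite) <- vapply(suite, function(x) x$name, "")
  bs <- function(ct, lab) ct$sites$b[ct$sites$label == lab]
  # methylene M under the D2 scheme carries b_D
  expect_equal(bs(suite[["Gly-D2"]], "M"), bD)
  expect_equal(bs(suite[["Gly-D2"]], "H"), bH)   # amino H in H2O
  # every hydrogen under the 50/50 solute mixture in 50/50 water
  for (lab in c("M", "H", "Hw")) {
    expect_equal(bs(suite[["Gly-50/50"]], lab), (bH + bD) / 2)
  }
  # carboxyl O under any scheme keeps natural b(O)
  for (ct in suite) expect_equal(bs(ct, "O"), 5.803)
  # fully deuterated glycine: all hydrogen sites carry b_D
  for (lab in c("M", "H", "Hw")) {
    expect_equal(bs(suite[["Gly-D5"]], lab), bD)
  }
  # H5 and D5 differ only in hydrogen-site b values
  h5 <- suite[["Gly-H5"]]$sites; d5 <- suite[["Gly-D5"]]$sites
  expect_identical(h5$c, d5$c)
  same <- h5$element != "H"
  expect_identical(h5$b[same], d5$b[same])
  expect_true(all(h5$b[!same] != d5$b[!same]))
})

test_that("atomic fractions sum to one and follow the box composition", {
  sys <- load_builtin_system("glycine")
  ct <- contrast_definition(sys, contrast_scheme("nat", water_d = 0))
  expect_equal(sum(ct$sites$c), 1, tolerance = 1e-9)
  # 30 glycine x 2 carboxyl O out of 3000 atoms
  expect_equal(ct$sites$c[ct$sites$label == "O"], 60 / 3000)
  expect_equal(ct$sites$c[ct$sites$label == "Hw"], 1800 / 3000)
})

test_that("single-species F equals c^2 b^2 (S - 1) and scales quartically in b", {
  Q <- seq(0.5, 8, by = 0.1)
  S <- 1 + 0.3 * sin(Q) / Q
  partials <- list(Q = Q, S = matrix(S, ncol = 1),
                   pairs = data.frame(a = "A", b = "A"), rho = 0.1)
  c1 <- list(name = "x", sites = data.frame(label = "A", c = 1, b = 3))
  f1 <- weigh_total_fq(partials, c1)
  expect_equal(f1$F, 9 * (S - 1))
  c2 <- c1; c2$sites$b <- 6
  f2 <- weigh_total_fq(partials, c2)
  expect_equal(f2$F, 4 * f1$F)
})

test_that("F(Q) is symmetric under swapping pair labels", {
  Q <- seq(0.5, 8, by = 0.5)
  set.seed(2)
  S <- matrix(1 + rnorm(3 * length(Q), 0, 0.1), ncol = 3)
  pairsAB <- data.frame(a = c("A", "A", "B"), b = c("A", "B", "B"))
  pairsBA <- data.frame(a = c("A", "B", "B"), b = c("A", "A", "B"))
  ct <- list(name = "x", sites = data.frame(label = c("A", "B"),
                                            c = c(0.4, 0.6), b = c(2, -3)))
  f1 <- weigh_total_fq(list(Q = Q, S = S, pairs = pairsAB), ct)
  f2 <- weigh_total_fq(list(Q = Q, S = S, pairs = pairsBA), ct)
  expect_equal(f1$F, f2$F)
})

test_that("missing pair curves are reported by name", {
  Q <- seq(0.5, 8, by = 0.5)
  partials <- list(Q = Q, S = matrix(1, length(Q), 1),
                   pairs = data.frame(a = "A", b = "A"))
  ct <- list(name = "x", sites = data.frame(label = c("A", "B"),
                                            c = c(0.5, 0.5), b = c(2, 3)))
  expect_error(weigh_total_fq(partials, ct), "A-B")
})

test_that("RDF-transform F(Q) agrees with the direct Debye sum on the 10-atom fixture", {
  ens <- toy_fixture("debye10")
  X <- ens$frames[[1]]
  b <- ifelse(ens$atoms$label == "X", 6.0, -3.9)
  N <- nrow(X)
  Q <- seq(0.5, 10, by = 0.05)
  # independent oracle: distinct-pair Debye double sum, per atom
  Fref <- sapply(Q, function(q) {
    s <- 0
    for (i in 1:N) for (j in 1:N) {
      if (i == j) next
      rij <- sqrt(sum((X[i, ] - X[j, ])^2))
      s <- s + b[i] * b[j] * sin(q * rij) / (q * rij)
    }
    s / N
  })
  partials <- partial_structure_factors(ens, Q, dr = 0.002, window = "none")
  cx <- sum(ens$atoms$label == "X") / N
  ct <- list(name = "fix", sites = data.frame(label = c("X", "Y"),
                                              c = c(cx, 1 - cx),
                                              b = c(6.0, -3.9)))
  fq <- weigh_total_fq(partials, ct)
  rel_rms <- sqrt(mean((fq$F - Fref)^2)) / sqrt(mean(Fref^2))
  expect_lt(rel_rms, 0.02)
})

test_that("effective-b F equals the average over independent per-molecule labelings", {
  # exact quadratic identity for the intermolecular (distinct) Debye sum:
  # with each molecule labeled independently, E[b_i b_j] = E[b]^2 for i != j
  ens <- toy_fixture("debye10")
  X <- ens$frames[[1]]
  N <- nrow(X)
  lab_site <- ens$atoms$label == "X"       # the labelable species
  bH <- -3.739; bD <- 6.671; f <- 0.5
  b_other <- 5.803
  Q <- c(0.7, 2.3, 5.1)
  debye <- function(b, q) {
    s <- 0
    for (i in 1:N) for (j in 1:N) {
      if (i == j) next
      rij <- sqrt(sum((X[i, ] - X[j, ])^2))
      s <- s + b[i] * b[j] * sin(q * rij) / (q * rij)
    }
    s / N
  }
  nx <- sum(lab_site)
  combos <- expand.grid(rep(list(c(bH, bD)), nx))
  wts <- apply(combos, 1, function(bb) prod(ifelse(bb == bD, f, 1 - f)))
  for (q in Q) {
    Favg <- 0
    for (k in seq_len(nrow(combos))) {
      b <- ifelse(lab_site, NA, b_other)
      b[lab_site] <- as.numeric(combos[k, ])
      Favg <- Favg + wts[k] * debye(b, q)
    }
    beff <- ifelse(lab_site, (1 - f) * bH + f * bD, b_other)
    expect_equal(Favg, debye(beff, q), tolerance = 1e-10)
  }
})

test_that("coordination numbers: analytic, delta-shell, and direct-count checks", {
  # uniform g: n(r) = 4/3 pi rho r^3
  r <- seq(0.05, 8, by = 0.1)
  rdf <- list(r = r, g = rep(1, length(r)), dr = 0.1, rho_partner = 0.033)
  expect_equal(coordination_number(rdf, 5), 4 / 3 * pi * 0.033 * 125,
               tolerance = 1e-6)
  # two atoms: exactly one neighbor beyond the occupied bin
  coords <- rbind(c(5, 5, 5), c(8, 5, 5))
  ens2 <- static_ensemble(coords, c("A", "B"), 1:2, L = 30)
  r2 <- compute_rdf(ens2, c("A", "B"), dr = 0.1)
  expect_equal(coordination_number(r2, 4), 1, tolerance = 1e-9)
  # ensemble value vs direct per-frame neighbor counting
  ens <- mini_glycine()
  rdfc <- compute_rdf(ens, c("Co", "Ow"), dr = 0.03)
  cn <- coordination_number(rdfc, 4.2)
  ico <- which(ens$atoms$label == "Co")
  iow <- which(ens$atoms$label == "Ow")
  L <- ens$L
  direct <- mean(vapply(ens$frames, function(X) {
    tot <- 0
    for (i in ico) {
      d <- sweep(X[iow, , drop = FALSE], 2, X[i, ])
      d <- d - L * round(d / L)
      tot <- tot + sum(rowSums(d^2) <= 4.2^2)
    }
    tot / length(ico)
  }, numeric(1)))
  expect_lt(abs(cn - direct) / direct, 0.01)
})

test_that("rmax beyond L/2 is rejected", {
  ens <- toy_fixture("debye10")
  expect_error(compute_rdf(ens, c("X", "Y"), dr = 0.1, rmax = 60), "L/2")
})

test_that("the intramolecular Debye term matches a hand sum for SPC/E water", {
  tp <- builtin_topology("water")
  sys <- load_builtin_system("water")
  ct <- contrast_definition(sys, contrast_scheme("pure-D2O", water_d = 1))
  Q <- c(0.5, 2, 7)
  got <- intramolecular_fq(tp, ct, Q, n_fraction = 1 / 3)
  bO <- 5.803; bD <- 6.671
  xyz <- as.matrix(tp$atoms[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  roh <- d[1, 2]; rhh <- d[2, 3]
  hand <- (2 * bO * bD * sin(Q * roh) / (Q * roh) * 2 +
             2 * bD * bD * sin(Q * rhh) / (Q * rhh)) / 3
  expect_equal(got, hand, tolerance = 1e-9)
})
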