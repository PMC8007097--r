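# hydration_analysis: shell fingerprints of the carboxyl/carboxylate group:
# angle distributions at the oxygen sites, carboxyl-frame spatial density
# maps with fractional-occupancy isolevels, first-shell cutoffs and peak
# positions.

.min_image_vec <- function(d, L) d - L * round(d / L)

# Molecules of the ensemble belonging to the (unique) carboxyl-bearing
# topology, unless one is named explicitly.
.carboxyl_topology <- function(ensemble, topology = NULL) {
  if (!is.null(topology)) return(topology)
  if (!is.null(ensemble$topology)) return(ensemble$topology)
  cands <- Filter(function(tp) !is.null(tp$carboxyl), ensemble$box$topologies)
  if (length(cands) == 0) .stopf("no carboxyl-bearing topology in ensemble")
  if (length(cands) > 1) {
    .stopf("several carboxyl-bearing topologies present; pass `topology`")
  }
  cands[[1]]
}

.molecule_rows <- function(ensemble, topo_name) {
  mols <- unique(ensemble$atoms$mol[ensemble$atoms$topology == topo_name])
  lapply(mols, function(m) which(ensemble$atoms$mol == m))
}

#' Local orthonormal frame of a carboxyl group
#'
#' z along the bisector of the two C-O bonds, x the in-plane component of
#' the first C-O bond perpendicular to z, y = z cross x (right-handed).
#' For a single-oxygen designation z is the C-O direction and x an
#' arbitrary-but-deterministic perpendicular (the result is flagged).
#'
#' @param coords Coordinates of one molecule instance (atoms in topology
#'   order), n x 3.
#' @param topology The molecule's [molecule_topology()] (must carry a
#'   carboxyl designation).
#' @return `list(origin =, axes =, degenerate =)`; `axes` is a 3 x 3 matrix
#'   with rows x, y, z.
#' @export
carboxyl_local_frame <- function(coords, topology) {
  cb <- topology$carboxyl
  if (is.null(cb)) .stopf("topology '%s' has no carboxyl designation",
                          topology$name)
  co <- coords[cb$carbon, ]
  if (length(cb$oxygens) >= 2) {
    u1 <- .unitv(coords[cb$oxygens[1], ] - co)
    u2 <- .unitv(coords[cb$oxygens[2], ] - co)
    bis <- u1 + u2
    if (sqrt(sum(bis^2)) < 1e-6) {
      .stopf("degenerate carboxyl frame: collinear O-C-O geometry")
    }
    z <- .unitv(bis)
    xr <- u1 - sum(u1 * z) * z
    if (sqrt(sum(xr^2)) < 1e-6) {
      .stopf("degenerate carboxyl frame: O along the bisector")
    }
    x <- .unitv(xr)
    degenerate <- FALSE
  } else {
    z <- .unitv(coords[cb$oxygens[1], ] - co)
    a <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    x <- .unitv(a - sum(a * z) * z)
    degenerate <- TRUE
  }
  y <- .cross(z, x)
  list(origin = co, axes = rbind(x = x, y = y, z = z),
       degenerate = degenerate)
}

#' Angle distribution at the carboxyl oxygen
#'
#' For every solute oxygen atom of site `oxygen_site` and every water atom
#' of species `water_site` within `shell_cutoff` of it, accumulates the
#' angle Co-O...W at the O vertex, i.e. between the rays O -> Co and
#' O -> water (alpha for Ow, beta for Hw). Every qualifying
#' (O, water-atom) pair is counted. The histogram is a raw angle frequency
#' (no sin-theta Jacobian), normalized to unit integral over degrees.
#'
#' @param ensemble An [run_simulation()] result (or [static_ensemble()] with
#'   a topology).
#' @param oxygen_site Carboxyl oxygen site label ("O", or "Oh" for the
#'   single-bonded site of ectoine/trigonelline).
#' @param water_site "Ow" or "Hw".
#' @param shell_cutoff Shell radius around the oxygen, Angstrom. Defaults:
#'   3.3 for O...Ow, 2.4 for O...Hw (hydrogen-bond first-minimum
#'   conventions).
#' @param bins Number of bins on 0-180 degrees.
#' @param topology Optional explicit solute [molecule_topology()].
#' @return A list of class `angle_distribution`: theta (bin centers, deg),
#'   density (1/deg, unit integral), counts, definition ("alpha"/"beta"),
#'   shell_cutoff, n_pairs.
#' @export
angle_distribution <- function(ensemble, oxygen_site = "O",
                               water_site = c("Ow", "Hw"),
                               shell_cutoff = NULL, bins = 90,
                               topology = NULL) {
  water_site <- match.arg(water_site)
  if (is.null(shell_cutoff)) {
    shell_cutoff <- if (water_site == "Ow") 3.3 else 2.4
  }
  tp <- .carboxyl_topology(ensemble, topology)
  cb <- tp$carboxyl
  ox_local <- intersect(cb$oxygens,
                        which(tp$atoms$label == oxygen_site))
  if (length(ox_local) == 0) {
    .stopf("site '%s' is not part of the carboxyl designation of %s",
           oxygen_site, tp$name)
  }
  mol_rows <- .molecule_rows(ensemble, tp$name)
  if (length(mol_rows) == 0) .stopf("no %s molecules in ensemble", tp$name)
  wat <- .site_indices(ensemble, water_site)
  if (length(wat) == 0) .stopf("no %s atoms in ensemble", water_site)
  L <- ensemble$L
  width <- 180 / bins
  counts <- numeric(bins)
  npairs <- 0
  for (X in ensemble$frames) {
    W <- X[wat, , drop = FALSE]
    for (rows in mol_rows) {
      co <- X[rows[cb$carbon], ]
      for (oi in ox_local) {
        o <- X[rows[oi], ]
        dv <- sweep(W, 2, o)
        dv <- dv - L * round(dv / L)
        d2 <- rowSums(dv^2)
        sel <- which(d2 <= shell_cutoff^2 & d2 > 1e-12)
        if (!length(sel)) next
        # angle at the O vertex between the rays O -> Co and O -> water
        # (the Co-O...W convention: a water collinear beyond O reads 180 deg)
        u <- .min_image_vec(co - o, L)
        u <- u / sqrt(sum(u^2))
        ct <- (dv[sel, , drop = FALSE] %*% u) / sqrt(d2[sel])
        ang <- acos(pmin(1, pmax(-1, ct))) / .deg2rad
        b <- pmin(bins, floor(ang / width) + 1)
        for (k in b) counts[k] <- counts[k] + 1
        npairs <- npairs + length(sel)
      }
    }
  }
  if (npairs == 0) {
    .stopf(paste("empty shell: no %s atoms within %.2f A of any %s site;",
                 "run longer or enlarge the cutoff"),
           water_site, shell_cutoff, oxygen_site)
  }
  density <- counts / (sum(counts) * width)
  structure(list(theta = width * (seq_len(bins) - 0.5), density = density,
                 counts = counts,
                 definition = if (water_site == "Ow") "alpha" else "beta",
                 oxygen_site = oxygen_site, water_site = water_site,
                 shell_cutoff = shell_cutoff, n_pairs = npairs),
            class = "angle_distribution")
}

#' Peak position by quadratic interpolation
#'
#' Location of the maximum of a sampled curve, refined by a three-point
#' quadratic fit around the argmax. A maximum on the grid boundary is
#' flagged and returned unrefined.
#'
#' @param x Grid.
#' @param y Values (same length); pass an `angle_distribution` or
#'   `pair_rdf` as `x` to use its natural grid.
#' @return `list(position =, height =, at_boundary =)`.
#' @export
peak_position <- function(x, y = NULL) {
  if (inherits(x, "angle_distribution")) { y <- x$density; x <- x$theta }
  if (inherits(x, "pair_rdf")) { y <- x$g; x <- x$r }
  stopifnot(length(x) == length(y), length(x) >= 3)
  i <- which.max(y)
  if (i == 1 || i == length(y)) {
    return(list(position = x[i], height = y[i], at_boundary = TRUE))
  }
  # vertex of the parabola through the three points around the maximum
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (abs(denom) < 1e-300) 0 else
    0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  h <- x[i + 1] - x[i]
  list(position = x[i] + delta * h,
       height = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta,
       at_boundary = FALSE)
}

#' Mode of an angle distribution
#'
#' Position of the maximum of the (lightly smoothed) angle histogram,
#' refined by quadratic interpolation.
#'
#' @param dist An [angle_distribution()].
#' @param smooth_bins Running-mean width in bins (default 5).
#' @return Mode in degrees.
#' @export
distribution_mode <- function(dist, smooth_bins = 5) {
  d <- .smooth_running(dist$density, smooth_bins)
  peak_position(dist$theta, d)$position
}

.smooth_running <- function(y, width) {
  if (width <= 1) return(y)
  if (width %% 2 == 0) width <- width + 1
  k <- rep(1 / width, width)
  n <- length(y)
  ys <- stats::filter(y, k, sides = 2)
  ys <- as.numeric(ys)
  # shrink the window near the edges instead of dropping points
  half <- (width - 1) / 2
  for (i in seq_len(half)) {
    ys[i] <- mean(y[1:(i + half)])
    ys[n - i + 1] <- mean(y[(n - i + 1 - half):n])
  }
  ys
}

#' First peak of an RDF
#'
#' Position of the first local maximum of a lightly smoothed g(r) exceeding
#' `min_height`, refined by quadratic interpolation.
#'
#' @param rdf A [compute_rdf()] result.
#' @param smooth_bins Running-mean width in bins (odd; default 5).
#' @param min_height Minimum smoothed g at the peak (default 1.2; a first
#'   peak of a liquid-state RDF exceeds the ideal-gas level).
#' @return `list(position =, height =, at_boundary =)`.
#' @export
first_peak_position <- function(rdf, smooth_bins = 5, min_height = 1.2) {
  gs <- .smooth_running(rdf$g, smooth_bins)
  n <- length(gs)
  for (i in 2:(n - 1)) {
    if (gs[i] >= min_height && gs[i] >= gs[i - 1] && gs[i] > gs[i + 1]) {
      # the smoothed curve locates the peak; the quadratic refinement uses
      # the raw histogram (running means skew an asymmetric peak)
      g <- rdf$g
      half <- max(1, (smooth_bins - 1) %/% 2)
      lo <- max(2, i - half); hi <- min(n - 1, i + half)
      j <- (lo:hi)[which.max(g[lo:hi])]
      denom <- g[j - 1] - 2 * g[j] + g[j + 1]
      delta <- if (abs(denom) < 1e-300) 0 else
        0.5 * (g[j - 1] - g[j + 1]) / denom
      delta <- max(-0.5, min(0.5, delta))
      return(list(position = rdf$r[j] + delta * rdf$dr, height = g[j],
                  at_boundary = FALSE))
    }
  }
  .stopf("no resolved first peak (max smoothed g = %.3f)", max(gs))
}

#' First-shell cutoff from an RDF
#'
#' Position of the first local minimum after the first maximum of a lightly
#' smoothed g(r), refined by quadratic interpolation. The smoothing width is
#' configurable and recorded in the result.
#'
#' @param rdf A [compute_rdf()] result.
#' @param smooth_bins Running-mean width in bins (default 9).
#' @param min_height Minimum smoothed g for the first maximum (default 1.2).
#' @param prominence A candidate minimum only counts as the shell boundary
#'   if the smoothed g(r) later rises above it by this fraction of the
#'   peak-to-minimum drop (default 0.2); shallower dips are treated as
#'   sampling noise and the scan continues.
#' @return `list(position =, g_min =, peak =, smooth_bins =)`.
#' @export
first_shell_cutoff <- function(rdf, smooth_bins = 9, min_height = 1.2,
                               prominence = 0.2) {
  g <- .smooth_running(rdf$g, smooth_bins)
  n <- length(g)
  ipk <- NA
  for (i in 2:(n - 1)) {
    if (g[i] >= min_height && g[i] >= g[i - 1] && g[i] > g[i + 1]) {
      ipk <- i; break
    }
  }
  if (is.na(ipk)) .stopf("no resolved first peak in g(r); no shell to cut")
  # track the running peak so the prominence test uses the true first
  # maximum even if g keeps rising briefly after ipk
  gpk <- max(g[ipk:min(n, ipk + smooth_bins)])
  imin <- NA
  for (i in (ipk + 1):(n - 1)) {
    if (g[i] <= g[i - 1] && g[i] < g[i + 1]) {
      # absolute cap so a shallow recovery after a dominant first peak
      # still qualifies (hard-shell-like g with a near-flat tail)
      rise_needed <- min(prominence * max(gpk - g[i], 1e-12), 0.25)
      ahead <- g[(i + 1):n]
      # does g recover by the required rise before falling below this dip?
      recov <- which(ahead >= g[i] + rise_needed)
      deeper <- which(ahead < g[i])
      if (length(recov) && (!length(deeper) || recov[1] < deeper[1])) {
        imin <- i; break
      }
    }
  }
  if (is.na(imin)) .stopf("g(r) has no local minimum after its first peak")
  # refine the minimum with the local three points (quadratic vertex)
  denom <- g[imin - 1] - 2 * g[imin] + g[imin + 1]
  delta <- if (abs(denom) < 1e-300) 0 else
    0.5 * (g[imin - 1] - g[imin + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(position = rdf$r[imin] + delta * rdf$dr, g_min = g[imin],
       peak = rdf$r[ipk], smooth_bins = smooth_bins)
}

#' Spatial density map of water around the carboxyl group
#'
#' For each frame and each solute molecule, water oxygens within `r_cut` of
#' the carboxyl carbon are transformed into the carboxyl local frame
#' ([carboxyl_local_frame()]) and accumulated on a cubic voxel grid centered
#' on the carbon; counts are converted to a number density averaged over
#' molecules and frames.
#'
#' @param ensemble An [run_simulation()] result.
#' @param r_cut First-shell cutoff around the carboxyl carbon, Angstrom.
#' @param grid_edge Cube edge of the map (>= 2 r_cut); default
#'   `2 * (r_cut + resolution)`.
#' @param resolution Voxel edge, Angstrom (default 0.25; must be <=
#'   r_cut / 4).
#' @param water_site Site binned into the map (default "Ow").
#' @param topology Optional explicit solute topology.
#' @return A list of class `spatial_density_map`: `density` (3D array,
#'   atoms/A^3), `axis` (voxel-center coordinates along each axis),
#'   `in_shell` (voxels attributable to the first shell), `r_cut`,
#'   `resolution`, `mean_shell_count`, `n_molecules`, `nframes`.
#' @export
compute_sdf <- function(ensemble, r_cut, grid_edge = NULL,
                        resolution = 0.25, water_site = "Ow",
                        topology = NULL) {
  if (resolution > r_cut / 4) {
    .stopf("resolution %.3f coarser than r_cut/4 = %.3f", resolution,
           r_cut / 4)
  }
  if (is.null(grid_edge)) grid_edge <- 2 * (r_cut + resolution)
  if (grid_edge < 2 * r_cut) .stopf("grid_edge must be >= 2 * r_cut")
  tp <- .carboxyl_topology(ensemble, topology)
  cb <- tp$carboxyl
  mol_rows <- .molecule_rows(ensemble, tp$name)
  wat <- .site_indices(ensemble, water_site)
  L <- ensemble$L
  nvox <- ceiling(grid_edge / resolution)
  half <- nvox * resolution / 2
  dens <- array(0, dim = c(nvox, nvox, nvox))
  total <- 0
  for (X in ensemble$frames) {
    W <- X[wat, , drop = FALSE]
    for (rows in mol_rows) {
      xyz <- X[rows, , drop = FALSE]
      fr <- carboxyl_local_frame(xyz, tp)
      dv <- sweep(W, 2, fr$origin)
      dv <- dv - L * round(dv / L)
      d2 <- rowSums(dv^2)
      sel <- which(d2 <= r_cut^2)
      if (!length(sel)) next
      loc <- dv[sel, , drop = FALSE] %*% t(fr$axes)
      ix <- floor((loc + half) / resolution) + 1
      ok <- rowSums(ix >= 1 & ix <= nvox) == 3
      ix <- ix[ok, , drop = FALSE]
      for (k in seq_len(nrow(ix))) {
        dens[ix[k, 1], ix[k, 2], ix[k, 3]] <-
          dens[ix[k, 1], ix[k, 2], ix[k, 3]] + 1
      }
      total <- total + nrow(ix)
    }
  }
  nf <- length(ensemble$frames)
  nm <- length(mol_rows)
  vox_vol <- resolution^3
  dens <- dens / (nf * nm * vox_vol)
  ax <- (seq_len(nvox) - 0.5) * resolution - half
  # voxels attributable to the shell: centers within r_cut plus the voxel
  # half-diagonal, so every binned water is inside the in-shell set and the
  # map integral over it equals the mean shell count exactly
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  in_shell <- rr <= r_cut + sqrt(3) / 2 * resolution
  structure(list(density = dens, axis = ax, in_shell = in_shell,
                 r_cut = r_cut, resolution = resolution,
                 mean_shell_count = total / (nf * nm),
                 n_molecules = nm, nframes = nf,
                 water_site = water_site), class = "spatial_density_map")
}

#' Isodensity level enclosing a given fraction of first-shell water
#'
#' Sorts in-shell voxels by density (descending, ties broken by voxel index
#' order) and accumulates until the enclosed water fraction first reaches
#' `fraction`; returns the threshold density and the voxel mask. A higher
#' fraction always yields a lower (or equal) threshold.
#'
#' @param map A [compute_sdf()] result.
#' @param fraction Target occupancy fraction, 0 < fraction < 1 (the study
#'   convention is 0.35: the densest regions holding 35% of first-shell
#'   water).
#' @return `list(level =, mask =, enclosed_fraction =, fraction =)`; `mask`
#'   is a logical array of the map's shape.
#' @export
isodensity_level <- function(map, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  d <- map$density[map$in_shell]
  tot <- sum(d)
  if (tot <= 0) .stopf("fraction unreachable: no density inside the shell")
  ord <- order(-d)          # ties: earlier voxel index first (order is stable)
  cum <- cumsum(d[ord]) / tot
  k <- which(cum >= fraction)[1]
  if (is.na(k)) .stopf("fraction unreachable")
  level <- d[ord[k]]
  mask <- array(FALSE, dim = dim(map$density))
  shell_idx <- which(map$in_shell)
  mask[shell_idx[ord[seq_len(k)]]] <- TRUE
  list(level = level, mask = mask, enclosed_fraction = cum[k],
       fraction = fraction)
}

#' Export a spatial density map
#'
#' Writes a Gaussian-cube-style grid (Angstrom units, axes = the carboxyl
#' local frame) or a voxel CSV (x, y, z, density, in_mask).
#'
#' @param map A [compute_sdf()] result.
#' @param path Output path.
#' @param format "cube" or "csv".
#' @param mask Optional logical array (e.g. from [isodensity_level()]) for
#'   the CSV in_mask column.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(map, path, format = c("cube", "csv"), mask = NULL) {
  format <- match.arg(format)
  n <- length(map$axis)
  res <- map$resolution
  orig <- map$axis[1] - res / 2
  if (format == "cube") {
    lines <- c("spatial density map (water oxygen, carboxyl local frame)",
               sprintf("r_cut %.4f A; density in atoms/A^3; axes x,y,z", map$r_cut),
               sprintf("%5d %11.6f %11.6f %11.6f", 1, orig, orig, orig),
               sprintf("%5d %11.6f %11.6f %11.6f", n, res, 0, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", n, 0, res, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", n, 0, 0, res),
               sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 6, 0, 0, 0, 0))
    vals <- character(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      row <- map$density[i, j, ]
      vals <- c(vals, paste(sprintf("%13.5e", row), collapse = " "))
    }
    writeLines(c(lines, vals), path)
  } else {
    grid <- expand.grid(x = map$axis, y = map$axis, z = map$axis)
    df <- data.frame(grid,
                     density = as.vector(map$density),
                     in_mask = if (is.null(mask)) as.vector(map$in_shell)
                               else as.vector(mask))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
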