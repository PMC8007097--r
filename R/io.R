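# cli_io file plumbing: tab-separated curve files with '#'-prefixed
# key: value metadata headers ('.' decimal, lengths in Angstrom, Q in 1/A,
# energies kJ/mol, angles degrees), ensemble XYZ reading, config hashing.

#' Write a curve table with metadata headers
#'
#' @param df data.frame of numeric columns.
#' @param path Output path.
#' @param meta Named list of scalar metadata written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 17),
                                            collapse = "\t")), con)
  }
  writeLines(paste(colnames(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a curve table written by [write_curve()]
#'
#' @param path Input path.
#' @return `list(data = data.frame, meta = named character list)`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!is_meta]
  header <- strsplit(body[1], "\t")[[1]]
  data <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                            sep = "\t", col.names = header,
                            check.names = FALSE)
  list(data = data, meta = meta)
}

#' Write a total F(Q) contrast set
#'
#' One Q column plus one column per contrast, with provenance metadata.
#'
#' @param fqset A `total_fq_set` (or compatible list with Q and F matrix).
#' @param path Output path.
#' @param meta Extra metadata entries.
#' @return `path`, invisibly.
#' @export
write_fq_set <- function(fqset, path, meta = list()) {
  df <- data.frame(Q = fqset$Q, fqset$F, check.names = FALSE)
  meta <- c(list(quantity = "total interference cross section F(Q), fm^2/atom",
                 contrasts = paste(colnames(fqset$F), collapse = "\t")),
            meta)
  write_curve(df, path, meta)
}

#' Read a total F(Q) contrast set written by [write_fq_set()]
#' @param path Input path.
#' @return A `total_fq_set`-compatible list (Q, F matrix, meta).
#' @export
read_fq_set <- function(path) {
  cv <- read_curve(path)
  Q <- cv$data$Q
  F <- as.matrix(cv$data[, setdiff(colnames(cv$data), "Q"), drop = FALSE])
  structure(list(Q = Q, F = F, meta = cv$meta), class = "total_fq_set")
}

#' Write / read a perturbation potential as tabular r/U pairs
#' @param pert A [perturbation_potential()].
#' @param path Output path.
#' @param meta Extra metadata.
#' @return `path`, invisibly.
#' @export
write_perturbation <- function(pert, path, meta = list()) {
  df <- data.frame(r = pert$r, pert$U, check.names = FALSE)
  write_curve(df, path, c(list(quantity = "perturbation potential, kJ/mol",
                               cap = pert$cap), meta))
}

#' @rdname write_perturbation
#' @export
read_perturbation <- function(path) {
  cv <- read_curve(path)
  cols <- setdiff(colnames(cv$data), "r")
  ab <- strsplit(cols, "-", fixed = TRUE)
  pairs <- data.frame(a = vapply(ab, `[`, "", 1),
                      b = vapply(ab, `[`, "", 2), stringsAsFactors = FALSE)
  r <- cv$data$r
  perturbation_potential(pairs, rmax = max(r), dr = r[2] - r[1],
                         U = as.matrix(cv$data[, cols, drop = FALSE]),
                         cap = as.numeric(cv$meta$cap))
}

#' Read a multi-frame extended XYZ ensemble written by [write_ensemble_xyz()]
#'
#' @param path Input path.
#' @param topology Optional [molecule_topology()] for the solute (enables
#'   the carboxyl-frame analysis on the restored ensemble).
#' @return An `mc_ensemble`-compatible list.
#' @export
read_ensemble_xyz <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms <- NULL
  L <- NA_real_
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    L <- as.numeric(regmatches(hdr, regexec('Lattice="([0-9.eE+-]+) ', hdr))[[1]][2])
    block <- lines[(i + 2):(i + 1 + n)]
    tab <- utils::read.table(text = paste(block, collapse = "\n"),
                             col.names = c("element", "x", "y", "z",
                                           "label", "mol", "topo"))
    frames[[length(frames) + 1]] <- as.matrix(tab[, c("x", "y", "z")])
    if (is.null(atoms)) {
      atoms <- data.frame(mol = tab$mol, topology = tab$topo,
                          label = tab$label, element = tab$element,
                          stringsAsFactors = FALSE)
    }
    i <- i + 2 + n
  }
  structure(list(frames = frames, L = L, volume = L^3, atoms = atoms,
                 system = NULL, topology = topology), class = "mc_ensemble")
}

#' Write an angle distribution as tab-separated text
#' @param dist An [angle_distribution()].
#' @param path Output path.
#' @param meta Extra metadata.
#' @return `path`, invisibly.
#' @export
write_angle_distribution <- function(dist, path, meta = list()) {
  write_curve(data.frame(theta_deg = dist$theta, density = dist$density),
              path,
              c(list(definition = dist$definition,
                     oxygen_site = dist$oxygen_site,
                     water_site = dist$water_site,
                     shell_cutoff_A = dist$shell_cutoff,
                     jacobian = "none (raw angle frequency)",
                     n_pairs = dist$n_pairs), meta))
}

#' Write a pair RDF as tab-separated text
#' @param rdf A [compute_rdf()].
#' @param path Output path.
#' @param meta Extra metadata.
#' @return `path`, invisibly.
#' @export
write_rdf <- function(rdf, path, meta = list()) {
  write_curve(data.frame(r = rdf$r, g = rdf$g), path,
              c(list(pair = paste(rdf$pair, collapse = "-"), dr = rdf$dr,
                     rho_partner = rdf$rho_partner), meta))
}

# md5 of a resolved-config file; stamped into output headers so outputs are
# traceable to the exact configuration that produced them.
.config_hash <- function(path) unname(tools::md5sum(path))
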