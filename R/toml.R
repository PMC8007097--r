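# Minimal TOML-subset reader/writer used for force-field, system and run
# configuration files. Supported subset: '#' comments, [table] headers,
# single-line `key = value` pairs where value is a string ("..."), boolean
# (true/false), number, or a flat array [v1, v2, ...] of one of those.
# Floats are written with %.17g so write -> read roundtrips are bit-exact.

.toml_escape <- function(s) gsub('"', '\\\\"', s)

.toml_format_scalar <- function(v) {
  if (is.character(v)) sprintf('"%s"', .toml_escape(v))
  else if (is.logical(v)) ifelse(v, "true", "false")
  else if (is.numeric(v)) {
    if (is.integer(v) || (is.finite(v) && v == round(v) && abs(v) < 2^31)) {
      sprintf("%d", as.integer(v))
    } else sprintf("%.17g", v)
  } else .stopf("unsupported TOML value of class %s", class(v)[1])
}

.toml_format_value <- function(v) {
  if (length(v) == 1 && !is.list(v)) return(.toml_format_scalar(v))
  sprintf("[%s]", paste(vapply(v, .toml_format_scalar, character(1)),
                        collapse = ", "))
}

#' Write a configuration list as TOML-subset text
#'
#' Top-level scalar/vector entries come first, then one `[name]` table per
#' list-valued entry. Values may be strings, booleans or numbers; vectors
#' become flat arrays.
#'
#' @param x Named list; list-valued elements become tables.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_toml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- character(0)
  simple <- !vapply(x, is.list, logical(1))
  for (k in names(x)[simple]) {
    lines <- c(lines, sprintf("%s = %s", k, .toml_format_value(x[[k]])))
  }
  for (k in names(x)[!simple]) {
    tab <- x[[k]]
    lines <- c(lines, "", sprintf("[%s]", k))
    for (kk in names(tab)) {
      if (is.list(tab[[kk]])) .stopf("nested tables beyond one level are not supported")
      lines <- c(lines, sprintf("%s = %s", kk, .toml_format_value(tab[[kk]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.toml_parse_scalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('\\\\"', '"', substr(tok, 2, nchar(tok) - 1)))
  if (tok == "true") return(TRUE)
  if (tok == "false") return(FALSE)
  num <- suppressWarnings(as.numeric(tok))
  if (is.na(num)) .stopf("cannot parse TOML value: %s", tok)
  num
}

# Split a flat array body on commas that are not inside quotes.
.toml_split_array <- function(body) {
  chars <- strsplit(body, "")[[1]]
  out <- character(0); cur <- ""; inq <- FALSE; esc <- FALSE
  for (ch in chars) {
    if (esc) { cur <- paste0(cur, ch); esc <- FALSE; next }
    if (ch == "\\") { cur <- paste0(cur, ch); esc <- TRUE; next }
    if (ch == '"') inq <- !inq
    if (ch == "," && !inq) { out <- c(out, cur); cur <- "" } else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

.toml_parse_value <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[", v)) {
    body <- sub("^\\[", "", sub("\\]$", "", v))
    if (trimws(body) == "") return(numeric(0))
    vals <- lapply(.toml_split_array(body), .toml_parse_scalar)
    return(unlist(vals))
  }
  .toml_parse_scalar(v)
}

#' Read a TOML-subset configuration file
#'
#' @param path File written by [write_toml()] (or conforming to the same
#'   subset: comments, one-line key/value pairs, single-level tables).
#' @return Named list; `[table]` sections become nested named lists.
#' @export
read_toml <- function(path) {
  raw <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (line in raw) {
    # strip comments outside quotes
    chars <- strsplit(line, "")[[1]]
    inq <- FALSE; keep <- character(0)
    for (ch in chars) {
      if (ch == '"') inq <- !inq
      if (ch == "#" && !inq) break
      keep <- c(keep, ch)
    }
    line <- trimws(paste(keep, collapse = ""))
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- sub("^\\[", "", sub("\\]$", "", line))
      out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) .stopf("malformed TOML line: %s", line)
    key <- trimws(substr(line, 1, eq - 1))
    val <- .toml_parse_value(substr(line, eq + 1, nchar(line)))
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}
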