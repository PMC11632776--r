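#' Read an engine-style or delimited numeric table
#'
#' Parses GROMACS xvg-style tables (lines starting with `#` or `@` are
#' comments; `@` axis-label metadata is ignored) or plain delimited text into
#' a [ts_table]. Blank lines and trailing whitespace are ignored. Columns are
#' auto-named `t, v1, v2, ...` unless `col_names` is given. A header row of
#' non-numeric tokens in the delimited dialect supplies column names.
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"auto"` (default), `"xvg"` (engine-table) or `"delim"`.
#' @param col_names optional character vector of column names.
#' @param units optional character vector of unit strings per column.
#' @param pressure_cols names/indices of columns holding pressure in bar, to be
#'   converted to GPa on read (1 bar = 1e-4 GPa).
#' @return a [ts_table].
#' @export
read_table <- function(source, dialect = c("auto", "xvg", "delim"),
                       col_names = NULL, units = NULL, pressure_cols = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows")

  is_comment <- grepl("^[ \t]*[#@]", lines)
  payload <- lines[!is_comment]
  payno <- lineno[!is_comment]
  if (length(payload) == 0L) stop("no data rows")

  ## delimited dialect may carry a header row of names
  toks1 <- strsplit(trimws(payload[1L]), "[,; \t]+")[[1L]]
  has_header <- dialect != "xvg" && anyNA(suppressWarnings(as.numeric(toks1)))
  if (has_header) {
    if (is.null(col_names)) col_names <- toks1
    payload <- payload[-1L]
    payno <- payno[-1L]
    if (length(payload) == 0L) stop("no data rows")
  }

  rows <- strsplit(trimws(payload), "[,; \t]+")
  arity <- lengths(rows)
  if (length(unique(arity)) != 1L)
    stop(sprintf("inconsistent arity at line %d (expected %d fields, got %d)",
                 payno[which(arity != arity[1L])[1L]], arity[1L],
                 arity[arity != arity[1L]][1L]))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(vapply(rows, function(r)
      anyNA(suppressWarnings(as.numeric(r))), logical(1)))[1L]
    stop(sprintf("non-numeric value at line %d", payno[bad]))
  }
  m <- matrix(vals, ncol = arity[1L], byrow = TRUE)
  if (is.null(col_names))
    col_names <- c("t", if (ncol(m) > 1L) paste0("v", seq_len(ncol(m) - 1L)))
  df <- as.data.frame(m)
  names(df) <- col_names[seq_len(ncol(m))]
  tab <- ts_table(df, units)
  if (!is.null(pressure_cols)) {
    u <- attr(tab, "units")
    for (pc in pressure_cols) {
      tab[[pc]] <- tab[[pc]] * 1e-4   # bar -> GPa
      u[[if (is.numeric(pc)) names(tab)[pc] else pc]] <- "GPa"
    }
    attr(tab, "units") <- u
  }
  tab
}

#' Write a time-series table as delimited text
#'
#' Header row carries column names; a second comment line records units.
#' Re-reading with [read_table] round-trips values to full stored precision.
#'
#' @param tab a [ts_table].
#' @param file output path.
#' @export
write_table <- function(tab, file) {
  u <- attr(tab, "units")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(paste0("# units: ", paste(u, collapse = "\t")), con)
  body <- apply(as.data.frame(tab), 1L,
                function(r) paste(formatC(r, digits = 17, format = "g"),
                                  collapse = "\t"))
  writeLines(body, con)
  invisible(file)
}

## ---- coordinate frames -----------------------------------------------------

element_from_name <- function(name) {
  sym <- sub("^[0-9]*", "", name)
  two <- substr(sym, 1, 2)
  one <- toupper(substr(sym, 1, 1))
  known2 <- c("Cl", "Br", "Na", "Mg", "Ca", "Fe", "Zn", "Si")
  ifelse(two %in% known2, two, one)
}

#' Read a single coordinate frame
#'
#' Supports GRO (fixed-width, positions in nm, final box line) and extended
#' XYZ (count line, comment line with `Lattice="..."`, atom lines). Only
#' orthorhombic boxes are supported; triclinic lattices raise an error.
#'
#' @param source path or character vector of lines.
#' @param format `"auto"`, `"gro"` or `"xyz"`.
#' @param xyz_unit unit of extended-XYZ coordinates; `"nm"` (default) or
#'   `"angstrom"` (converted to nm on read).
#' @return a [config_frame].
#' @export
read_frame <- function(source, format = c("auto", "gro", "xyz"),
                       xyz_unit = c("nm", "angstrom")) {
  format <- match.arg(format)
  xyz_unit <- match.arg(xyz_unit)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- sub("[\r]+$", "", lines)
  if (length(lines) < 2L) stop("truncated frame")
  if (format == "auto") {
    n2 <- suppressWarnings(as.integer(trimws(lines[1L])))
    format <- if (!is.na(n2)) "xyz" else "gro"
  }
  if (format == "gro") read_gro(lines) else read_xyz(lines, xyz_unit)
}

read_gro <- function(lines) {
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n)) stop("GRO: bad atom-count line")
  if (length(lines) < n + 3L) stop("truncated frame: fewer lines than declared atoms")
  at <- lines[3:(2 + n)]
  if (any(nchar(at) < 44L))
    stop(sprintf("GRO: atom count mismatch or short atom line (declared %d atoms)", n))
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (anyNA(c(x, y, z)) || anyNA(resid)) stop("GRO: unparsable atom line")
  boxline <- trimws(lines[n + 3L])
  if (!nzchar(boxline)) stop("missing box")
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "[ \t]+")[[1L]]))
  if (anyNA(bv) || length(bv) < 3L) stop("missing box")
  if (length(bv) > 3L && any(abs(bv[-(1:3)]) > 1e-12))
    stop("triclinic boxes are unsupported")
  config_frame(data.frame(element = element_from_name(name), name = name,
                          resname = resname, mol = resid,
                          x = x, y = y, z = z,
                          stringsAsFactors = FALSE),
               bv[1:3])
}

read_xyz <- function(lines, xyz_unit) {
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("XYZ: bad count line")
  if (length(lines) < n + 2L) stop("truncated frame: fewer lines than declared atoms")
  comment <- lines[2L]
  lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(lat) == 0L) stop("missing box (no Lattice in extended-XYZ comment)")
  lv <- as.numeric(strsplit(trimws(sub('Lattice="', "", sub('"$', "", lat))),
                            "[ \t]+")[[1L]])
  if (length(lv) != 9L || anyNA(lv)) stop("missing box (bad Lattice)")
  off <- lv[-c(1, 5, 9)]
  if (any(abs(off) > 1e-12)) stop("triclinic boxes are unsupported")
  box <- lv[c(1, 5, 9)]
  scale <- if (xyz_unit == "angstrom") 0.1 else 1
  toks <- strsplit(trimws(lines[3:(2 + n)]), "[ \t]+")
  if (any(lengths(toks) < 4L)) stop("XYZ: short atom line")
  el <- vapply(toks, `[[`, character(1), 1L)
  xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("XYZ: unparsable coordinates")
  config_frame(data.frame(element = element_from_name(el), name = el,
                          resname = "MOL", mol = seq_len(n),
                          x = xyz[, 1] * scale, y = xyz[, 2] * scale,
                          z = xyz[, 3] * scale, stringsAsFactors = FALSE),
               box * scale)
}

#' Write a configuration frame in GRO format
#'
#' Fixed-width GRO with positions to 0.001 nm (the format's precision).
#'
#' @param frame a [config_frame].
#' @param file output path.
#' @param title title line content.
#' @export
write_frame <- function(frame, file, title = "mdprops frame") {
  a <- frame$atoms
  n <- nrow(a)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", n), con)
  if (n > 0L) {
    ln <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  a$mol %% 100000L, substr(a$resname, 1, 5),
                  substr(a$name, 1, 5), seq_len(n) %% 100000L,
                  a$x, a$y, a$z)
    writeLines(ln, con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     frame$box[1], frame$box[2], frame$box[3]), con)
  invisible(file)
}

## ---- results ---------------------------------------------------------------

#' Write property results as delimited text
#'
#' One record per result with a fixed header `name value unit error` followed
#' by provenance key=value pairs. Deterministic: identical inputs give
#' byte-identical output.
#'
#' @param results a list of [property_result] objects (or a single one).
#' @param file output path.
#' @export
write_results <- function(results, file) {
  if (inherits(results, "property_result")) results <- list(results)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("name\tvalue\tunit\terror\tprovenance", con)
  for (r in results) {
    fmt1 <- function(v) {
      v <- unlist(v)
      if (is.numeric(v)) paste(formatC(v, format = "g", digits = 17),
                               collapse = ":")
      else paste(as.character(v), collapse = ":")
    }
    prov <- if (length(r$provenance))
      paste(vapply(names(r$provenance), function(k)
        sprintf("%s=%s", k, fmt1(r$provenance[[k]])), character(1)),
        collapse = ";")
    else ""
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", r$name,
                       formatC(r$value, digits = 17, format = "g"), r$unit,
                       if (is.na(r$error)) "NA"
                       else formatC(r$error, digits = 17, format = "g"),
                       prov), con)
  }
  invisible(file)
}

#' Read back a results file written by [write_results]
#' @param file path.
#' @return data.frame with columns name, value, unit, error, provenance.
#' @export
read_results <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df$error <- suppressWarnings(as.numeric(df$error))
  df
}
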