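#' Time-series table
#'
#' The universal tabular carrier for engine-style analysis output: an ordered
#' set of records whose first column is the independent variable (time in ns,
#' temperature in K, or strain). Internally a `data.frame` with a `units`
#' attribute, one unit string per column (`"dimensionless"` is the explicit
#' marker for unitless columns).
#'
#' @param data a data.frame of numeric columns; the first column must be
#'   strictly increasing.
#' @param units character vector of unit strings, one per column. Missing or
#'   `NA` entries become `"dimensionless"`.
#' @return an object of class `ts_table` (a data.frame).
#' @export
ts_table <- function(data, units = NULL) {
  data <- as.data.frame(data)
  if (ncol(data) < 1L || nrow(data) < 1L)
    stop("ts_table needs at least one column and one row")
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all ts_table columns must be numeric")
  iv <- data[[1L]]
  if (anyNA(iv) || any(diff(iv) <= 0))
    stop("independent variable (first column) must be strictly increasing")
  if (is.null(units)) units <- rep("dimensionless", ncol(data))
  units <- as.character(units)
  if (length(units) != ncol(data))
    stop("length(units) must equal ncol(data)")
  units[is.na(units) | !nzchar(units)] <- "dimensionless"
  attr(data, "units") <- stats::setNames(units, names(data))
  class(data) <- c("ts_table", "data.frame")
  data
}

#' Units of a time-series table
#' @param x a `ts_table`.
#' @return named character vector of unit strings.
#' @export
units_of <- function(x) attr(x, "units")

#' @export
print.ts_table <- function(x, ...) {
  u <- attr(x, "units")
  cat(sprintf("ts_table: %d rows x %d cols\n", nrow(x), ncol(x)))
  cat("  columns:", paste(sprintf("%s [%s]", names(x), u), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Periodic configuration frame
#'
#' One coordinate frame: atom identities and positions plus an orthorhombic
#' periodic box. Positions and box lengths are in nm. Triclinic boxes are not
#' supported.
#'
#' @param atoms data.frame with columns `element`, `name`, `resname`, `mol`
#'   (molecule index), `x`, `y`, `z` (nm). Missing identity columns are filled
#'   from `element`.
#' @param box numeric length-3 vector of orthorhombic box edge lengths (nm).
#' @return an object of class `config_frame`.
#' @export
config_frame <- function(atoms, box) {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) > 0L) {
    if (is.null(atoms$element)) stop("atoms need an 'element' column")
    if (is.null(atoms$name)) atoms$name <- atoms$element
    if (is.null(atoms$resname)) atoms$resname <- "MOL"
    if (is.null(atoms$mol)) atoms$mol <- seq_len(nrow(atoms))
    for (cc in c("x", "y", "z"))
      if (is.null(atoms[[cc]])) stop("atoms need numeric x, y, z columns (nm)")
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("atom positions must be finite")
    if (any(atoms$mol < 0)) stop("molecule indices must be non-negative")
  }
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (nm)")
  structure(list(atoms = atoms, box = box), class = "config_frame")
}

#' @export
print.config_frame <- function(x, ...) {
  cat(sprintf("config_frame: %d atoms, box %.4f x %.4f x %.4f nm\n",
              nrow(x$atoms), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Positions of a configuration frame as a matrix
#' @param frame a `config_frame`.
#' @return n x 3 numeric matrix (nm).
#' @export
frame_positions <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Named scalar property with provenance
#'
#' @param name short property identifier.
#' @param value numeric scalar.
#' @param unit unit string (`"dimensionless"` for unitless).
#' @param error non-negative uncertainty, or `NA` when absent.
#' @param provenance named list of every window/threshold/setting that
#'   influenced the value.
#' @return an object of class `property_result`.
#' @export
property_result <- function(name, value, unit, error = NA_real_,
                            provenance = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(value), length(value) == 1L,
            is.character(unit), length(unit) == 1L, nzchar(unit))
  error <- as.numeric(error)
  if (!is.na(error) && error < 0) stop("error must be non-negative")
  structure(list(name = name, value = as.numeric(value), unit = unit,
                 error = error, provenance = provenance),
            class = "property_result")
}

#' @export
print.property_result <- function(x, ...) {
  err <- if (is.na(x$error)) "" else sprintf(" +/- %.6g", x$error)
  cat(sprintf("%s = %.6g%s %s\n", x$name, x$value, err, x$unit))
  if (length(x$provenance)) {
    kv <- vapply(names(x$provenance),
                 function(k) sprintf("%s=%s", k,
                                     paste(format(x$provenance[[k]]), collapse = ":")),
                 character(1))
    cat("  provenance:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

## minimum-image displacement, vectorized over rows of a displacement matrix
min_image <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = length(box))
  for (k in seq_along(box)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
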