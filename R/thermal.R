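#' Temperature-indexed density / specific-volume series
#'
#' Points of a cooling curve: temperature (K), density (g/cm3) and specific
#' volume (cm3/g, always the reciprocal density). Temperatures are sorted and
#' must be distinct; densities must be positive.
#'
#' @param data data.frame with columns `temperature` and `density` (a
#'   `specific_volume` column, if present, is validated against 1/density).
#' @param cooling_step cooling increment metadata (K), optional.
#' @param window averaging-window metadata (ns), optional.
#' @return an object of class `vt_series` (a data.frame).
#' @export
vt_series <- function(data, cooling_step = NA_real_, window = NA_real_) {
  data <- as.data.frame(data)
  stopifnot(all(c("temperature", "density") %in% names(data)))
  if (anyDuplicated(data$temperature)) stop("duplicate temperatures")
  if (any(data$density <= 0)) stop("densities must be positive")
  data <- data[order(data$temperature), , drop = FALSE]
  sv <- 1 / data$density
  if (!is.null(data$specific_volume) &&
      any(abs(data$specific_volume - sv) > 1e-12 * abs(sv)))
    stop("specific_volume must equal 1/density")
  data$specific_volume <- sv
  rownames(data) <- NULL
  structure(data, class = c("vt_series", "data.frame"),
            cooling_step = cooling_step, window = window)
}

#' @export
print.vt_series <- function(x, ...) {
  cat(sprintf("vt_series: %d temperatures, %g-%g K\n", nrow(x),
              min(x$temperature), max(x$temperature)))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Mean density over the final window of a run
#'
#' Averages the density over the last `window` ns of a (time, density)
#' series, the convention used to report one density per cooling step.
#'
#' @param series a [ts_table] whose first column is time (ns) and second is
#'   density (g/cm3).
#' @param window averaging window (ns); the series must span at least this.
#' @return a [property_result] (mean density, sd as error, window in
#'   provenance).
#' @export
average_density <- function(series, window = 0.5) {
  t <- series[[1L]]
  if (max(t) - min(t) < window) stop("window exceeds series")
  sel <- t >= max(t) - window
  rho <- series[[2L]][sel]
  property_result("density", mean(rho), "g/cm^3",
                  error = stats::sd(rho) * sqrt((sum(sel) - 1) / sum(sel)),
                  provenance = list(window_ns = window, n_samples = sum(sel)))
}

#' Assemble a cooling curve from per-temperature densities
#'
#' @param temperatures temperatures (K), distinct.
#' @param densities densities, either numeric (g/cm3) or a list of
#'   [property_result]s as returned by [average_density].
#' @param cooling_step,window metadata passed to [vt_series].
#' @return a [vt_series], sorted by temperature, with specific volume as
#'   reciprocal density.
#' @export
build_vt_series <- function(temperatures, densities,
                            cooling_step = NA_real_, window = NA_real_) {
  if (is.list(densities) && all(vapply(densities, inherits, logical(1),
                                       "property_result")))
    densities <- vapply(densities, `[[`, numeric(1), "value")
  stopifnot(length(temperatures) == length(densities))
  vt_series(data.frame(temperature = temperatures, density = densities),
            cooling_step = cooling_step, window = window)
}

#' Glass-transition temperature by broken-stick regression
#'
#' Fits ordinary least-squares lines to specific volume vs temperature
#' independently over a low-temperature and a high-temperature window (both
#' inclusive); the intersection abscissa of the two lines estimates Tg.
#'
#' @param vt a [vt_series].
#' @param low_window,high_window length-2 numeric ranges (K), endpoints
#'   inclusive; each must contain at least 2 points.
#' @param parallel_tol slope-difference (cm3/(g K)) below which the lines are
#'   declared parallel and Tg undefined.
#' @return an object of class `tg_result`: `tg` (K), `low_fit` / `high_fit`
#'   (slope, intercept, residual standard error, n) and the windows used.
#' @export
broken_stick_tg <- function(vt, low_window = c(150, 275),
                            high_window = c(475, 600),
                            parallel_tol = 1e-12) {
  fit_win <- function(win) {
    sel <- vt$temperature >= win[1] & vt$temperature <= win[2]
    if (sum(sel) < 2L)
      stop(sprintf("fewer than 2 points in window [%g, %g] K", win[1], win[2]))
    x <- vt$temperature[sel]; y <- vt$specific_volume[sel]
    fit <- stats::lm.fit(cbind(1, x), y)
    rse <- if (sum(sel) > 2L) sqrt(sum(fit$residuals^2) / (sum(sel) - 2L))
           else 0
    list(slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         rse = rse, n = sum(sel))
  }
  lo <- fit_win(low_window)
  hi <- fit_win(high_window)
  dslope <- hi$slope - lo$slope
  if (abs(dslope) < parallel_tol) stop("parallel fits, Tg undefined")
  tg <- (lo$intercept - hi$intercept) / dslope
  structure(list(tg = tg, low_fit = lo, high_fit = hi,
                 low_window = low_window, high_window = high_window),
            class = "tg_result")
}

#' @export
print.tg_result <- function(x, ...) {
  cat(sprintf("Tg = %.3f K (broken-stick regression)\n", x$tg))
  cat(sprintf("  low  [%g, %g] K: slope %.4g, n=%d\n", x$low_window[1],
              x$low_window[2], x$low_fit$slope, x$low_fit$n))
  cat(sprintf("  high [%g, %g] K: slope %.4g, n=%d\n", x$high_window[1],
              x$high_window[2], x$high_fit$slope, x$high_fit$n))
  invisible(x)
}

#' Volumetric thermal expansion coefficient over a temperature interval
#'
#' `alpha_V = (V(T2) - V(T1)) / ((T2 - T1) * V_ref)` in 1/K, from two points
#' of a cooling curve. The reference volume is `V(T1)` by default
#' (switchable to the midpoint volume); a narrow interval (25 K) is
#' recommended because alpha_V is strongly temperature dependent.
#'
#' @param vt a [vt_series].
#' @param T1,T2 temperatures (K) present in `vt`, `T2 > T1`.
#' @param normalization `"lower"` (reference `V(T1)`, default) or
#'   `"midpoint"` (reference `(V(T1)+V(T2))/2`).
#' @return a [property_result] in 1/K with the convention in provenance.
#' @export
thermal_expansion <- function(vt, T1, T2,
                              normalization = c("lower", "midpoint")) {
  normalization <- match.arg(normalization)
  if (T2 <= T1) stop("T2 must exceed T1")
  pick <- function(Tq) {
    i <- which(abs(vt$temperature - Tq) < 1e-9)
    if (length(i) != 1L) stop(sprintf("temperature %g K not in series", Tq))
    vt$specific_volume[i]
  }
  V1 <- pick(T1); V2 <- pick(T2)
  Vref <- if (normalization == "lower") V1 else (V1 + V2) / 2
  property_result("alpha_V", (V2 - V1) / ((T2 - T1) * Vref), "1/K",
                  provenance = list(T1_K = T1, T2_K = T2,
                                    normalization = normalization))
}
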