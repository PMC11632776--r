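#' Stress-strain curve
#'
#' Raw (and, after [smooth_reflect], smoothed) tensile stress vs engineering
#' strain. Stress is in GPa, strain dimensionless in \[0, 1\].
#'
#' @param strain strain grid, increasing, in \[0, 1\].
#' @param stress raw stress (GPa).
#' @param smoothed smoothed stress on the same grid, or `NULL`.
#' @param half_width smoothing half-width used (strain units), or `NA`.
#' @param reflected whether odd reflection around zero strain was applied.
#' @return an object of class `stress_strain`.
#' @export
stress_strain <- function(strain, stress, smoothed = NULL,
                          half_width = NA_real_, reflected = FALSE) {
  stopifnot(length(strain) == length(stress), all(diff(strain) > 0),
            all(strain >= 0), all(strain <= 1))
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress),
                 smoothed = smoothed, half_width = half_width,
                 reflected = reflected),
            class = "stress_strain")
}

#' @export
print.stress_strain <- function(x, ...) {
  cat(sprintf("stress_strain: %d points, strain %.4g-%.4g%s\n",
              length(x$strain), min(x$strain), max(x$strain),
              if (is.null(x$smoothed)) " (raw)" else
                sprintf(" (smoothed, half-width %.3g)", x$half_width)))
  invisible(x)
}

## stress values used by extraction operations: smoothed when available
curve_stress <- function(curve) {
  if (is.null(curve$smoothed)) curve$stress else curve$smoothed
}

#' Stress-strain curve from the axial pressure-tensor component
#'
#' Tensile stress is the negated axial pressure, `sigma = -P_z`, converted
#' from bar to GPa (1 bar = 1e-4 GPa) unless the pressure column is already
#' in GPa.
#'
#' @param pz a [ts_table] with columns (strain, P_z); the pressure column's
#'   unit must be `"bar"` or `"GPa"`.
#' @return a raw `stress_strain` curve.
#' @export
stress_from_pressure <- function(pz) {
  if (!"strain" %in% names(pz) && names(pz)[1L] != "strain")
    stop("missing strain column")
  u <- attr(pz, "units")[2L]
  fac <- switch(u, bar = 1e-4, GPa = 1,
                stop("pressure column must be flagged bar or GPa, got ", u))
  stress_strain(pz[[1L]], -pz[[2L]] * fac)
}

#' Engineering strain from box-length series
#'
#' `strain = (L_t - L0) / L0` per record.
#'
#' @param lengths a [ts_table] whose second column is the extended axial box
#'   length (nm).
#' @param L0 initial axial box length (nm), > 0.
#' @return numeric strain vector.
#' @export
strain_series <- function(lengths, L0) {
  if (L0 <= 0) stop("L0 must be positive")
  (lengths[[2L]] - L0) / L0
}

#' Smooth a stress-strain curve with odd reflection around zero strain
#'
#' Each smoothed value is the unweighted mean of the raw stress over the
#' strain window `[eps - h, eps + h]` (inclusive). For window portions below
#' zero strain the data are extended by odd reflection (points `(-eps',
#' -sigma')`), which forces the smoothed curve through (0, 0) and preserves
#' linear curves exactly; at the upper data edge the half-width shrinks
#' symmetrically to `min(h, eps_max - eps)` so no window extrapolates.
#'
#' @param curve a raw `stress_strain`.
#' @param half_width smoothing half-width in strain units (default 0.025,
#'   i.e. +/- 2.5 percent strain); must be positive and smaller than the
#'   data span.
#' @param reflect apply the odd reflection (default `TRUE`).
#' @return the curve with `smoothed` filled on the same grid.
#' @export
smooth_reflect <- function(curve, half_width = 0.025, reflect = TRUE) {
  eps <- curve$strain; sig <- curve$stress
  span <- max(eps) - min(eps)
  if (half_width <= 0) stop("half_width must be positive")
  if (half_width >= span) stop("half_width must be smaller than the data span")
  if (reflect) {
    ## odd extension around zero strain: negated mirror of the strictly
    ## positive points; a sample exactly at zero strain enters with its odd
    ## part (zero), so the extended set is point-symmetric and the smoothed
    ## curve passes through the origin exactly.
    pos <- eps > 0
    xall <- c(-rev(eps[pos]), eps)
    yall <- c(-rev(sig[pos]), ifelse(eps == 0, 0, sig))
  } else {
    xall <- eps; yall <- sig
  }
  tol <- 1e-12
  sm <- vapply(eps, function(e) {
    h <- min(half_width, max(eps) - e)
    if (!reflect) h <- min(h, e - min(eps))
    sel <- xall >= e - h - tol & xall <= e + h + tol
    mean(yall[sel])
  }, numeric(1))
  stress_strain(eps, sig, smoothed = sm, half_width = half_width,
                reflected = reflect)
}

#' Young's modulus from Hooke's law over a strain window
#'
#' Zero-intercept least-squares slope of stress vs strain over the window
#' (default 0.3 to 3 percent strain): `E = sum(sigma * eps) / sum(eps^2)`.
#' The reflected smoothing already forces the curve through the origin, so
#' the intercept is fixed at zero.
#'
#' @param curve a `stress_strain` (smoothed values are used if present).
#' @param fit_lo,fit_hi strain window, endpoints inclusive.
#' @return a [property_result] in GPa.
#' @export
youngs_modulus <- function(curve, fit_lo = 0.003, fit_hi = 0.03) {
  sig <- curve_stress(curve)
  sel <- curve$strain >= fit_lo & curve$strain <= fit_hi
  if (sum(sel) < 2L) stop("fewer than 2 points in the fit window")
  e <- curve$strain[sel]; s <- sig[sel]
  property_result("youngs_modulus", sum(s * e) / sum(e^2), "GPa",
                  provenance = list(fit_lo = fit_lo, fit_hi = fit_hi,
                                    n_points = sum(sel),
                                    smoothed = !is.null(curve$smoothed)))
}

#' Maximum tensile stress over a strain interval
#'
#' Largest smoothed stress on the closed interval (default 3 to 97 percent
#' strain); among equal maxima the smallest strain is reported.
#'
#' @param curve a `stress_strain` (smoothed values are used if present).
#' @param lo,hi strain interval, endpoints inclusive.
#' @return a [property_result] in GPa with `strain_at_max` in provenance.
#' @export
max_stress <- function(curve, lo = 0.03, hi = 0.97) {
  sig <- curve_stress(curve)
  sel <- which(curve$strain >= lo & curve$strain <= hi)
  if (length(sel) == 0L) stop("no points in the interval")
  i <- sel[which.max(sig[sel])]   # which.max returns the first (smallest strain)
  property_result("max_stress", sig[i], "GPa",
                  provenance = list(lo = lo, hi = hi,
                                    strain_at_max = curve$strain[i]))
}

#' Poisson's ratio from the transverse box response
#'
#' Transverse strain is computed from each transverse box length relative to
#' its value at zero axial strain; nu is the negated ordinary least-squares
#' slope of (mean) transverse strain vs axial strain over the window
#' (default 1 to 2 percent axial strain).
#'
#' @param deformation a [ts_table] with columns `strain` (axial) and one or
#'   two transverse length columns (names starting `L_trans`); a single
#'   transverse direction is accepted with a warning.
#' @param fit_lo,fit_hi axial-strain window, endpoints inclusive.
#' @return a [property_result] (dimensionless).
#' @export
poisson_ratio <- function(deformation, fit_lo = 0.01, fit_hi = 0.02) {
  tcols <- grep("^L_trans", names(deformation), value = TRUE)
  if (length(tcols) == 0L) stop("no transverse length columns (L_trans*)")
  if (length(tcols) == 1L)
    warning("single transverse direction supplied; assuming the coupled direction is equal")
  eps_a <- deformation[[1L]]
  i0 <- which(abs(eps_a) < 1e-12)
  if (length(i0) == 0L) {
    warning("no zero-axial-strain record; using the first record as transverse reference")
    i0 <- 1L
  }
  eps_t <- rowMeans(vapply(tcols, function(cn) {
    L <- deformation[[cn]]
    (L - L[i0[1L]]) / L[i0[1L]]
  }, numeric(nrow(deformation))))
  sel <- eps_a >= fit_lo & eps_a <= fit_hi
  if (sum(sel) < 2L) stop("fewer than 2 points in the fit window")
  slope <- stats::cov(eps_a[sel], eps_t[sel]) / stats::var(eps_a[sel])
  property_result("poisson_ratio", -slope, "dimensionless",
                  provenance = list(fit_lo = fit_lo, fit_hi = fit_hi,
                                    n_points = sum(sel),
                                    n_transverse = length(tcols)))
}

#' Bulk modulus from Lame's relation
#'
#' `K = E / (3 (1 - 2 nu))` (GPa). Near nu = 0.5 the denominator vanishes
#' and K diverges; within `tol` of that point the result is flagged
#' near-incompressible and the value withheld (`NA`) rather than reported as
#' a bare number.
#'
#' @param E Young's modulus (GPa), >= 0 (a [property_result] or numeric).
#' @param nu Poisson's ratio, <= 0.5 (a [property_result] or numeric).
#' @param tol near-incompressibility tolerance on `|1 - 2 nu|`.
#' @return a [property_result] in GPa; flagged via provenance `flag` when
#'   near-incompressible.
#' @export
bulk_modulus <- function(E, nu, tol = 1e-3) {
  if (inherits(E, "property_result")) E <- E$value
  if (inherits(nu, "property_result")) nu <- nu$value
  if (E < 0) stop("E must be non-negative")
  if (nu > 0.5) stop("nu > 0.5 is non-physical for Lame's relation")
  den <- 1 - 2 * nu
  if (abs(den) < tol)
    return(property_result("bulk_modulus", NA_real_, "GPa",
                           provenance = list(E_GPa = E, nu = nu,
                                             flag = "near-incompressible: K unreliable")))
  property_result("bulk_modulus", E / (3 * den), "GPa",
                  provenance = list(E_GPa = E, nu = nu))
}

#' Elastic-constant set for one deformation direction
#'
#' @param E,sigma_max,nu,K numeric scalars ([property_result]s accepted).
#' @param direction label ("x", "y" or "z").
#' @return an object of class `elastic_constants`.
#' @export
elastic_constants <- function(E, sigma_max, nu, K, direction = NA_character_) {
  val <- function(v) if (inherits(v, "property_result")) v$value else as.numeric(v)
  structure(list(E = val(E), sigma_max = val(sigma_max), nu = val(nu),
                 K = val(K), direction = direction),
            class = "elastic_constants")
}

#' Aggregate elastic constants over the three deformation directions
#'
#' Deformation runs repeated in x, y and z from the same initial
#' configuration give an error estimate: per constant, the mean and the
#' population standard deviation across the three directions.
#'
#' @param constants list of exactly 3 `elastic_constants`.
#' @return list of class `elastic_aggregate` with per-constant `mean` and
#'   `sd` plus the per-direction values.
#' @export
aggregate_directions <- function(constants) {
  if (length(constants) != 3L)
    stop("exactly 3 per-direction inputs required")
  stopifnot(all(vapply(constants, inherits, logical(1), "elastic_constants")))
  fields <- c("E", "sigma_max", "nu", "K")
  agg <- lapply(fields, function(f) {
    v <- vapply(constants, `[[`, numeric(1), f)
    list(mean = mean(v), sd = pop_sd(v), values = v)
  })
  names(agg) <- fields
  structure(list(per_direction = constants, aggregate = agg),
            class = "elastic_aggregate")
}

#' @export
print.elastic_aggregate <- function(x, ...) {
  for (f in names(x$aggregate))
    cat(sprintf("%-10s %.4g +/- %.4g\n", f, x$aggregate[[f]]$mean,
                x$aggregate[[f]]$sd))
  invisible(x)
}

#' Energy-term deltas relative to the undeformed state
#'
#' Subtracts the first-row value from every term column, giving `E - E0` per
#' energy contribution as a function of strain; the first output row is all
#' zeros.
#'
#' @param energies a [ts_table] whose first column is strain and remaining
#'   columns are energy terms (kJ/mol).
#' @return a [ts_table] of the same shape with differenced term columns.
#' @export
delta_energy <- function(energies) {
  df <- as.data.frame(energies)
  for (j in seq_along(df)[-1L]) df[[j]] <- df[[j]] - df[[j]][1L]
  ts_table(df, attr(energies, "units"))
}
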