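#' Unwrapped displacement trajectory
#'
#' Positions per particle per frame, already unwrapped (no periodic jumps),
#' with strictly increasing frame times. Stored as an array
#' `frames x particles x 3` (nm).
#'
#' @param pos numeric array `n_frames x n_particles x 3` (nm), finite.
#' @param times frame times (ns), strictly increasing.
#' @param ids particle identifiers (default 1..n).
#' @param mol molecule/chain index per particle (for center-of-mass
#'   grouping), optional.
#' @param masses particle masses (amu), optional.
#' @return an object of class `displacement_traj`.
#' @export
displacement_traj <- function(pos, times, ids = NULL, mol = NULL,
                              masses = NULL) {
  stopifnot(length(dim(pos)) == 3L, dim(pos)[3L] == 3L,
            dim(pos)[1L] == length(times))
  if (!all(is.finite(pos))) stop("positions must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  n <- dim(pos)[2L]
  if (is.null(ids)) ids <- seq_len(n)
  structure(list(pos = pos, times = as.numeric(times), ids = ids,
                 mol = mol, masses = masses),
            class = "displacement_traj")
}

#' @export
print.displacement_traj <- function(x, ...) {
  cat(sprintf("displacement_traj: %d particles x %d frames (%.4g-%.4g ns)\n",
              dim(x$pos)[2L], dim(x$pos)[1L], min(x$times), max(x$times)))
  invisible(x)
}

#' Unwrap periodically wrapped coordinates
#'
#' Accumulates minimum-image per-step displacements, valid when no particle
#' moves half a box edge or more between consecutive frames (a step of
#' exactly half a box is ambiguous and raises an error).
#'
#' @param pos wrapped positions, array `n_frames x n_particles x 3` (nm).
#' @param box orthorhombic box edges (nm) (constant across frames).
#' @param times frame times (ns).
#' @param ... passed to [displacement_traj].
#' @return a `displacement_traj` with unwrapped coordinates.
#' @export
unwrap_trajectory <- function(pos, box, times, ...) {
  stopifnot(length(dim(pos)) == 3L, dim(pos)[3L] == 3L, length(box) == 3L)
  out <- pos
  nf <- dim(pos)[1L]
  if (nf > 1L) {
    for (f in 2:nf) {
      d <- pos[f, , , drop = FALSE] - pos[f - 1L, , , drop = FALSE]
      for (k in 1:3) {
        dk <- d[1L, , k]
        dk <- dk - box[k] * round(dk / box[k])
        if (any(abs(dk) >= box[k] / 2 * (1 - 1e-12)))
          stop("sampling too coarse to unwrap")
        d[1L, , k] <- dk
      }
      out[f, , ] <- out[f - 1L, , ] + d[1L, , ]
    }
  }
  displacement_traj(out, times, ...)
}

#' Center-of-mass trajectory per molecule
#'
#' Mass-weighted center of each molecule/chain per frame.
#'
#' @param traj a `displacement_traj` with `mol` set (or supplied here).
#' @param mol molecule index per particle (overrides `traj$mol`).
#' @param masses particle masses (overrides `traj$masses`; default: unit
#'   masses).
#' @return a `displacement_traj` with one particle per molecule, in order of
#'   sorted unique molecule index.
#' @export
com_series <- function(traj, mol = NULL, masses = NULL) {
  if (is.null(mol)) mol <- traj$mol
  if (is.null(mol)) stop("molecule grouping required")
  if (is.null(masses)) masses <- traj$masses
  n <- dim(traj$pos)[2L]
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(mol) == n, length(masses) == n)
  groups <- sort(unique(mol))
  tot <- vapply(groups, function(g) sum(masses[mol == g]), numeric(1))
  if (any(tot <= 0)) stop("group with zero total mass")
  nf <- dim(traj$pos)[1L]
  out <- array(0, dim = c(nf, length(groups), 3L))
  for (gi in seq_along(groups)) {
    sel <- which(mol == groups[gi])
    w <- masses[sel] / tot[gi]
    for (k in 1:3)
      out[, gi, k] <- matrix(traj$pos[, sel, k], nrow = nf) %*% w
  }
  displacement_traj(out, traj$times, ids = groups)
}

## multi-origin MSD of one scalar coordinate series via FFT autocorrelation;
## returns the length-N vector of mean squared displacements per lag
msd_fft_1d <- function(x) {
  N <- length(x)
  nfft <- 2^ceiling(log2(2L * N))
  fx <- stats::fft(c(x, rep(0, nfft - N)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(N)] / nfft
  d <- x^2
  q <- 2 * sum(d)
  s1 <- numeric(N)
  for (m in 0:(N - 1L)) {
    if (m > 0L) q <- q - d[m] - d[N + 1L - m]
    s1[m + 1L] <- q / (N - m)
  }
  s1 - 2 * s2 / (N - 0:(N - 1L))
}

#' Mean-square displacement
#'
#' MSD per lag time, averaged over particles and, by default, over all
#' valid time origins (computed with the FFT autocorrelation algorithm);
#' `origins = "single"` uses only the first frame as origin.
#'
#' @param traj a `displacement_traj` with at least 2 frames and uniform
#'   frame spacing (required for the multi-origin average).
#' @param origins `"multiple"` (default) or `"single"`.
#' @return a [ts_table] (lag time ns, msd nm2); MSD(0) = 0.
#' @export
msd <- function(traj, origins = c("multiple", "single")) {
  origins <- match.arg(origins)
  nf <- dim(traj$pos)[1L]
  if (nf < 2L) stop("need at least 2 frames")
  np <- dim(traj$pos)[2L]
  lags <- traj$times - traj$times[1L]
  if (origins == "multiple") {
    dts <- diff(traj$times)
    if (max(dts) - min(dts) > 1e-9 * max(dts))
      stop("multi-origin MSD requires uniform frame spacing")
    acc <- numeric(nf)
    for (p in seq_len(np))
      for (k in 1:3) acc <- acc + msd_fft_1d(traj$pos[, p, k])
    m <- acc / np
  } else {
    disp2 <- (traj$pos - traj$pos[rep(1L, nf), , , drop = FALSE])^2
    m <- apply(disp2, 1L, sum) / np
  }
  m[1L] <- 0
  m <- pmax(m, 0)   # guard tiny negative FFT round-off
  ts_table(data.frame(time = lags, msd = m), units = c("ns", "nm^2"))
}

ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Diffusion coefficient from the linear part of an MSD curve
#'
#' Einstein relation in 3D: `D = slope / 6` of an ordinary least-squares
#' line (free intercept) fitted to MSD vs lag time restricted to the
#' fractional window of the trace (default 0.1 to 0.9, reproducing a 1-9 ns
#' fit on a 10 ns trace). Reported in cm2/s (1 nm2/ns = 1e-5 cm2/s). The
#' error is the split-half estimate: the absolute difference between D
#' fitted on the first and on the second half of the window.
#'
#' @param msd_tab a [ts_table] (lag ns, msd nm2).
#' @param window fraction pair of the maximum lag, default `c(0.1, 0.9)`.
#' @return a [property_result] in cm2/s; a negative fitted slope is flagged
#'   `non-diffusive` in provenance.
#' @export
diffusivity_from_msd <- function(msd_tab, window = c(0.1, 0.9)) {
  t <- msd_tab[[1L]]; m <- msd_tab[[2L]]
  tmax <- max(t)
  lo <- window[1L] * tmax; hi <- window[2L] * tmax
  sel <- t >= lo & t <= hi
  if (sum(sel) < 4L) stop("fewer than 4 points in the fit window")
  to_cm2s <- 1e-5
  dfit <- function(s) ols_slope(t[s], m[s]) / 6 * to_cm2s
  D <- dfit(sel)
  mid <- (lo + hi) / 2
  h1 <- sel & t <= mid
  h2 <- sel & t >= mid
  err <- if (sum(h1) >= 2L && sum(h2) >= 2L) abs(dfit(h1) - dfit(h2))
         else NA_real_
  prov <- list(window = window, n_points = sum(sel))
  if (D < 0) prov$flag <- "non-diffusive"
  property_result("diffusivity", D, "cm^2/s", error = err, provenance = prov)
}

#' Per-chain diffusivity with across-chain error
#'
#' Computes D for each chain separately (multi-origin MSD of the chain's
#' center-of-mass track, same fractional fit window) and reports the mean
#' with the population standard deviation across chains as the error.
#'
#' @param com a `displacement_traj` of chain centers (>= 2 chains), e.g.
#'   from [com_series].
#' @param window fraction pair, as in [diffusivity_from_msd].
#' @return a [property_result] in cm2/s with per-chain values in
#'   provenance.
#' @export
per_chain_diffusivity <- function(com, window = c(0.1, 0.9)) {
  nc <- dim(com$pos)[2L]
  if (nc < 2L)
    stop("need at least 2 chains; use diffusivity_from_msd for a single track")
  Ds <- vapply(seq_len(nc), function(p) {
    one <- displacement_traj(com$pos[, p, , drop = FALSE], com$times)
    diffusivity_from_msd(msd(one), window)$value
  }, numeric(1))
  property_result("diffusivity_per_chain", mean(Ds), "cm^2/s",
                  error = pop_sd(Ds),
                  provenance = list(n_chains = nc, window = window,
                                    per_chain = Ds))
}
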