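#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond exists when the donor-oxygen to acceptor-oxygen
#' minimum-image distance is strictly below `r_max` and the angle at the
#' donor oxygen between its hydrogen and the acceptor oxygen is strictly
#' below `theta_max`. Boundary values are excluded.
#'
#' @param r_max O-O distance threshold (nm), default 0.35.
#' @param theta_max hydrogen - donor oxygen - acceptor oxygen angle
#'   threshold (degrees), default 30.
#' @return an object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(r_max = 0.35, theta_max = 30) {
  stopifnot(r_max > 0, theta_max > 0, theta_max < 180)
  structure(list(r_max = r_max, theta_max = theta_max),
            class = "hbond_criterion")
}

water_resnames_default <- c("SOL", "HOH", "WAT", "TIP3", "SPC")

## donor O-H pairs: oxygens (matching donor_pattern) with a hydrogen of the
## same molecule within bond_cutoff (min-image)
find_donor_pairs <- function(frame, donor_pattern, h_pattern, bond_cutoff,
                             require_h = FALSE) {
  a <- frame$atoms
  pos <- frame_positions(frame)
  oi <- which(a$element == "O" & grepl(donor_pattern, a$name))
  hi <- which(a$element == "H" & grepl(h_pattern, a$name))
  pairs <- NULL
  orphan <- character(0)
  for (i in oi) {
    hh <- hi[a$mol[hi] == a$mol[i]]
    if (length(hh)) {
      d2 <- rowSums(min_image(pos[hh, , drop = FALSE] -
                                matrix(pos[i, ], length(hh), 3L, byrow = TRUE),
                              frame$box)^2)
      hh <- hh[d2 < bond_cutoff^2]
    }
    if (length(hh) == 0L) {
      orphan <- c(orphan, a$name[i])
    } else {
      pairs <- rbind(pairs, cbind(donor = i, hydrogen = hh))
    }
  }
  if (require_h && length(orphan))
    stop("donor oxygen without attached hydrogen: ",
         paste(orphan, collapse = ", "))
  pairs
}

#' Detect hydrogen bonds in a configuration frame
#'
#' Donors are oxygens with an attached hydrogen (same molecule, within
#' `bond_cutoff`), acceptors all oxygens matching `acceptor_pattern`; both
#' selections are configurable atom-name regexes. Distances and the angle at
#' the donor oxygen use the minimum-image convention.
#'
#' @param frame a [config_frame].
#' @param criterion an [hbond_criterion].
#' @param donor_pattern,acceptor_pattern,h_pattern regexes on atom names
#'   (defaults select every O as donor candidate / acceptor, every H as
#'   hydrogen).
#' @param bond_cutoff covalent O-H cutoff (nm).
#' @param require_h if `TRUE`, a donor-pattern oxygen with no attached
#'   hydrogen is an error (use with explicit donor selections).
#' @return data.frame with one row per bond: indices `donor`, `hydrogen`,
#'   `acceptor`, plus `distance` (nm) and `angle` (degrees).
#' @export
detect_hbonds <- function(frame, criterion = hbond_criterion(),
                          donor_pattern = "", acceptor_pattern = "",
                          h_pattern = "", bond_cutoff = 0.12,
                          require_h = FALSE) {
  a <- frame$atoms
  pos <- frame_positions(frame)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (nrow(a) == 0L) return(empty)
  pairs <- find_donor_pairs(frame, donor_pattern, h_pattern, bond_cutoff,
                            require_h)
  acc <- which(a$element == "O" & grepl(acceptor_pattern, a$name))
  if (is.null(pairs) || length(acc) == 0L) return(empty)
  out <- empty
  for (r in seq_len(nrow(pairs))) {
    di <- pairs[r, "donor"]; hy <- pairs[r, "hydrogen"]
    aa <- acc[acc != di]
    if (length(aa) == 0L) next
    doa <- min_image(pos[aa, , drop = FALSE] -
                       matrix(pos[di, ], length(aa), 3L, byrow = TRUE),
                     frame$box)
    dist <- sqrt(rowSums(doa^2))
    doh <- min_image(matrix(pos[hy, ] - pos[di, ], 1L, 3L), frame$box)
    cosang <- (doa %*% t(doh)) / (dist * sqrt(sum(doh^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- dist < criterion$r_max & ang < criterion$theta_max
    if (any(hit))
      out <- rbind(out, data.frame(donor = di, hydrogen = hy,
                                   acceptor = aa[hit],
                                   distance = dist[hit], angle = ang[hit]))
  }
  rownames(out) <- NULL
  out
}

#' Bond-event matrix
#'
#' Indicator values (0/1) per bond per frame with strictly increasing frame
#' times, bond identities and interaction-group labels.
#'
#' @param matrix integer 0/1 matrix, bonds x frames.
#' @param times frame times (ns), strictly increasing.
#' @param bonds data.frame of bond identities (donor, hydrogen, acceptor).
#' @param groups character vector of group labels per bond
#'   (e.g. polymer-polymer / polymer-water / water-water).
#' @return an object of class `bond_events`.
#' @export
bond_events <- function(matrix, times, bonds = NULL, groups = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (!all(matrix %in% c(0L, 1L))) stop("indicator values must be 0/1")
  if (length(times) != ncol(matrix)) stop("times must match frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(groups)) groups <- rep("all", nrow(matrix))
  structure(list(matrix = matrix, times = as.numeric(times), bonds = bonds,
                 groups = groups), class = "bond_events")
}

#' @export
print.bond_events <- function(x, ...) {
  cat(sprintf("bond_events: %d bonds x %d frames (%.4g-%.4g ns)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$times), max(x$times)))
  invisible(x)
}

classify_group <- function(frame, i, j, water_resnames) {
  wi <- frame$atoms$resname[i] %in% water_resnames
  wj <- frame$atoms$resname[j] %in% water_resnames
  if (wi && wj) "water-water"
  else if (!wi && !wj) "polymer-polymer"
  else "polymer-water"
}

#' Track hydrogen bonds across frames
#'
#' Detects bonds in every frame; the bond universe is the union of bonds
#' ever observed, and each bond gets a 0/1 indicator per frame. Group labels
#' (polymer-polymer / polymer-water / water-water) are assigned from residue
#' names.
#'
#' @param frames list of [config_frame]s with consistent atom ordering.
#' @param times frame times (ns); defaults to 0, 1, 2, ... frame index.
#' @param criterion an [hbond_criterion].
#' @param water_resnames residue names treated as water.
#' @param ... passed to [detect_hbonds].
#' @return a [bond_events] object.
#' @export
track_bonds <- function(frames, times = NULL,
                        criterion = hbond_criterion(),
                        water_resnames = water_resnames_default, ...) {
  n_at <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n_at)) != 1L)
    stop("atom-count mismatch between frames")
  if (is.null(times)) times <- seq_along(frames) - 1
  per <- lapply(frames, detect_hbonds, criterion = criterion, ...)
  keys <- lapply(per, function(b) paste(b$donor, b$hydrogen, b$acceptor))
  universe <- unique(unlist(keys))
  h <- matrix(0L, length(universe), length(frames))
  for (f in seq_along(frames))
    h[match(keys[[f]], universe), f] <- 1L
  ids <- do.call(rbind, strsplit(universe, " "))
  bonds <- if (length(universe))
    data.frame(donor = as.integer(ids[, 1]), hydrogen = as.integer(ids[, 2]),
               acceptor = as.integer(ids[, 3]))
  else data.frame(donor = integer(0), hydrogen = integer(0),
                  acceptor = integer(0))
  groups <- if (length(universe))
    mapply(classify_group, i = bonds$donor, j = bonds$acceptor,
           MoreArgs = list(frame = frames[[1L]],
                           water_resnames = water_resnames))
  else character(0)
  bond_events(h, times, bonds, groups)
}

#' Hydrogen bonds per monomer
#'
#' Average bond count per frame divided by the number of monomers, the
#' normalization used when comparing systems of different size.
#'
#' @param events a [bond_events].
#' @param n_monomers monomer count, > 0.
#' @return bonds per monomer (numeric scalar).
#' @export
bonds_per_monomer <- function(events, n_monomers) {
  stopifnot(n_monomers > 0)
  mean(colSums(events$matrix)) / n_monomers
}

#' Intermittent hydrogen-bond existence function
#'
#' Multi-origin intermittent autocorrelation of the bond indicator:
#' `C(t) = sum_origins sum_bonds h(t0) h(t0+t) / sum_origins sum_bonds
#' h(t0)^2`, with origins restricted to those for which `t0 + t` is inside
#' the series. A bond that breaks and later reforms contributes again
#' (intermittent, not continuous, convention). C(0) = 1 whenever any bond
#' exists.
#'
#' @param events a [bond_events] with at least 2 frames.
#' @return a [ts_table] (time ns, C_HB).
#' @export
existence_function <- function(events) {
  h <- events$matrix
  nf <- ncol(h)
  if (nf < 2L) stop("need at least 2 frames")
  cs <- colSums(h)
  if (sum(cs) == 0) stop("empty bond population")
  hm <- h
  storage.mode(hm) <- "double"
  M <- crossprod(hm)                       # M[i, j] = sum_b h(t_i) h(t_j)
  num <- vapply(0:(nf - 1L), function(lag)
    sum(M[cbind(seq_len(nf - lag), seq_len(nf - lag) + lag)]), numeric(1))
  den <- rev(cumsum(cs))                   # den[lag+1] = sum(cs[1:(nf-lag)])
  if (any(den == 0)) stop("empty bond population")
  ts_table(data.frame(time = events$times - events$times[1L],
                      C_HB = num / den),
           units = c("ns", "dimensionless"))
}

#' Bi-exponential fit of the existence function
#'
#' Bounded nonlinear least squares of
#' `C(t) = K1 exp(-t/tau1) + K2 exp(-t/tau2)` with `K1, K2 >= 0` and
#' `tau1, tau2 > 0`, using Levenberg-Marquardt with a deterministic
#' multi-start grid of timescale initializations. The component with the
#' smaller tau is reported first.
#'
#' @param c_tab a [ts_table] (time ns, C) with at least 8 points and values
#'   in `[0, 1 + tol]`.
#' @param tol upper tolerance on C values.
#' @return an object of class `decay_fit`: `K1`, `tau1`, `K2`, `tau2`,
#'   residual norm, `converged` flag and `flags`.
#' @export
fit_decay <- function(c_tab, tol = 1e-6) {
  t <- c_tab[[1L]]; cc <- c_tab[[2L]]
  if (length(t) < 8L) stop("need at least 8 points")
  if (any(cc < -tol) || any(cc > 1 + tol))
    stop("C values outside [0, 1]")
  span <- max(t) - min(t)
  flags <- character(0)
  if (max(cc) - min(cc) < 1e-9) {
    ## no decay at all: tau -> infinity, nothing to fit
    return(structure(list(K1 = mean(cc), tau1 = Inf, K2 = 0, tau2 = Inf,
                          resid_norm = 0, converged = FALSE,
                          flags = "no decay: tau unbounded"),
                     class = "decay_fit"))
  }
  ## bounded Levenberg-Marquardt on the residual function directly (robust
  ## to the singular Jacobian of the tau1 = tau2 degenerate optimum)
  biexp_resid <- function(p) {
    p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) - cc
  }
  run_lm <- function(par, resid_fn, lower, upper) {
    r <- tryCatch(
      minpack.lm::nls.lm(par, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    list(par = r$par, rn = sqrt(sum(r$fvec^2)), conv = r$info %in% 1:4)
  }
  best <- NULL
  starts <- expand.grid(tau1 = span * c(0.02, 0.1, 0.5),
                        tau2 = span * c(0.5, 2, 10))
  starts <- starts[starts$tau2 > starts$tau1, , drop = FALSE]
  c0 <- max(cc[1L], 0.1)
  for (s in seq_len(nrow(starts))) {
    fit <- run_lm(c(K1 = c0 / 2, tau1 = starts$tau1[s],
                    K2 = c0 / 2, tau2 = starts$tau2[s]),
                  biexp_resid,
                  lower = c(0, 1e-9, 0, 1e-9),
                  upper = c(2, 1e6 * span, 2, 1e6 * span))
    if (is.null(fit)) next
    if (is.null(best) || fit$rn < best$rn)
      best <- list(rn = fit$rn, par = fit$par, conv = fit$conv)
  }
  if (is.null(best))
    return(structure(list(K1 = NA_real_, tau1 = NA_real_, K2 = NA_real_,
                          tau2 = NA_real_, resid_norm = NA_real_,
                          converged = FALSE, flags = "no start converged"),
                     class = "decay_fit"))
  p <- best$par
  if (p[["tau1"]] > p[["tau2"]])
    p <- c(K1 = p[["K2"]], tau1 = p[["tau2"]], K2 = p[["K1"]],
           tau2 = p[["tau1"]])
  ## model reduction: a component carrying < 1% of the weight with a
  ## timescale beyond the observation span is unidentifiable from the data
  ## (it is indistinguishable from a constant offset) and would dominate the
  ## extrapolated integral; drop it and refit a single exponential.
  drop2 <- p[["K2"]] < 0.01 && p[["tau2"]] > span
  drop1 <- p[["K1"]] < 0.01 && p[["tau1"]] > span
  if (drop1 || drop2) {
    keep_tau <- if (drop2) p[["tau1"]] else p[["tau2"]]
    fit1 <- run_lm(c(K = c0, tau = keep_tau),
                   function(q) q[1] * exp(-t / q[2]) - cc,
                   lower = c(0, 1e-9), upper = c(2, 1e6 * span))
    if (!is.null(fit1)) {
      p <- c(K1 = unname(fit1$par[["K"]]), tau1 = unname(fit1$par[["tau"]]),
             K2 = 0, tau2 = unname(fit1$par[["tau"]]))
      best$rn <- fit1$rn
      best$conv <- fit1$conv
      flags <- c(flags, "reduced to single exponential")
    }
  }
  if (max(p[["tau1"]], p[["tau2"]]) > 1e5 * span)
    flags <- c(flags, "tau at bound: extrapolation unreliable")
  structure(list(K1 = unname(p[["K1"]]), tau1 = unname(p[["tau1"]]),
                 K2 = unname(p[["K2"]]), tau2 = unname(p[["tau2"]]),
                 resid_norm = best$rn,
                 converged = isTRUE(best$conv) &&
                   !any(grepl("tau at bound", flags)),
                 flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: K1=%.4g tau1=%.4g ns, K2=%.4g tau2=%.4g ns (%s)\n",
              x$K1, x$tau1, x$K2, x$tau2,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a fitted existence-function decay
#' @param fit a `decay_fit`.
#' @param t times (ns).
#' @return fitted C values.
#' @export
decay_value <- function(fit, t) {
  fit$K1 * exp(-t / fit$tau1) + fit$K2 * exp(-t / fit$tau2)
}

#' Hydrogen-bond lifetime and half-life from a fitted decay
#'
#' The lifetime extrapolates and integrates the fitted existence function to
#' zero: `integral_0^inf C_fit dt = K1 tau1 + K2 tau2` (ns). The half-life
#' is, by default, the time at which the fitted C crosses 0.5, found by
#' bracketed root-finding; the alternative `"integral"` convention instead
#' integrates C_fit from 0 until it first reaches 0.5. If `C_fit(0) < 0.5`
#' the half-life is 0 with a flag.
#'
#' @param fit a converged `decay_fit`.
#' @param halflife_convention `"crossing"` (default) or `"integral"`.
#' @return list with `lifetime` (ns), `half_life` (ns) and `flags`.
#' @export
lifetime_halflife <- function(fit,
                              halflife_convention = c("crossing", "integral")) {
  halflife_convention <- match.arg(halflife_convention)
  if (!isTRUE(fit$converged))
    stop("decay fit not converged; refusing lifetime extrapolation")
  lifetime <- fit$K1 * fit$tau1 + fit$K2 * fit$tau2
  flags <- character(0)
  c0 <- decay_value(fit, 0)
  if (c0 < 0.5) {
    half <- 0
    flags <- "C(0) < 0.5"
  } else {
    ## bracket the 0.5 crossing, then bisect via uniroot
    hi <- max(fit$tau1, fit$tau2)
    while (decay_value(fit, hi) > 0.5) hi <- hi * 2
    t_star <- stats::uniroot(function(tt) decay_value(fit, tt) - 0.5,
                             c(0, hi), tol = 1e-12)$root
    half <- if (halflife_convention == "crossing") t_star
    else {
      ## partial integral of C_fit from 0 to the 0.5 level
      fit$K1 * fit$tau1 * (1 - exp(-t_star / fit$tau1)) +
        fit$K2 * fit$tau2 * (1 - exp(-t_star / fit$tau2))
    }
  }
  list(lifetime = lifetime, half_life = half, flags = flags)
}
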