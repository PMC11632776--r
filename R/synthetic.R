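## Synthetic-data generators: every input class the pipeline consumes, with
## known ground-truth parameters, so each analysis stage is testable by
## parameter recovery without an MD engine. All generators are pure functions
## of their arguments: the same seed gives bit-identical output and the
## caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Synthetic specific-volume vs temperature curve (two-line hinge)
#'
#' Emulates the cooling-curve input to broken-stick Tg regression: below `tg`
#' the specific volume follows the glassy line, above it the rubbery line,
#' the two meeting at `(tg, v_at_tg)`. Independent Gaussian noise of sd
#' `noise_sd` (cm3/g) is added per point.
#'
#' @param tg hinge temperature (K).
#' @param slope_low glassy-branch slope, cm3/(g K); must be positive.
#' @param slope_high rubbery-branch slope, cm3/(g K); must exceed `slope_low`
#'   for an identifiable transition (equal slopes attach a warning flag).
#' @param v_at_tg specific volume at the hinge (cm3/g).
#' @param temps strictly increasing temperatures (K).
#' @param noise_sd Gaussian noise sd (cm3/g).
#' @param seed RNG seed.
#' @return a [vt_series] with attribute `truth` holding the generator
#'   parameters (and `flags` if the transition is unidentifiable).
#' @export
gen_vt_curve <- function(tg, slope_low, slope_high, v_at_tg, temps,
                         noise_sd = 0, seed = 1L) {
  stopifnot(slope_low > 0, slope_high >= slope_low, noise_sd >= 0,
            all(diff(temps) > 0))
  v <- ifelse(temps <= tg,
              v_at_tg + slope_low * (temps - tg),
              v_at_tg + slope_high * (temps - tg))
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(temps), 0, noise_sd))
  out <- vt_series(data.frame(temperature = temps, density = 1 / v))
  attr(out, "truth") <- list(tg = tg, slope_low = slope_low,
                             slope_high = slope_high, v_at_tg = v_at_tg,
                             noise_sd = noise_sd, seed = seed)
  if (slope_high == slope_low) attr(out, "flags") <- "Tg unidentifiable"
  out
}

#' Synthetic two-state hydrogen-bond event matrix
#'
#' Each bond evolves as a discrete-time two-state Markov chain with per-step
#' break probability `1 - exp(-k_break * dt)` and reform probability
#' `1 - exp(-k_reform * dt)`. All bonds start formed, so the existence
#' function is conditioned on an initial bond and C(0) = 1.
#'
#' @param n_bonds number of bonds.
#' @param n_frames number of frames (including t = 0).
#' @param dt frame spacing (ns).
#' @param k_break,k_reform rates (1/ns), both >= 0.
#' @param seed RNG seed.
#' @return a `bond_events` object (indicator matrix `n_bonds x n_frames`,
#'   frame times, bond metadata, group labels).
#' @export
gen_bond_events <- function(n_bonds, n_frames, dt, k_break, k_reform = 0,
                            seed = 1L) {
  stopifnot(n_bonds >= 1, n_frames >= 1, dt > 0, k_break >= 0, k_reform >= 0)
  p_break <- 1 - exp(-k_break * dt)
  p_reform <- 1 - exp(-k_reform * dt)
  h <- matrix(0L, n_bonds, n_frames)
  h[, 1L] <- 1L
  with_seed(seed, {
    for (f in seq_len(n_frames - 1L)) {
      cur <- h[, f]
      u <- stats::runif(n_bonds)
      h[, f + 1L] <- ifelse(cur == 1L,
                            as.integer(u >= p_break),
                            as.integer(u < p_reform))
    }
  })
  bond_events(h, times = (seq_len(n_frames) - 1L) * dt,
              bonds = data.frame(donor = paste0("D", seq_len(n_bonds)),
                                 hydrogen = paste0("H", seq_len(n_bonds)),
                                 acceptor = paste0("A", seq_len(n_bonds)),
                                 stringsAsFactors = FALSE),
              groups = rep("synthetic", n_bonds))
}

## C1 elastic-plastic knee: exactly linear below strain_yield, smooth
## exponential approach to the plateau above it.
knee_stress <- function(eps, E, eps_y, sigma_p) {
  sig_y <- E * eps_y
  out <- E * eps
  if (sigma_p > sig_y) {
    hi <- eps > eps_y
    out[hi] <- sigma_p - (sigma_p - sig_y) *
      exp(-E * (eps[hi] - eps_y) / (sigma_p - sig_y))
  } else {
    out <- pmin(out, sigma_p)
  }
  out
}

#' Synthetic stress-strain trace
#'
#' Noiseless stress is `E_true * strain` below the yield strain and bends
#' smoothly (C1) toward the plateau `sigma_plateau` above it; Gaussian noise
#' of sd `noise_sd` (GPa) is added. Only non-negative strains are emitted;
#' reflection around zero strain is the analyzer's job.
#'
#' @param E_true Young's modulus (GPa), >= 0.
#' @param strain_yield strain at the knee.
#' @param sigma_plateau plateau stress (GPa).
#' @param strains increasing strain grid in \[0, 1\].
#' @param noise_sd Gaussian noise sd (GPa).
#' @param seed RNG seed.
#' @return a [ts_table] (strain, stress) with attribute `truth`.
#' @export
gen_stress_strain <- function(E_true, strain_yield, sigma_plateau, strains,
                              noise_sd = 0, seed = 1L) {
  stopifnot(E_true >= 0, all(strains >= 0), all(strains <= 1),
            all(diff(strains) > 0), noise_sd >= 0)
  sig <- knee_stress(strains, E_true, strain_yield, sigma_plateau)
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(strains), 0, noise_sd))
  out <- ts_table(data.frame(strain = strains, stress = sig),
                  units = c("dimensionless", "GPa"))
  attr(out, "truth") <- list(E_true = E_true, strain_yield = strain_yield,
                             sigma_plateau = sigma_plateau,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic semi-isotropic box deformation
#'
#' Axial box length grows as `L0 * (1 + strain)`; both transverse directions
#' respond identically. In the default linear convention the transverse
#' strain is exactly `-nu_true * strain`; with `volume_preserving = TRUE` the
#' transverse lengths follow `L0 * (1 + strain)^(-1/2)` instead (an
#' incompressible finite-strain response, giving an apparent Poisson ratio
#' just below 0.5 over small strain windows).
#'
#' @param nu_true Poisson ratio in \[-1, 0.5\] (ignored when
#'   `volume_preserving`).
#' @param L0 initial box edge (nm).
#' @param strains increasing axial strain grid.
#' @param volume_preserving use the finite-strain incompressible variant.
#' @param noise_sd Gaussian noise sd on the transverse lengths (nm).
#' @param seed RNG seed.
#' @return a [ts_table] (strain, L_axial, L_trans_x, L_trans_y) with
#'   attribute `truth`.
#' @export
gen_box_deformation <- function(nu_true, L0, strains,
                                volume_preserving = FALSE,
                                noise_sd = 0, seed = 1L) {
  stopifnot(nu_true >= -1, nu_true <= 0.5, L0 > 0, all(diff(strains) > 0),
            noise_sd >= 0)
  lt <- if (volume_preserving) L0 * (1 + strains)^(-0.5)
        else L0 * (1 - nu_true * strains)
  if (noise_sd > 0) {
    eta <- with_seed(seed, stats::rnorm(2L * length(strains), 0, noise_sd))
    ltx <- lt + eta[seq_along(strains)]
    lty <- lt + eta[length(strains) + seq_along(strains)]
  } else {
    ltx <- lty <- lt
  }
  out <- ts_table(data.frame(strain = strains, L_axial = L0 * (1 + strains),
                             L_trans_x = ltx, L_trans_y = lty),
                  units = c("dimensionless", "nm", "nm", "nm"))
  attr(out, "truth") <- list(nu_true = nu_true, L0 = L0,
                             volume_preserving = volume_preserving,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic Brownian displacement trajectories
#'
#' Unwrapped random walks: each coordinate increment is Gaussian with
#' variance `2 * D_true * dt`, so the ensemble MSD is `6 * D_true * t`.
#'
#' @param D_true diffusion coefficient (nm2/ns), >= 0.
#' @param n_particles number of particles.
#' @param n_frames number of frames (including t = 0).
#' @param dt frame spacing (ns).
#' @param seed RNG seed.
#' @param origin common starting position (nm).
#' @return a `displacement_traj` with attribute `truth`.
#' @export
gen_random_walk <- function(D_true, n_particles, n_frames, dt, seed = 1L,
                            origin = c(0, 0, 0)) {
  stopifnot(D_true >= 0, n_particles >= 1, n_frames >= 1, dt > 0)
  pos <- array(0, dim = c(n_frames, n_particles, 3L))
  if (n_frames > 1L && D_true > 0) {
    inc <- with_seed(seed, stats::rnorm((n_frames - 1L) * n_particles * 3L,
                                        0, sqrt(2 * D_true * dt)))
    dim(inc) <- c(n_frames - 1L, n_particles, 3L)
    for (k in 1:3) pos[-1L, , k] <- apply(inc[, , k, drop = FALSE], 2L, cumsum)
  }
  for (k in 1:3) pos[, , k] <- pos[, , k] + origin[k]
  out <- displacement_traj(pos, times = (seq_len(n_frames) - 1L) * dt)
  attr(out, "truth") <- list(D_true = D_true, dt = dt, seed = seed)
  out
}

#' Synthetic non-overlapping periodic sphere packing
#'
#' Atom centers uniform in the box with pairwise minimum-image distance
#' >= `2 * radius`, placed by rejection sampling.
#'
#' @param n_atoms number of atoms.
#' @param radius hard-sphere radius (nm).
#' @param box three box edges (nm).
#' @param element element symbol used for every atom.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per atom.
#' @return a [config_frame].
#' @export
gen_packing <- function(n_atoms, radius, box, element = "C", seed = 1L,
                        max_tries = 10000L) {
  stopifnot(n_atoms >= 0, radius >= 0, length(box) == 3L, all(box > 0))
  pos <- matrix(numeric(0), 0L, 3L)
  if (n_atoms > 0L) with_seed(seed, {
    for (i in seq_len(n_atoms)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- stats::runif(3L) * box
        if (nrow(pos) == 0L) { ok <- TRUE; break }
        d <- min_image(sweep(pos, 2L, p), box)
        if (min(rowSums(d^2)) >= (2 * radius)^2) { ok <- TRUE; break }
      }
      if (!ok) stop("packing too dense")
      pos <- rbind(pos, p)
    }
  })
  config_frame(data.frame(element = rep(element, n_atoms),
                          name = rep(element, n_atoms),
                          resname = rep("PAK", n_atoms),
                          mol = seq_len(max(n_atoms, 0L)),
                          x = pos[, 1][seq_len(n_atoms)],
                          y = pos[, 2][seq_len(n_atoms)],
                          z = pos[, 3][seq_len(n_atoms)],
                          stringsAsFactors = FALSE)[seq_len(n_atoms), ],
               box)
}

#' Minimal donor/hydrogen/acceptor geometry
#'
#' Builds a frame with one donor oxygen (with its hydrogen) and one acceptor
#' oxygen: the O-O distance is `d_OO` and the hydrogen - donor oxygen -
#' acceptor oxygen angle is `theta` degrees. The donor sits at the box
#' center; the O-H bond length is 0.1 nm.
#'
#' @param d_OO donor-acceptor oxygen distance (nm), > 0.
#' @param theta H-O(donor)-O(acceptor) angle (degrees) in \[0, 180\].
#' @param box three box edges (nm).
#' @return a [config_frame] with atoms OD, HD (molecule 1) and OA
#'   (molecule 2).
#' @export
gen_hbond_geometry <- function(d_OO, theta, box = c(3, 3, 3)) {
  stopifnot(d_OO > 0, theta >= 0, theta <= 180, all(box > 0))
  ctr <- box / 2
  th <- theta * pi / 180
  od <- ctr
  oa <- ctr + c(d_OO, 0, 0)
  hd <- ctr + 0.1 * c(cos(th), sin(th), 0)
  config_frame(data.frame(element = c("O", "H", "O"),
                          name = c("OD", "HD", "OA"),
                          resname = c("POL", "POL", "POL"),
                          mol = c(1L, 1L, 2L),
                          x = c(od[1], hd[1], oa[1]),
                          y = c(od[2], hd[2], oa[2]),
                          z = c(od[3], hd[3], oa[3]),
                          stringsAsFactors = FALSE),
               box)
}
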