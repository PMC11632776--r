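## Default study conditions for the bundled "virtual material": an amorphous
## polymer emulated by the synthetic generators. See the methods vignette
## for the rationale behind each value.
virtual_material_defaults <- function() {
  list(
    thermal = list(tg = 400, slope_low = 1e-4, slope_high = 3e-4,
                   v_at_tg = 0.54, t_min = 150, t_max = 600, t_step = 25,
                   noise_sd = 5e-4, low_window = c(150, 275),
                   high_window = c(475, 600), alpha_t1 = 300, alpha_t2 = 325),
    hbond = list(n_bonds = 10000, n_frames = 401, dt = 0.01, k_break = 1,
                 k_reform = 0),
    mech = list(E_true = 3.0, strain_yield = 0.05, sigma_plateau = 0.25,
                n_points = 2000, strain_max = 1.0, noise_sd = 0.05,
                half_width = 0.025, nu_true = 0.3, L0 = 8,
                nu_noise_sd = 0, nu_points = 80, nu_strain_max = 0.04),
    freevol = list(n_atoms = 60, radius = 0.15, box = c(2.5, 2.5, 2.5),
                   probes = c(0.1, 0.05, 0.01), spacing = 0.02),
    diffusion = list(D_true = 0.1, n_particles = 100, n_frames = 1001,
                     dt = 0.01, n_chains = 30))
}

merge_config <- function(defaults, override) {
  for (sec in names(override)) {
    if (is.list(override[[sec]]) && sec %in% names(defaults))
      defaults[[sec]][names(override[[sec]])] <- override[[sec]]
    else defaults[[sec]] <- override[[sec]]
  }
  defaults
}

#' Serialize a displacement trajectory as a wide table
#' @param traj a `displacement_traj`.
#' @return a [ts_table] with time plus x/y/z columns per particle.
#' @export
traj_to_table <- function(traj) {
  np <- dim(traj$pos)[2L]
  df <- data.frame(t = traj$times)
  for (p in seq_len(np)) for (k in 1:3)
    df[[paste0(c("x", "y", "z")[k], p)]] <- traj$pos[, p, k]
  ts_table(df, units = c("ns", rep("nm", 3L * np)))
}

#' Rebuild a displacement trajectory from a wide table
#' @param tab a [ts_table] as written by [traj_to_table].
#' @return a `displacement_traj`.
#' @export
table_to_traj <- function(tab) {
  np <- (ncol(tab) - 1L) %/% 3L
  pos <- array(0, dim = c(nrow(tab), np, 3L))
  for (p in seq_len(np)) for (k in 1:3)
    pos[, p, k] <- tab[[1L + (p - 1L) * 3L + k]]
  displacement_traj(pos, tab[[1L]])
}

#' Run the full analysis pipeline on a synthetic virtual material
#'
#' Generates every input class with the synthetic-data module (cooling
#' curve, bond events, deformation runs in three directions, a sphere
#' packing, Brownian trajectories), runs every analysis stage on them, and
#' writes one results file per stage plus the resolved configuration into
#' `outdir`.
#'
#' @param seed master RNG seed; every generator seed derives from it.
#' @param outdir output directory (created if missing).
#' @param config named list overriding entries of the default virtual
#'   material configuration (see the methods vignette).
#' @return invisibly, a named list with every computed property.
#' @export
run_virtual_material <- function(seed = 1L, outdir = ".", config = list()) {
  cfg <- merge_config(virtual_material_defaults(), config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(seed) %% 100000L
  yaml::write_yaml(c(list(seed = seed), cfg),
                   file.path(outdir, "resolved_config.yaml"))
  out <- list()

  ## --- thermal: cooling curve -> Tg, alpha_V -------------------------------
  th <- cfg$thermal
  vt <- gen_vt_curve(th$tg, th$slope_low, th$slope_high, th$v_at_tg,
                     temps = seq(th$t_min, th$t_max, by = th$t_step),
                     noise_sd = th$noise_sd, seed = seed * 10L + 1L)
  tg <- broken_stick_tg(vt, th$low_window, th$high_window)
  alpha <- thermal_expansion(vt, th$alpha_t1, th$alpha_t2)
  write_table(ts_table(data.frame(temperature = vt$temperature,
                                  density = vt$density,
                                  specific_volume = vt$specific_volume),
                       units = c("K", "g/cm^3", "cm^3/g")),
              file.path(outdir, "cooling_curve.tsv"))
  write_results(list(
    property_result("tg", tg$tg, "K",
                    provenance = list(low_window = th$low_window,
                                      high_window = th$high_window)),
    alpha), file.path(outdir, "thermal_results.tsv"))
  out$tg <- tg
  out$alpha <- alpha

  ## --- hydrogen bonds: events -> C_HB -> decay fit -> lifetimes ------------
  hb <- cfg$hbond
  ev <- gen_bond_events(hb$n_bonds, hb$n_frames, hb$dt, hb$k_break,
                        hb$k_reform, seed = seed * 10L + 2L)
  chb <- existence_function(ev)
  fit <- fit_decay(chb)
  lt <- lifetime_halflife(fit)
  write_table(chb, file.path(outdir, "existence_function.tsv"))
  write_results(list(
    property_result("hbond_lifetime", lt$lifetime, "ns",
                    provenance = list(K1 = fit$K1, tau1 = fit$tau1,
                                      K2 = fit$K2, tau2 = fit$tau2)),
    property_result("hbond_half_life", lt$half_life, "ns")),
    file.path(outdir, "hbond_results.tsv"))
  out$hbond_fit <- fit
  out$hbond <- lt

  ## --- mechanics: three deformation directions -----------------------------
  me <- cfg$mech
  strains <- seq(0, me$strain_max, length.out = me$n_points)
  per_dir <- lapply(1:3, function(d) {
    ss <- gen_stress_strain(me$E_true, me$strain_yield, me$sigma_plateau,
                            strains, noise_sd = me$noise_sd,
                            seed = seed * 10L + 2L + d)
    curve <- smooth_reflect(stress_strain(ss$strain, ss$stress),
                            half_width = me$half_width)
    E <- youngs_modulus(curve)
    smax <- max_stress(curve)
    defo <- gen_box_deformation(me$nu_true, me$L0,
                                strains = seq(0, me$nu_strain_max,
                                              length.out = me$nu_points),
                                noise_sd = me$nu_noise_sd,
                                seed = seed * 10L + 5L + d)
    nu <- poisson_ratio(defo)
    K <- bulk_modulus(E, nu)
    write_table(ts_table(data.frame(strain = curve$strain,
                                    stress_raw = curve$stress,
                                    stress_smoothed = curve$smoothed),
                         units = c("dimensionless", "GPa", "GPa")),
                file.path(outdir, sprintf("stress_strain_%s.tsv",
                                          c("x", "y", "z")[d])))
    elastic_constants(E, smax, nu, K, direction = c("x", "y", "z")[d])
  })
  agg <- aggregate_directions(per_dir)
  mres <- lapply(names(agg$aggregate), function(f)
    property_result(f, agg$aggregate[[f]]$mean,
                    c(E = "GPa", sigma_max = "GPa",
                      nu = "dimensionless", K = "GPa")[[f]],
                    error = agg$aggregate[[f]]$sd,
                    provenance = list(directions = "x:y:z")))
  write_results(mres, file.path(outdir, "mech_results.tsv"))
  out$mech <- agg

  ## --- free volume ----------------------------------------------------------
  fv <- cfg$freevol
  pk <- gen_packing(fv$n_atoms, fv$radius, fv$box, seed = seed * 10L + 9L)
  spec <- probe_spec(fv$probes, fv$spacing)
  spec$radii[["C"]] <- fv$radius   # packing spheres carry their own radius
  write_frame(pk, file.path(outdir, "packing.gro"))
  fv_res <- lapply(fv$probes, function(pr) {
    r <- free_volume_fraction(pk, pr, spec)
    property_result(sprintf("free_volume_probe_%g", pr), r$value,
                    "dimensionless", provenance = r$provenance)
  })
  write_results(fv_res, file.path(outdir, "freevol_results.tsv"))
  out$free_volume <- fv_res

  ## --- diffusion -------------------------------------------------------------
  di <- cfg$diffusion
  walk <- gen_random_walk(di$D_true, di$n_particles, di$n_frames, di$dt,
                          seed = seed * 10L + 7L)
  mtab <- msd(walk)
  D <- diffusivity_from_msd(mtab)
  chains <- gen_random_walk(di$D_true, di$n_chains, di$n_frames, di$dt,
                            seed = seed * 10L + 8L)
  Dchain <- per_chain_diffusivity(chains)
  write_table(mtab, file.path(outdir, "msd.tsv"))
  write_results(list(D, Dchain), file.path(outdir, "diffusion_results.tsv"))
  out$diffusivity <- D
  out$diffusivity_per_chain <- Dchain

  invisible(out)
}
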