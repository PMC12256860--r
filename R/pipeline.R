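pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, render = FALSE, segment = FALSE,
                  stats = TRUE, spectrum = TRUE, rheology = TRUE,
                  morphotype = TRUE),
    membrane = list(gamma = 4e-5, kappa = 2e-19, eta = 1.0, d = 8e-8,
                    R_bar = 3.6e-6, T = 310.15, Sigma0 = 8e-9),
    activity = list(phi = 0.3, p_on = 1, f0 = 2.5e-12, Lambda0 = 5e-8,
                    omega_A = 50, rate_mode = "log_uniform_ensemble",
                    rate_span = c(5, 500), eta0 = 1e-3),
    sim = list(N = 2048L, n_frames = 10000L, dt = 5e-4, n_modes = NULL),
    optics = list(pixel_size = 5e-8, ring_sigma_px = 2, noise_sd = 0.02,
                  contrast = 0.5, background = 0.75, polarity = "dark",
                  margin_px = 12),
    spectrum = list(segment_length = 2048L),
    thresholds = list(contrast_min = 0.2, c_min = 0.95, Delta_max = 0.1,
                      k_hot = 2),
    report_format = "json"
  )
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown %s key(s): %s", path, paste(extra, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste(path, k, sep = "$"))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Merges a user configuration (an R list, or the path to a JSON file) over
#' the package defaults. Unknown keys are rejected before any computation.
#'
#' @param config List or JSON file path; \code{NULL} gives the defaults.
#' @return Resolved configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(pipeline_defaults(), config)
  cfg$sim$N <- as.integer(cfg$sim$N)
  cfg$sim$n_frames <- as.integer(cfg$sim$n_frames)
  if (is.null(cfg$sim$n_modes)) cfg$sim$n_modes <- cfg$sim$N %/% 2L
  structure(cfg, class = "pipeline_config")
}

#' Run the full flickering analysis pipeline
#'
#' Orchestrates simulate -> (render -> segment) -> stats -> spectrum ->
#' rheology -> morphotype on a single synthetic cell, with all randomness
#' derived from the root seed; a rerun with an identical configuration is
#' bit-identical. When \code{out_dir} is set, the resolved configuration,
#' per-site table, spectra and rheology tables and the report JSON are
#' written there.
#'
#' @param config As in \code{\link{pipeline_config}}.
#' @return An object of class \code{run_report}: per-cell summary (Sigma,
#'   2*Sigma, G_eff, phi_est, morphotype), fit parameters, stage outputs and
#'   provenance (version, seed).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  m <- do.call(membrane_params, cfg$membrane)
  a <- do.call(activity_params, cfg$activity)
  out <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir,
                                                 "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!cfg$stages$simulate) stop("pipeline requires the simulate stage")
  s <- withCallingHandlers(
    simulate_active_contour(m, a, N = cfg$sim$N, n_frames = cfg$sim$n_frames,
                            dt = cfg$sim$dt, n_modes = cfg$sim$n_modes,
                            seed = derive_seed(cfg$seed, 1L)),
    flicker_aliasing = function(w) invokeRestart("muffleWarning"))
  out$series <- s
  if (cfg$stages$render || cfg$stages$segment) {
    optics <- do.call(render_optics, cfg$optics)
    stack <- render_contour_frames(s, optics,
                                   seed = derive_seed(cfg$seed, 2L))
    out$stack <- stack
    if (cfg$stages$segment) {
      prof <- segment_stack(stack, N = cfg$sim$N,
                            polarity = cfg$optics$polarity)
      prof <- correct_drift(prof)
      s <- assemble_series(prof, dt = cfg$sim$dt,
                           pixel_size = cfg$optics$pixel_size)
      out$series_segmented <- s
    }
    if (!is.null(cfg$out_dir))
      write_image_stack(stack, file.path(cfg$out_dir, "frames.tif"))
  }
  report <- list(version = as.character(utils::packageVersion("flickering")),
                 seed = cfg$seed, N = cfg$sim$N, n_frames = cfg$sim$n_frames,
                 dt = cfg$sim$dt)
  Sigma2_ref <- .kB * m$T / m$G0
  if (cfg$stages$stats) {
    st <- flicker_stats(s, G0 = m$G0, T = m$T, Sigma2_ref = Sigma2_ref,
                        k_hot = cfg$thresholds$k_hot)
    out$stats <- st
    report$Sigma_nm <- sqrt(st$Sigma2) * 1e9
    report$two_Sigma_nm <- st$two_Sigma * 1e9
    report$G_eff_uN_per_m <- st$G_eff * 1e6
    report$phi_est <- st$phi_est
    report$Teff_mean_K <- mean(st$Teff_map)
    report$D_bar_m2_per_s <- st$D_bar
    if (!is.null(cfg$out_dir))
      utils::write.csv(data.frame(site = seq_along(st$sigma2),
                                  sigma2_m2 = st$sigma2,
                                  Teff_K = st$Teff_map, hot = st$hot_mask,
                                  D_m2_per_s = st$Dloc),
                       file.path(cfg$out_dir, "per_site_stats.csv"),
                       row.names = FALSE)
  }
  if (cfg$stages$spectrum) {
    sp <- compute_psd(s, segment_length = cfg$spectrum$segment_length)
    out$spectrum <- sp
    report$spectral_variance_m2 <- spectrum_integral(sp)
    if (!is.null(cfg$out_dir))
      utils::write.csv(data.frame(omega_rad_per_s = sp$omega,
                                  psd_m2_s = sp$psd),
                       file.path(cfg$out_dir, "spectrum.csv"),
                       row.names = FALSE)
  }
  if (cfg$stages$rheology) {
    rh <- gser_modulus(out$spectrum, L = s$L, T = m$T)
    out$rheology <- rh
    vc <- viscoelastic_ratio_and_crossovers(rh)
    report$omega_D_rad_per_s <- vc$omega_D
    report$omega_C_rad_per_s <- vc$omega_C
    frf <- tryCatch(fit_fractional_rigidity(rh, R = m$R_bar, T = m$T),
                    error = function(e) NULL)
    if (!is.null(frf)) {
      out$fractional_fit <- frf
      report$alpha <- frf$alpha
      report$G_gamma_uN_per_m <- frf$G_gamma * 1e6
      report$tau_D_s <- frf$tau_D
    }
    if (!is.null(cfg$out_dir))
      utils::write.csv(data.frame(omega_rad_per_s = rh$omega,
                                  G_prime_N_per_m = rh$G_prime,
                                  eta_eff_Pa_s = rh$eta_eff,
                                  ratio_per_s = rh$ratio),
                       file.path(cfg$out_dir, "rheology.csv"),
                       row.names = FALSE)
  }
  if (cfg$stages$morphotype) {
    mean_r <- s$R_bar + rowMeans(s$dh)
    contour <- structure(list(theta = 2 * pi * (seq_len(nrow(s$dh)) - 1) /
                                nrow(s$dh),
                              r = mean_r, contrast = 1, kind = "measured"),
                         class = "cell_contour")
    rec <- morphotype_record(contour)
    report$morphotype <- classify_morphotype(
      rec, contrast_min = cfg$thresholds$contrast_min,
      c_min = cfg$thresholds$c_min, Delta_max = cfg$thresholds$Delta_max)
    report$circularity <- rec$c
    report$Delta <- rec$Delta
  }
  if (!is.null(cfg$out_dir))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  structure(list(report = report, outputs = out, config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("Flickering pipeline report\n")
  cat(sprintf("  seed %s | N %d x %d frames, dt %.3g ms\n",
              r$seed, r$N, r$n_frames, r$dt * 1e3))
  if (!is.null(r$Sigma_nm))
    cat(sprintf("  Sigma %.3g nm (2*Sigma %.3g nm), G_eff %.3g uN/m, phi_est %.3f\n",
                r$Sigma_nm, r$two_Sigma_nm, r$G_eff_uN_per_m, r$phi_est))
  if (!is.null(r$omega_D_rad_per_s))
    cat(sprintf("  omega_D %.3g rad/s, alpha %.3g\n",
                r$omega_D_rad_per_s, if (is.null(r$alpha)) NA else r$alpha))
  if (!is.null(r$morphotype))
    cat(sprintf("  mean-shape morphotype: %s (c %.3f, Delta %.4f)\n",
                r$morphotype, r$circularity, r$Delta))
  invisible(x)
}
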