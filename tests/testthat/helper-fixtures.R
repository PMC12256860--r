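## Shared fixtures, built lazily and cached for the whole test session.
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

kB_ <- flickering::kB()

## --- parameter sets (study conditions) -------------------------------------

## healthy-discocyte defaults
fx_m <- function() membrane_params()

## bending-dominated membrane (gamma = 0): wide Zilman-Granek window
fx_m_bend <- function() membrane_params(gamma = 0, kappa = 2e-19, eta = 1.0)

## --- simulations ------------------------------------------------------------

## mid-size passive run with well-resolved mode rates (equipartition etc.)
fx_eq_sim <- function() fx("eq_sim", function() {
  suppressWarnings(simulate_passive_contour(fx_m(), N = 128, n_frames = 20000,
                                            dt = 5e-4, n_modes = 64,
                                            seed = 17))
})

## matched passive/active pair at moderate size (stats, ordering, maps)
fx_pass_mid <- function() fx("pass_mid", function() {
  suppressWarnings(simulate_passive_contour(fx_m(), N = 256, n_frames = 30000,
                                            dt = 5e-4, n_modes = 128,
                                            seed = 21))
})
fx_act_mid <- function() fx("act_mid", function() {
  suppressWarnings(simulate_active_contour(fx_m(), activity_params(phi = 0.3),
                                           N = 256, n_frames = 30000,
                                           dt = 5e-4, n_modes = 128,
                                           seed = 21))
})

## acceptance-scale bending-dominated passive run + spectrum
fx_bend_sp <- function() fx("bend_sp", function() {
  s <- suppressWarnings(simulate_passive_contour(fx_m_bend(), N = 512,
                                                 n_frames = 1e5, dt = 5e-4,
                                                 n_modes = 256, seed = 1))
  list(s = s, sp = compute_psd(s, segment_length = 8192))
})

## acceptance-scale kickers-only run (athermal membrane) + spectrum
fx_act_sp <- function() fx("act_sp", function() {
  m0 <- membrane_params(T = 0, G0 = kB_ * 310.15 / (8e-9)^2)
  s <- simulate_active_contour(m0, activity_params(phi = 0.3), N = 512,
                               n_frames = 1e5, dt = 5e-4, n_modes = 256,
                               seed = 1)
  list(s = s, sp = compute_psd(s, segment_length = 8192, msd_lags = 0))
})

## rendered stack of a passive run (round trips, segmentation accuracy);
## spatially oversampled (n_modes = N/4) so angular resampling is faithful
fx_render <- function() fx("render", function() {
  s <- suppressWarnings(simulate_passive_contour(membrane_params(gamma = 1e-5),
                                                 N = 128, n_frames = 400,
                                                 dt = 5e-4, n_modes = 32,
                                                 seed = 31))
  optics <- render_optics(pixel_size = 2e-8, noise_sd = 0.005)
  list(s = s, optics = optics,
       stack = render_contour_frames(s, optics, seed = 5))
})

## --- independent oracles ----------------------------------------------------

## brute-force Otsu: exhaustive between-class variance scan
brute_otsu <- function(x, levels = 65536L) {
  cand <- seq(0, 1, length.out = levels)
  bcv <- vapply(cand, function(t) {
    w0 <- mean(x < t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x < t]) - mean(x[x >= t]))^2
  }, 0)
  list(threshold = cand[which.max(bcv)], bcv = max(bcv),
       bcv_at = function(t) {
         w0 <- mean(x < t)
         if (w0 == 0 || w0 == 1) return(0)
         w0 * (1 - w0) * (mean(x[x < t]) - mean(x[x >= t]))^2
       })
}

## fine-grid arc-length quadrature of r(theta) = R(1 + a cos(m theta))
arclength_quadrature <- function(R, a, m, n = 2^17) {
  th <- 2 * pi * (0:(n - 1)) / n
  r <- R * (1 + a * cos(m * th))
  dr <- -R * a * m * sin(m * th)
  sum(sqrt(r^2 + dr^2)) * 2 * pi / n
}

## perimeter of an ellipse with semi-axes a >= b (complete elliptic integral)
ellipse_perimeter <- function(a, b) {
  4 * a * stats::integrate(function(t) sqrt(1 - (1 - (b / a)^2) * sin(t)^2),
                           0, pi / 2, rel.tol = 1e-12)$value
}

## clean morphotype fixture set with hand-assigned labels
morpho_fixture_set <- function() {
  specs <- list(
    list(shape_spec("circle"), "discocyte"),
    list(shape_spec("circle", R = 4e-6), "discocyte"),
    list(shape_spec("ellipse", axis_ratio = 0.97), "discocyte"),
    list(shape_spec("ellipse", axis_ratio = 0.90), "elliptocyte"),
    list(shape_spec("ellipse", axis_ratio = 0.80), "elliptocyte"),
    list(shape_spec("ellipse", axis_ratio = 0.60), "elliptocyte"),
    list(shape_spec("spiculated", lobes = 12, lobe_amplitude = 0.15),
         "echinocyte"),
    list(shape_spec("spiculated", lobes = 8, lobe_amplitude = 0.2),
         "echinocyte"),
    list(shape_spec("ghost", contrast = 0.05), "ghost"),
    list(shape_spec("ghost", contrast = 0.01), "ghost"))
  data.frame(idx = seq_along(specs),
             label = vapply(specs, `[[`, "", 2)) -> truth
  list(specs = lapply(specs, `[[`, 1), truth = truth)
}
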