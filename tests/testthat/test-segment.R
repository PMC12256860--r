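test_that("Otsu binarization maximizes between-class variance", {
  ## two separable levels: threshold falls strictly between them
  img <- matrix(10, 64, 64); img[, 33:64] <- 200
  mask <- denoise_binarize(img, sigma_px = 0.5)
  th <- attr(mask, "threshold")
  expect_gt(th, 10); expect_lt(th, 200)
  ## threshold matches the exhaustive between-class variance scan
  set.seed(3)
  img2 <- matrix(c(rnorm(5000, 0.25, 0.03), rnorm(5000, 0.7, 0.05)), 100, 100)
  mask2 <- denoise_binarize(img2, sigma_px = 0.5)
  sm <- as.matrix(EBImage::gblur(
    EBImage::Image((img2 - min(img2)) / diff(range(img2))), 0.5))
  oracle <- brute_otsu(as.numeric(sm))
  th2 <- (attr(mask2, "threshold") - min(img2)) / diff(range(img2))
  expect_gte(oracle$bcv_at(th2), oracle$bcv * (1 - 1e-6))
  expect_error(denoise_binarize(matrix(1, 8, 8)), "constant")
})

test_that("binarized disk area matches the geometric disk", {
  n <- 201; R <- 60
  xg <- (1:n) - 101; rho <- sqrt(outer(xg^2, xg^2, `+`))
  disk <- ifelse(rho < R, 0.2, 0.9)
  mask <- denoise_binarize(disk, sigma_px = 2)
  expect_lt(abs(sum(mask) / (pi * R^2) - 1), 0.01)
  expect_equal(unname(attr(mask, "centroid")), c(101, 101), tolerance = 1e-2)
})

test_that("subpixel ray segmentation locates the rendered ring", {
  ## noiseless circle, R = 50 px: mean radius error far below 0.2 px and
  ## per-ray profile minima within 0.1 px at 2 px blur
  circ <- generate_shape(shape_spec("circle", R = 50 * 5e-8), n = 256)
  st <- render_contour_frames(circ, render_optics(pixel_size = 5e-8,
                                                  ring_sigma_px = 2))
  r <- extract_contour(st$frames[[1]], st$optics$center, N = 256)
  expect_lt(abs(mean(r) - 50), 0.2)
  expect_lt(max(abs(r - 50)), 0.1)
  ## zero-noise circle frame is 4-fold symmetric
  f <- st$frames[[1]]
  expect_equal(f, f[nrow(f):1, ], tolerance = 1e-12)
  expect_equal(f, t(f), tolerance = 1e-12)
  ## ellipse: radii match the parametric polar radius function
  ell <- generate_shape(shape_spec("ellipse", R = 55 * 5e-8,
                                   axis_ratio = 0.9), n = 512)
  ste <- render_contour_frames(ell, render_optics(pixel_size = 5e-8))
  re <- extract_contour(ste$frames[[1]], ste$optics$center, N = 512)
  a <- 55; b <- 0.9 * 55
  th <- 2 * pi * (0:511) / 512
  r_true <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_lt(sqrt(mean((re - r_true)^2)), 0.2)
  ## translation covariance: integer-pixel shifted frame + shifted center
  f2 <- rbind(f[4:nrow(f), ], f[1:3, ])          # shift rows by -3
  r_ref <- extract_contour(f, st$optics$center, N = 256, r_range = c(40, 60))
  r_shift <- extract_contour(f2, st$optics$center - c(3, 0), N = 256,
                             r_range = c(40, 60))
  expect_equal(r_shift, r_ref, tolerance = 1e-12)
  expect_error(extract_contour(f, c(-5, 10)), "inside")
})

test_that("segmentation stays below 0.2 px RMS on noisy rendered stacks", {
  fr <- fx_render()
  frames100 <- fr$stack$frames[1:100]
  truth <- t(fr$s$R_bar + fr$s$dh[, 1:100]) / fr$optics$pixel_size
  r <- t(vapply(frames100, function(f)
    extract_contour(f, fr$stack$optics$center, N = 128), numeric(128)))
  expect_lt(sqrt(mean((r - truth)^2)), 0.2)
})

test_that("drift correction removes injected rigid motion", {
  theta <- 2 * pi * (0:255) / 256
  r0 <- 80 + 2 * cos(2 * theta) + 1.5 * sin(3 * theta) + cos(5 * theta)
  ## pure translation injected, then removed below 0.05 px
  drift <- cbind(seq(-2, 2, length.out = 30), seq(1.5, -1, length.out = 30))
  Rd <- t(sapply(1:30, function(t)
    flickering:::recenter_profile(r0, theta, -drift[t, ])))
  corr <- correct_drift(radial_profile_stack(Rd), rotate = FALSE)
  ref <- correct_drift(radial_profile_stack(
    matrix(r0, 30, 256, byrow = TRUE)), rotate = FALSE)
  expect_lt(max(abs(corr$radii - ref$radii)), 0.05)
  ## pure rotation by k grid steps: recovered shift equals k
  k <- 9
  rrot <- r0[c((256 - k + 1):256, 1:(256 - k))]    # r0(theta - k dtheta)
  st2 <- correct_drift(radial_profile_stack(rbind(r0, rrot)), rotate = TRUE)
  expect_equal(attr(st2, "rotations")[2] / (2 * pi / 256), k, tolerance = 1e-6)
  expect_lt(max(abs(st2$radii[2, ] - st2$radii[1, ])), 0.05)
  ## an already-corrected stack is a fixed point
  again <- correct_drift(ref, rotate = FALSE)
  expect_lt(max(abs(again$radii - ref$radii)), 1e-6)
  expect_error(correct_drift(radial_profile_stack(matrix(r0, 1, 256))),
               "at least 2")
})

test_that("drift-corrected statistics match the static twin within 2 percent", {
  ## rigid translation injected into the segmented profile stack; after
  ## barycenter correction the statistics must match the static twin
  fr <- fx_render()
  n <- 150
  prof_s <- t(vapply(fr$stack$frames[1:n], function(f)
    extract_contour(f, fr$stack$optics$center, N = 128), numeric(128)))
  theta <- 2 * pi * (0:127) / 128
  drift <- cbind(1.2 * sin(seq(0, 4 * pi, length.out = n)),
                 0.8 * cos(seq(0, 3 * pi, length.out = n)))
  prof_d <- t(sapply(seq_len(n), function(t)
    flickering:::recenter_profile(prof_s[t, ], theta, -drift[t, ])))
  c_static <- correct_drift(radial_profile_stack(prof_s), rotate = FALSE)
  c_drift <- correct_drift(radial_profile_stack(prof_d), rotate = FALSE)
  s_static <- assemble_series(c_static, dt = 5e-4,
                              pixel_size = fr$optics$pixel_size)
  s_drift <- assemble_series(c_drift, dt = 5e-4,
                             pixel_size = fr$optics$pixel_size)
  S2s <- mean(local_variance(s_static))
  S2d <- mean(local_variance(s_drift))
  expect_lt(abs(S2d / S2s - 1), 0.02)
  ps <- compute_psd(s_static, segment_length = 64, msd_lags = 0)
  pd <- compute_psd(s_drift, segment_length = 64, msd_lags = 0)
  expect_lt(abs(spectrum_integral(pd) / spectrum_integral(ps) - 1), 0.02)
})

test_that("assembled series are centered displacements about the global mean", {
  fr <- fx_render()
  prof <- radial_profile_stack(
    t(vapply(fr$stack$frames[1:150], function(f)
      extract_contour(f, fr$stack$optics$center, N = 128), numeric(128))))
  s <- assemble_series(prof, dt = 5e-4, pixel_size = fr$optics$pixel_size)
  expect_lt(abs(mean(s$dh)), 1e-9 * s$R_bar)
  expect_equal(ncol(s$dh), 150)
  ## frame-count consistency: 5 s at 0.5 ms is 1e4 frames
  expect_equal(round(5 / 5e-4), 10000)
  expect_error(assemble_series(prof, dt = 5e-4,
                               pixel_size = fr$optics$pixel_size,
                               duration = 5), "inconsistent")
})

test_that("simulate-render-segment-assemble round trip recovers local variances", {
  fr <- fx_render()
  r <- t(vapply(fr$stack$frames, function(f)
    extract_contour(f, fr$stack$optics$center, N = 128), numeric(128)))
  s_rec <- assemble_series(radial_profile_stack(r), dt = 5e-4,
                           pixel_size = fr$optics$pixel_size)
  sig_true <- local_variance(fr$s)
  sig_rec <- local_variance(s_rec)
  ratio <- sqrt(sig_rec / sig_true)
  expect_lt(abs(mean(sig_rec) / mean(sig_true) - 1), 0.05)
  expect_gte(mean(abs(ratio - 1) <= 0.1), 0.95)
  expect_lt(max(abs(ratio - 1)), 0.2)
})
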