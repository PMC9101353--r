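test_that("identical seeds give byte-identical outputs, new seeds differ", {
  cfg1 <- generator_config(seed = 11)
  cfg2 <- generator_config(seed = 12)
  a <- generate_radius_trace(cfg1)
  b <- generate_radius_trace(cfg1)
  c <- generate_radius_trace(cfg2)
  expect_identical(a$trace, b$trace)
  expect_false(isTRUE(all.equal(a$trace$R, c$trace$R)))
  expect_identical(generate_recruitment_cohort(cfg1, n_per = 2)$traces,
                   generate_recruitment_cohort(cfg1, n_per = 2)$traces)
})

test_that("noise-free configuration returns the simulation exactly", {
  cfg <- generator_config(seed = 3, radius_noise_sd = 0)
  out <- generate_radius_trace(cfg, replicate_variability = FALSE)
  expect_equal(out$trace$R, out$trace$R_true)
  prot <- cfg$protocol
  sim <- simulate_global(prot, cfg$params,
                         seq(-cfg$baseline, cfg$duration, by = cfg$dt))
  expect_equal(out$trace$R_true, sim$R)
})

test_that("recruitment cohort is centred on the model curve", {
  cfg <- generator_config(seed = 8)
  rec <- generate_recruitment_cohort(cfg, eps_levels = 0.3, n_per = 30)
  resid <- rec$traces$dI_I0 - rec$traces$dI_I0_true
  expect_lt(abs(mean(resid)), 0.01)
  expect_equal(sd(resid), cfg$intensity_cv * (1 + mean(rec$traces$dI_I0_true)),
               tolerance = 0.15)
})

test_that("flat, dynamics-free, bleach-free kymograph is constant", {
  cfg <- generator_config(seed = 4, intensity_cv = 0, tau_b = Inf,
                          protocol = stretch_protocol(0))
  kg <- generate_kymograph(cfg, spatial_template = "flat")
  expect_equal(max(kg$kym$I) - min(kg$kym$I), 0)
})

test_that("kymograph analysis chain recovers the generator truths", {
  cfg <- generator_config(seed = 21, intensity_cv = 0.03)
  kg <- generate_kymograph(cfg)
  kc <- photobleach_correct(kg$kym, c(-cfg$baseline, 0))
  expect_rel_equal(kc$tau_b, cfg$tau_b, 0.10)
  kn <- normalize_relative(kc, c(-cfg$baseline, 0))
  # whole-bundle trace follows the recruitment model
  post <- dplyr::filter(kn$total_trace, t >= 0)
  ft <- fit_exponential_relax(post, t, dI_I0, kind = "decay_to_plateau")
  expect_rel_equal(ft$estimates$timescale, cfg$params$t_star, 0.35)
  # landmarks sit at the ends and middle of the segment-averaged profile
  ks <- segment_average(kn, 5)
  lm <- locate_landmarks(kg$truth$profile, kg$kym$s)
  expect_lt(abs(lm$s[lm$landmark == "msf"] - cfg$L0 / 2), 2.5)
})

test_that("arc stack round-trips through the circle fit", {
  cfg <- generator_config(seed = 5)
  R_series <- c(65.6, 70, 75)
  st <- generate_arc_stack(cfg, R_series = R_series, camera_noise = FALSE)
  # ground-truth edges reproduce the radii exactly
  out <- radius_timeseries(st$edges)
  expect_equal(out$R, R_series, tolerance = 1e-7)
  # a ridge trace from the noiseless image recovers R within 0.5%;
  # columns near the rounded endpoint caps are excluded (a per-column
  # maximum is only a valid ridge between the anchors) and the ridge is
  # refined to sub-pixel by the log-parabola vertex, which is exact for
  # the Gaussian line profile; whole-pixel quantization alone leaves a
  # sawtooth that biases the curvature by ~1%
  img <- st$stack[, , 1]
  px <- st$truth$pixel_size
  ridge <- do.call(rbind, lapply(seq_len(ncol(img)), function(j) {
    x <- (j - 0.5) * px
    if (abs(x - st$truth$x0) > st$truth$chord / 2 - 1) return(NULL)
    i <- which.max(img[, j])
    if (img[i, j] <= 100 || i == 1 || i == nrow(img)) return(NULL)
    lg <- log(img[(i - 1):(i + 1), j] - 20)  # background-subtracted
    dsub <- 0.5 * (lg[1] - lg[3]) / (lg[1] - 2 * lg[2] + lg[3])
    c(x, (i + dsub - 0.5) * px)
  }))
  fit <- fit_circle_arc(data.frame(x = ridge[, 1], y = ridge[, 2]))
  expect_rel_equal(fit$R, R_series[1], 0.005)
  # impossible geometry errors out
  expect_error(generate_arc_stack(cfg, R_series = 10), "no arc")
})

test_that("kymograph CSV writer round-trips the matrix", {
  cfg <- generator_config(seed = 6)
  kg <- generate_kymograph(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kymograph_csv(kg$kym, path)
  back <- utils::read.csv(path)
  expect_equal(back$s_um, kg$kym$s)
  expect_equal(unname(as.matrix(back[, -1])), unname(kg$kym$I),
               tolerance = 1e-12)
})
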