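make_kym <- function(I, s = seq_len(nrow(I)) * 0.2, t = seq(0, by = 2,
                     length.out = ncol(I)), state = "raw") {
  kymograph(I, s, t, pixel_size = 0.2, state = state)
}

test_that("constructor validates grids and intensities", {
  I <- matrix(1, 4, 5)
  expect_s3_class(make_kym(I), "kymograph")
  expect_error(kymograph(I, s = c(1, 2, 3), t = 1:5, pixel_size = 0.2))
  expect_error(kymograph(I, s = c(1, 2, 2, 3), t = 1:5, pixel_size = 0.2),
               "increasing")
  expect_error(make_kym(matrix(-1, 4, 5)), "non-negative")
  expect_error(make_kym(matrix(NA_real_, 4, 5)), "finite")
})

test_that("processing state moves one way", {
  I <- matrix(100 * exp(-seq(0, 198, 2) / 1500), nrow = 10, ncol = 100,
              byrow = TRUE)
  k <- make_kym(I)
  kc <- photobleach_correct(k, c(0, 60))
  expect_equal(kc$state, "bleach_corrected")
  expect_error(photobleach_correct(kc, c(0, 60)), "raw")
  expect_error(normalize_relative(k, c(0, 60)), "bleach")
  kn <- normalize_relative(kc, c(0, 60))
  expect_equal(kn$state, "normalized_relative")
})

test_that("photobleach correction inverts a synthetic bleach exactly", {
  t <- seq(0, 400, 2)
  P <- 100 + 30 * sin(seq(0, pi, length.out = 25))
  I <- P %o% exp(-t / 1500)
  k <- kymograph(I, s = seq_along(P) * 0.2, t = t, pixel_size = 0.2)
  kc <- photobleach_correct(k, c(0, 400))
  expect_equal(kc$tau_b, 1500, tolerance = 1e-6)
  expect_equal(kc$I, P %o% rep(1, length(t)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("bleach time scale is recovered within 10% at 3% noise", {
  withr::local_seed(2)
  t <- seq(0, 600, 2)
  P <- rep(100, 40)
  I <- (P %o% exp(-t / 1500)) * (1 + matrix(rnorm(40 * length(t), 0, 0.03), 40))
  k <- kymograph(I, s = seq_len(40) * 0.2, t = t, pixel_size = 0.2)
  kc <- photobleach_correct(k, range(t))
  expect_rel_equal(kc$tau_b, 1500, 0.10)
})

test_that("brightening data yields a correction failure, not silence", {
  t <- seq(0, 100, 2)
  I <- rep(100, 10) %o% exp(t / 500)
  k <- kymograph(I, s = 1:10, t = t, pixel_size = 0.2)
  expect_error(photobleach_correct(k, c(0, 100)), "non-positive")
})

test_that("relative normalisation is zero on the baseline window", {
  t <- seq(0, 200, 2)
  P <- c(80, 120, 100)
  I <- P %o% rep(1, length(t))
  I[, t > 100] <- I[, t > 100] * 1.2
  k <- kymograph(I, s = 1:3, t = t, pixel_size = 1, state = "bleach_corrected")
  kn <- normalize_relative(k, c(0, 100))
  expect_equal(max(abs(kn$I[, t <= 100])), 0)
  expect_true(all(abs(kn$I[, t > 100] - 0.2) < 1e-12))
  # per-region normalisation uses one scalar baseline
  kr <- normalize_relative(k, c(0, 100), per = "region")
  expect_equal(kr$I[, 1], P / 100 - 1)
  # whole-bundle trace is stored
  expect_equal(kn$total_trace$dI_I0[t > 100][1], 0.2)
})

test_that("segment averaging tiles 5-um segments and merges small remainders", {
  s <- seq(0, 36.4, by = 0.2)  # 36.4 um bundle, remainder 1.4 < 2.5
  I <- matrix(rep(s, 3), ncol = 3)
  k <- kymograph(I, s, t = 1:3, pixel_size = 0.2)
  ka <- segment_average(k, 5)
  expect_equal(nrow(ka$I), 7)
  expect_equal(sum(ka$segment_n), length(s))
  # averaging a linear profile returns the segment mean position
  expect_equal(ka$I[, 1], ka$s)
  expect_error(segment_average(k, 0.1), "pixel")
  expect_error(segment_average(k, 100), "exceeds")
})

test_that("landmarks find the FA peaks and mid-fiber valley", {
  s <- seq(0, 36, by = 0.2)
  prof <- 100 * (1 + 0.8 * exp(-s^2 / 18) + 0.8 * exp(-(s - 36)^2 / 18) -
                   0.3 * exp(-(s - 18)^2 / 72))
  lm <- locate_landmarks(prof, s)
  expect_equal(lm$landmark, c("fa1", "msf", "fa2"))
  expect_equal(lm$s[lm$landmark == "fa1"], 0)
  expect_equal(lm$s[lm$landmark == "fa2"], 36)
  expect_equal(lm$s[lm$landmark == "msf"], 18, tolerance = 0.5)
  expect_warning(locate_landmarks(seq(1, 2, length.out = 20)), "monotone")
})

test_that("extraction reproduces a straight-line profile with sub-pixel accuracy", {
  # image whose intensity is linear in x: bilinear sampling is exact
  px <- 0.2
  nx <- 60; ny <- 40
  xcenters <- (seq_len(nx) - 0.5) * px
  img <- matrix(rep(10 + 5 * xcenters, each = ny), ny, nx)
  stack <- array(rep(img, 3), dim = c(ny, nx, 3))
  path <- data.frame(x = c(1, 11), y = c(4, 4))
  k <- extract_kymograph(stack, path, width = 0, pixel_size = px,
                         t = c(0, 2, 4))
  expect_equal(nrow(k$I), length(seq(0, 10, by = px)))
  s_expect <- 10 + 5 * (1 + k$s)
  expect_equal(k$I[, 1], s_expect, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(extract_kymograph(stack, data.frame(x = c(-5, 1), y = c(1, 1)),
                                 pixel_size = px), "bounds")
})

test_that("as_tibble flattens the grid", {
  k <- make_kym(matrix(1:6, 2, 3))
  tb <- as_tibble(k)
  expect_equal(nrow(tb), 6)
  expect_setequal(names(tb), c("t", "s", "intensity"))
})
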