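arc_points <- function(R, span_deg, n = 50, center = c(0, 0), start = 0) {
  ang <- start + seq(0, span_deg * pi / 180, length.out = n)
  data.frame(x = center[1] + R * cos(ang), y = center[2] + R * sin(ang))
}

test_that("circle fit is exact on noiseless arcs across radii and spans", {
  withr::local_seed(7)
  for (i in 1:12) {
    R <- 10^runif(1, 0, 3)          # 1..1000 um
    span <- runif(1, 10, 180)       # degrees
    fit <- fit_circle_arc(arc_points(R, span, center = rnorm(2, 0, 50),
                                     start = runif(1, 0, 2 * pi)))
    expect_lt(abs(fit$R - R), 1e-9 * max(1, R))
    expect_lt(fit$rms_residual, 1e-9)
  }
})

test_that("circle fit is rotation and translation invariant", {
  pts <- arc_points(65.6, 60)
  fit0 <- fit_circle_arc(pts)
  th <- 37 * pi / 180
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y + 5,
                    y = sin(th) * pts$x + cos(th) * pts$y - 3)
  fit1 <- fit_circle_arc(rot)
  expect_equal(fit1$R, fit0$R, tolerance = 1e-9)
})

test_that("chord-sagitta formula agrees with the 3-point circle fit", {
  L <- 36.47; h <- 2.585
  R_cs <- radius_from_chord_sagitta(L, h)
  fit <- fit_circle_arc(data.frame(x = c(-L / 2, 0, L / 2), y = c(0, h, 0)))
  expect_equal(fit$R, R_cs, tolerance = 1e-9)
})

test_that("collinear points raise a degenerate-geometry error", {
  expect_error(fit_circle_arc(data.frame(x = 1:10, y = 2 * (1:10) + 1)),
               "collinear")
  expect_error(fit_circle_arc(data.frame(x = 1:2, y = c(0, 1))), "3")
})

test_that("arc_fit chord endpoints lie on the fitted circle", {
  fit <- fit_circle_arc(arc_points(65.6, 40, center = c(10, -4)))
  d <- sqrt(colSums((t(fit$chord) - fit$center)^2))
  expect_true(all(abs(d - fit$R) <= fit$rms_residual + 1e-9))
})

test_that("fitted radius is unbiased within 0.5% at study geometry", {
  withr::local_seed(99)
  L <- 36.47; R <- 65.6
  half <- asin(L / 2 / R)
  ang <- seq(pi / 2 - half, pi / 2 + half, length.out = 50)
  Rs <- replicate(1000, {
    pts <- data.frame(x = R * cos(ang) + rnorm(50, 0, 0.5),
                      y = R * sin(ang) + rnorm(50, 0, 0.5))
    fit_circle_arc(pts)$R
  })
  expect_lt(abs(mean(Rs) / R - 1), 0.005)
})

test_that("radius_timeseries keeps degenerate frames as NA", {
  good <- arc_points(50, 90)
  frames <- rbind(data.frame(frame = 1, good),
                  data.frame(frame = 2, x = 1:10, y = 1:10),  # collinear
                  data.frame(frame = 3, good))
  out <- radius_timeseries(frames)
  expect_equal(nrow(out), 3)
  expect_true(is.na(out$R[2]))
  expect_equal(out$R[c(1, 3)], c(50, 50), tolerance = 1e-9)
  all_bad <- data.frame(frame = 1, x = 1:5, y = 1:5)
  expect_error(radius_timeseries(all_bad), "degenerate")
})

test_that("tension balance round-trips", {
  expect_equal(tension_from_radius(65.60, 0.0357), 2.34192)
  expect_equal(radius_from_tension(tension_from_radius(70, 0.04), 0.04), 70)
  expect_error(tension_from_radius(-1, 0.04))
})

test_that("tidy and glance methods return one-row summaries", {
  fit <- fit_circle_arc(arc_points(65.6, 45))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("R", "center_x", "center_y"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("R", "rms_residual", "n_points") %in% names(gl)))
})
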