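#' Intensity kymograph along a bundle
#'
#' A kymograph is an arc-length x time intensity grid sampled along a
#' stress fiber. The object records its processing state, which moves
#' one way: `raw` -> `bleach_corrected` -> `normalized_relative`.
#'
#' @param I Intensity matrix, rows = arc-length positions, cols = times.
#' @param s Arc-length grid (um, strictly increasing).
#' @param t Time grid (s, strictly increasing, uniform spacing).
#' @param pixel_size Spatial sampling (um).
#' @param state Processing state.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(I, s, t, pixel_size,
                      state = c("raw", "bleach_corrected", "normalized_relative")) {
  state <- match.arg(state)
  I <- as.matrix(I)
  stopifnot(nrow(I) == length(s), ncol(I) == length(t))
  if (is.unsorted(s, strictly = TRUE)) stop("`s` must be strictly increasing",
                                            call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("`t` must be strictly increasing",
                                            call. = FALSE)
  if (any(!is.finite(I))) stop("intensities must be finite", call. = FALSE)
  if (state == "raw" && any(I < 0)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  dt <- if (length(t) > 1) stats::median(diff(t)) else NA_real_
  structure(list(I = I, s = as.numeric(s), t = as.numeric(t),
                 pixel_size = pixel_size, dt = dt, state = state,
                 history = character()),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d positions x %d frames, state: %s\n",
              nrow(x$I), ncol(x$I), x$state))
  cat(sprintf("  s: %.2f..%.2f um (pixel %.3g um), t: %.1f..%.1f s (dt %.3g s)\n",
              min(x$s), max(x$s), x$pixel_size, min(x$t), max(x$t), x$dt))
  if (length(x$history)) cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.kymograph <- function(x, ...) {
  tidyr::expand_grid(t = x$t, s = x$s) |>
    dplyr::arrange(.data$s, .data$t) |>
    dplyr::mutate(intensity = as.vector(x$I))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Sample a kymograph from an image stack along a polyline
#'
#' For every frame, samples the intensity along `path` with bilinear
#' sub-pixel interpolation, averaging transversely over `width` (um,
#' perpendicular to the path). The arc-length grid is at pixel resolution.
#' Image coordinates are continuous um with the origin at the lower-left
#' corner and pixel centers at half-integer multiples of `pixel_size`.
#'
#' @param stack 3-D numeric array `[ny, nx, nt]` (row 1 = bottom of image)
#'   or a list of matrices.
#' @param path Data frame of polyline vertices `x`, `y` (um).
#' @param width Transverse averaging width (um); `0` samples the line only.
#' @param pixel_size Pixel size of the stack (um).
#' @param t Frame times (s); defaults to frame index.
#' @return A `kymograph` in `raw` state.
#' @export
extract_kymograph <- function(stack, path, width = 1, pixel_size = 0.2,
                              t = NULL) {
  if (is.list(stack) && !is.array(stack)) {
    stack <- simplify2array(stack)
  }
  stopifnot(length(dim(stack)) == 3, width >= 0)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]
  if (is.null(t)) t <- seq_len(nt)
  path <- as.data.frame(path)

  bad <- path$x < 0 | path$x > nx * pixel_size |
    path$y < 0 | path$y > ny * pixel_size
  if (any(bad)) {
    stop("path vertices outside image bounds: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }

  # resample the polyline at pixel-resolution arc length
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s_grid <- seq(0, L, by = pixel_size)
  px <- stats::approx(cum, path$x, xout = s_grid)$y
  py <- stats::approx(cum, path$y, xout = s_grid)$y
  # unit tangents / normals
  tx <- c(diff(px), utils::tail(diff(px), 1))
  ty <- c(diff(py), utils::tail(diff(py), 1))
  nrm <- sqrt(tx^2 + ty^2)
  nxv <- -ty / nrm; nyv <- tx / nrm

  offs <- if (width > 0) {
    seq(-width / 2, width / 2, length.out = max(3, ceiling(width / pixel_size) + 1))
  } else 0

  bilinear <- function(img, xq, yq) {
    u <- xq / pixel_size + 0.5
    v <- yq / pixel_size + 0.5
    u <- pmin(pmax(u, 1), nx); v <- pmin(pmax(v, 1), ny)
    j0 <- pmin(floor(u), nx - 1); i0 <- pmin(floor(v), ny - 1)
    fu <- u - j0; fv <- v - i0
    img[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
      img[cbind(i0, j0 + 1)] * fu * (1 - fv) +
      img[cbind(i0 + 1, j0)] * (1 - fu) * fv +
      img[cbind(i0 + 1, j0 + 1)] * fu * fv
  }

  I <- matrix(0, length(s_grid), nt)
  for (k in seq_len(nt)) {
    img <- stack[, , k]
    acc <- 0
    for (o in offs) acc <- acc + bilinear(img, px + o * nxv, py + o * nyv)
    I[, k] <- acc / length(offs)
  }
  kymograph(I, s_grid, t, pixel_size, state = "raw")
}

#' Correct photobleaching by exponential-decay normalisation
#'
#' Fits `I_total(t) = C exp(-t / tau_b)` to the total bundle intensity over
#' `fit_window` (a stimulus-free time range, typically before the stretch)
#' and divides the whole kymograph by the fitted decay `exp(-t / tau_b)`.
#'
#' @param kym A `kymograph` in `raw` state.
#' @param fit_window Length-2 numeric, time range (s) used for the fit;
#'   must contain at least 10 frames.
#' @return A `kymograph` in `bleach_corrected` state, with attribute
#'   `tau_b` (s) stored in the object (`$tau_b`).
#' @export
photobleach_correct <- function(kym, fit_window) {
  stopifnot(inherits(kym, "kymograph"))
  if (kym$state != "raw") {
    stop("photobleach correction requires a raw kymograph (state is '",
         kym$state, "')", call. = FALSE)
  }
  sel <- kym$t >= fit_window[1] & kym$t <= fit_window[2]
  if (sum(sel) < 10) stop("fit_window must contain at least 10 frames",
                          call. = FALSE)
  tot <- colSums(kym$I)
  if (any(tot[sel] <= 0)) stop("non-positive total intensity in fit window",
                               call. = FALSE)
  fit <- stats::lm(log(tot[sel]) ~ kym$t[sel])
  slope <- unname(stats::coef(fit)[2])
  tau_b <- -1 / slope
  if (is.finite(tau_b) && tau_b <= 0) {
    stop("correction failure: fitted bleaching time scale is non-positive (",
         format(tau_b, digits = 4), " s)", call. = FALSE)
  }
  decay <- if (is.finite(tau_b)) exp(-(kym$t - kym$t[1]) / tau_b) else rep(1, length(kym$t))
  out <- kym
  out$I <- sweep(kym$I, 2, decay, "/")
  out$state <- "bleach_corrected"
  out$tau_b <- tau_b
  out$history <- c(kym$history, sprintf("photobleach_correct(tau_b=%.4g)", tau_b))
  out
}

#' Normalise a kymograph to relative intensity
#'
#' Converts a bleach-corrected kymograph to relative intensity
#' `(I(s,t) - I0(s)) / I0(s)` where `I0` is the mean over
#' `baseline_window`. With `per = "region"` a single scalar baseline (the
#' grand mean over the window) is used instead of a per-position one. The
#' whole-bundle relative trace `DeltaI/I0` is stored as `$total_trace`.
#'
#' @param kym A `kymograph` in `bleach_corrected` state.
#' @param baseline_window Length-2 numeric time range (s).
#' @param per `"position"` (default) or `"region"`.
#' @return A `kymograph` in `normalized_relative` state.
#' @export
normalize_relative <- function(kym, baseline_window,
                               per = c("position", "region")) {
  stopifnot(inherits(kym, "kymograph"))
  per <- match.arg(per)
  if (kym$state != "bleach_corrected") {
    stop("normalisation requires a bleach-corrected kymograph (state is '",
         kym$state, "')", call. = FALSE)
  }
  sel <- kym$t >= baseline_window[1] & kym$t <= baseline_window[2]
  if (!any(sel)) stop("baseline_window selects no frames", call. = FALSE)
  I0 <- rowMeans(kym$I[, sel, drop = FALSE])
  if (per == "region") I0 <- rep(mean(I0), length(I0))
  bad <- which(I0 <= 0)
  if (length(bad)) {
    stop("non-positive baseline at positions s = ",
         paste(format(kym$s[bad], digits = 4), collapse = ", "), call. = FALSE)
  }
  tot <- colSums(kym$I)
  tot0 <- mean(tot[sel])
  out <- kym
  out$I <- sweep(sweep(kym$I, 1, I0, "-"), 1, I0, "/")
  out$state <- "normalized_relative"
  out$total_trace <- tibble::tibble(t = kym$t, dI_I0 = tot / tot0 - 1)
  out$history <- c(kym$history, paste0("normalize_relative(", per, ")"))
  out
}

#' Average a kymograph over fixed-length arc segments
#'
#' Tiles the arc length into contiguous `segment_length` segments starting
#' from the first (focal-adhesion proximal) end; a trailing remainder
#' shorter than half a segment is merged into the last full segment,
#' otherwise it forms a final short segment. Each output row is the mean
#' over the positions in one segment.
#'
#' @param kym A `kymograph` (any state).
#' @param segment_length Segment length (um), `>= pixel_size`.
#' @return A `kymograph` on the coarse segment grid (`s` = segment
#'   midpoints) with per-segment pixel counts in `$segment_n`.
#' @export
segment_average <- function(kym, segment_length = 5) {
  stopifnot(inherits(kym, "kymograph"))
  if (segment_length < kym$pixel_size) {
    stop("segment_length must be at least one pixel", call. = FALSE)
  }
  L <- max(kym$s) - min(kym$s)
  if (segment_length > L + kym$pixel_size) {
    stop("segment_length exceeds bundle length", call. = FALSE)
  }
  n_full <- floor(L / segment_length)
  remainder <- L - n_full * segment_length
  edges <- min(kym$s) + segment_length * seq(0, n_full)
  if (remainder >= segment_length / 2) {
    edges <- c(edges, max(kym$s))
  } else {
    edges[length(edges)] <- max(kym$s)
  }
  idx <- findInterval(kym$s, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  groups <- sort(unique(idx))
  Ic <- do.call(rbind, lapply(groups, function(g) {
    colMeans(kym$I[idx == g, , drop = FALSE])
  }))
  s_mid <- vapply(groups, function(g) mean(kym$s[idx == g]), numeric(1))
  out <- kym
  out$I <- Ic
  out$s <- s_mid
  out$segment_n <- vapply(groups, function(g) sum(idx == g), integer(1))
  out$segment_edges <- edges
  out$history <- c(kym$history, sprintf("segment_average(%g um)", segment_length))
  out
}

#' Locate focal-adhesion peaks and the mid-fiber valley
#'
#' Stress fibers carry high actin density at both anchored ends (the focal
#' adhesions, FA) and a valley near the middle of the bundle (mSF, the
#' "weak point" where healing actin accrues). The FA positions are the
#' maxima of the outer 25% of arc length on each side; the mSF is the
#' minimum of the central 50%. Ties are broken toward the bundle midpoint;
#' a monotone profile triggers an ambiguity warning with best-effort
#' positions.
#'
#' @param profile Intensity values along the bundle.
#' @param s Arc-length coordinates (um); defaults to the index.
#' @return A tibble with columns `landmark` (`fa1`, `msf`, `fa2`), `s`,
#'   `index`, `intensity`.
#' @export
locate_landmarks <- function(profile, s = seq_along(profile)) {
  n <- length(profile)
  if (n < 5) stop("profile must have at least 5 samples", call. = FALSE)
  stopifnot(length(s) == n)
  d <- diff(profile)
  if (all(d >= 0) || all(d <= 0)) {
    warning("monotone (or flat) profile: landmark positions are ambiguous",
            call. = FALSE)
  }
  mid_s <- (s[1] + s[n]) / 2
  pick <- function(idx, decreasing) {
    v <- profile[idx]
    extreme <- if (decreasing) max(v) else min(v)
    cand <- idx[abs(v - extreme) <= 1e-12 * max(1, abs(extreme))]
    cand[which.min(abs(s[cand] - mid_s))]
  }
  left <- which(s <= s[1] + 0.25 * (s[n] - s[1]))
  right <- which(s >= s[1] + 0.75 * (s[n] - s[1]))
  central <- which(s >= s[1] + 0.25 * (s[n] - s[1]) &
                     s <= s[1] + 0.75 * (s[n] - s[1]))
  i_fa1 <- pick(left, decreasing = TRUE)
  i_fa2 <- pick(right, decreasing = TRUE)
  i_msf <- pick(central, decreasing = FALSE)
  tibble::tibble(landmark = c("fa1", "msf", "fa2"),
                 s = s[c(i_fa1, i_msf, i_fa2)],
                 index = c(i_fa1, i_msf, i_fa2),
                 intensity = profile[c(i_fa1, i_msf, i_fa2)])
}

#' Total bundle intensity over time
#'
#' @param kym A `kymograph`.
#' @return A tibble with columns `t` and `total`.
#' @export
total_intensity_trace <- function(kym) {
  stopifnot(inherits(kym, "kymograph"))
  tibble::tibble(t = kym$t, total = colSums(kym$I))
}
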