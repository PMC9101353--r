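#' Least-squares circle fit to arc points
#'
#' Fits a circle to 2-D points by the algebraic (Kasa) linear least-squares
#' fit followed by geometric (orthogonal-distance) refinement with
#' Gauss-Newton and a leading-order bias correction driven by the residual
#' variance (shallow noisy arcs otherwise overestimate the radius). Exact on
#' noiseless circles and invariant under rotation and translation. Used to
#' measure the radius of curvature of arc-shaped stress fibers from edge
#' coordinates.
#'
#' @param points A data frame (or matrix) with columns `x`, `y` in um.
#' @return An object of class `arc_fit`: list with `center` (length-2),
#'   `R` (um), `rms_residual` (um), `n_points`, and `chord` (the two
#'   extreme points along the arc).
#' @export
#' @examples
#' fit_circle_arc(data.frame(x = c(0, 1, 0), y = c(1, 0, -1)))
fit_circle_arc <- function(points) {
  pts <- as.data.frame(points)
  if (is.null(pts$x) || is.null(pts$y)) {
    colnames(pts)[1:2] <- c("x", "y")
  }
  x <- as.numeric(pts$x); y <- as.numeric(pts$y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite points", call. = FALSE)

  # collinearity check via the smallest singular value of centered coords
  mx <- mean(x); my <- mean(y)
  sv <- svd(cbind(x - mx, y - my))$d
  if (sv[2] < 1e-10 * max(sv[1], 1)) {
    stop("degenerate geometry: points are collinear (infinite radius)",
         call. = FALSE)
  }

  # Kasa algebraic fit: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  abc <- qr.solve(A, z)
  a <- abc[1]; b <- abc[2]
  R <- sqrt(abc[3] + a^2 + b^2)

  # geometric refinement (Gauss-Newton on orthogonal distances)
  par <- c(a, b, R)
  for (iter in 1:50) {
    dx <- x - par[1]; dy <- y - par[2]
    d <- sqrt(dx^2 + dy^2)
    r <- d - par[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 3))
    par <- par + step
    if (max(abs(step)) < 1e-12 * (1 + abs(par[3]))) break
  }
  dx <- x - par[1]; dy <- y - par[2]
  d <- sqrt(dx^2 + dy^2)
  resid <- d - par[3]

  # leading-order (Box-type) bias correction for the orthogonal-distance
  # fit: short shallow arcs inflate the radius by O(sigma^2); the correction
  # uses the residual variance estimate and vanishes on noiseless data
  if (n > 3) {
    u <- dx / d; v <- dy / d
    J <- cbind(-u, -v, -1)
    Gi <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(Gi)) {
      s2 <- sum(resid^2) / (n - 3)
      h <- (Gi[1, 1] * (1 - u^2) + Gi[2, 2] * (1 - v^2) -
              2 * Gi[1, 2] * u * v) / d
      bias <- -(s2 / 2) * as.numeric(Gi %*% crossprod(J, h))
      par <- par - bias
      dx <- x - par[1]; dy <- y - par[2]
      d <- sqrt(dx^2 + dy^2)
      resid <- d - par[3]
    }
  }

  # chord endpoints: extremes along the arc's angular extent
  ang <- atan2(dy, dx)
  ref <- atan2(mean(sin(ang)), mean(cos(ang)))
  rel <- ((ang - ref + pi) %% (2 * pi)) - pi
  i1 <- which.min(rel); i2 <- which.max(rel)

  structure(list(center = c(par[1], par[2]), R = par[3],
                 rms_residual = sqrt(mean(resid^2)), n_points = n,
                 chord = rbind(c(x[i1], y[i1]), c(x[i2], y[i2]))),
            class = "arc_fit")
}

#' @export
print.arc_fit <- function(x, ...) {
  cat(sprintf("<arc_fit> R = %.4f um, center (%.3f, %.3f), rms %.3g um, n = %d\n",
              x$R, x$center[1], x$center[2], x$rms_residual, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.arc_fit <- function(x, ...) {
  tibble::tibble(term = c("R", "center_x", "center_y"),
                 estimate = c(x$R, x$center[1], x$center[2]))
}

#' @exportS3Method generics::glance
glance.arc_fit <- function(x, ...) {
  tibble::tibble(R = x$R, rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Circle radius from chord length and sagitta
#'
#' Closed form `R = h/2 + L^2/(8h)` for an arc of chord `L` and sagitta `h`
#' (the perpendicular distance from the chord midpoint to the arc). A
#' cross-check for [fit_circle_arc()] on shallow arcs.
#'
#' @param L Chord length (um).
#' @param h Sagitta (um).
#' @return Radius (um).
#' @export
#' @examples
#' radius_from_chord_sagitta(36.47, 2.585)
radius_from_chord_sagitta <- function(L, h) {
  stopifnot(all(L > 0), all(h > 0))
  h / 2 + L^2 / (8 * h)
}

#' Radius-of-curvature time series from per-frame edge points
#'
#' Fits [fit_circle_arc()] to the edge points of every frame. Frames whose
#' fit fails (fewer than 3 points, collinear) carry `NA`, never silently
#' dropped.
#'
#' @param frames A data frame with columns `frame`, `x`, `y` (um), one row
#'   per edge point.
#' @param t_grid Optional times (s), one per distinct frame; defaults to the
#'   frame index.
#' @return A tibble with columns `t`, `frame`, `R` (um), `rms` (um), `n`.
#' @export
radius_timeseries <- function(frames, t_grid = NULL) {
  df <- as.data.frame(frames)
  stopifnot(all(c("frame", "x", "y") %in% names(df)))
  ids <- sort(unique(df$frame))
  if (is.null(t_grid)) t_grid <- ids
  stopifnot(length(t_grid) == length(ids))
  fits <- purrr::map(ids, function(f) {
    sub <- df[df$frame == f, c("x", "y")]
    tryCatch(fit_circle_arc(sub), error = function(e) NULL)
  })
  out <- tibble::tibble(
    t = t_grid, frame = ids,
    R = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$R),
    rms = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$rms_residual),
    n = purrr::map_int(fits, ~ if (is.null(.x)) NA_integer_ else .x$n_points))
  if (all(is.na(out$R))) stop("all frames degenerate: empty series", call. = FALSE)
  out
}

#' Tension balance of a curved stress fiber
#'
#' A peripheral stress fiber pulled inward by the cortical tension `sigma`
#' and along its length by the line tension `lambda` adopts a circular arc
#' of radius `R = lambda / sigma`. `tension_from_radius()` gives
#' `lambda = sigma * R`; `radius_from_tension()` is the inverse. The same
#' balance holds locally on a segment (`sigma_l = lambda_l / r_l`).
#'
#' @param R Radius of curvature (um).
#' @param sigma Cortical tension (nN/um).
#' @param lambda Line tension (nN).
#' @return Line tension (nN) or radius (um).
#' @export
#' @examples
#' tension_from_radius(65.60, 0.0357)  # about 2.34 nN
tension_from_radius <- function(R, sigma) {
  stopifnot(all(R > 0), all(sigma > 0))
  sigma * R
}

#' @rdname tension_from_radius
#' @export
radius_from_tension <- function(lambda, sigma) {
  stopifnot(all(lambda > 0), all(sigma > 0))
  lambda / sigma
}
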