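#' Configuration of the synthetic-data generator
#'
#' Collects everything the generators need: bundle geometry and its
#' cell-to-cell variability, mechanical parameters, the strain protocol,
#' noise magnitudes and the sampling scheme. Defaults mirror the study
#' conditions: `L0 = 36.47 +/- 4.21` um, `R0 = 65.60 +/- 5.44` um,
#' `A = 0.6 +/- 0.2` um^2 (population SDs, truncated at 3 SD), images every
#' `dt = 2` s for 900 s, stretch rate 100 um/s, a 3600 s prestretch hold
#' before compression steps, 5% multiplicative intensity noise, 0.3 um edge
#' point noise and a 1500 s photobleaching time scale. The seed fully
#' determines every stochastic output.
#'
#' @param L0,R0,A Mean bundle length (um), radius (um) and cross-section
#'   (um^2).
#' @param L0_sd,R0_sd,A_sd Population SDs for replicate draws.
#' @param params A [mech_params()] object.
#' @param protocol A [stretch_protocol()].
#' @param radius_noise_sd SD of the per-frame radius measurement noise (um).
#' @param edge_noise_sd SD of edge-point coordinate noise (um).
#' @param intensity_cv Multiplicative intensity noise (coefficient of
#'   variation).
#' @param tau_b Photobleaching time scale (s); `Inf` disables bleaching.
#' @param dt Frame interval (s).
#' @param duration Post-stretch acquisition time (s).
#' @param baseline Pre-stretch acquisition time (s), used for bleach and
#'   baseline windows.
#' @param pixel_size Spatial sampling (um).
#' @param seed Integer seed.
#' @param n_replicates Cohort size per condition.
#' @return A `generator_config` list.
#' @export
generator_config <- function(L0 = 36.47, R0 = 65.60, A = 0.6,
                             L0_sd = 4.21, R0_sd = 5.44, A_sd = 0.2,
                             params = study_params(),
                             protocol = stretch_protocol(0.2, L0 = L0),
                             radius_noise_sd = 1, edge_noise_sd = 0.3,
                             intensity_cv = 0.05, tau_b = 1500,
                             dt = 2, duration = 900, baseline = 120,
                             pixel_size = 0.2, seed = 1L, n_replicates = 12) {
  stopifnot(L0 > 0, R0 > 0, A > 0, dt > 0, duration > 0, pixel_size > 0)
  structure(list(L0 = L0, R0 = R0, A = A, L0_sd = L0_sd, R0_sd = R0_sd,
                 A_sd = A_sd, params = params, protocol = protocol,
                 radius_noise_sd = radius_noise_sd,
                 edge_noise_sd = edge_noise_sd, intensity_cv = intensity_cv,
                 tau_b = tau_b, dt = dt, duration = duration,
                 baseline = baseline, pixel_size = pixel_size,
                 seed = as.integer(seed), n_replicates = n_replicates),
            class = "generator_config")
}

# truncated-Gaussian replicate draw of the bundle geometry; the per-cell
# mechanical constants follow from K0 = E A / L0 and lambda0 = sigma R0.
draw_replicate <- function(cfg) {
  trunc_rnorm <- function(mean, sd) {
    if (sd == 0) return(mean)
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (abs(x - mean) <= 3 * sd && x > 0) return(x)
    }
  }
  L0 <- trunc_rnorm(cfg$L0, cfg$L0_sd)
  R0 <- trunc_rnorm(cfg$R0, cfg$R0_sd)
  A <- trunc_rnorm(cfg$A, cfg$A_sd)
  p <- cfg$params
  params <- mech_params(K0 = p$E * A / L0, k = p$k, gamma = p$gamma,
                        lambda0 = p$sigma * R0, V = p$V, sigma = p$sigma,
                        E = p$E, A = A, alpha = p$alpha, t_star = p$t_star)
  list(L0 = L0, R0 = R0, A = A, params = params)
}

#' Generate a noisy radius-of-curvature trace
#'
#' Runs the forward bundle simulation for the configured protocol, samples
#' the radius on the frame grid and adds Gaussian measurement noise
#' (`radius_noise_sd`), emulating the scatter of per-frame arc fits. The
#' noiseless trace and all true parameters are returned alongside.
#'
#' @param cfg A [generator_config()].
#' @param replicate_variability Draw the bundle geometry from the
#'   population distributions? If `FALSE` the configured means are used.
#' @return A list with `trace` (tibble `t`, `R`, `R_true`) and `truth`
#'   (list of the parameters, protocol, `R0` and the full noiseless
#'   `bundle_trace`).
#' @export
generate_radius_trace <- function(cfg, replicate_variability = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::local_seed(cfg$seed)
  rep_draw <- if (replicate_variability) draw_replicate(cfg) else
    list(L0 = cfg$L0, R0 = cfg$R0, A = cfg$A, params = cfg$params)
  prot <- cfg$protocol
  prot$L0 <- rep_draw$L0
  # include pre-step baseline frames so the unstretched (or prestretched)
  # radius can be measured the way the experiment measures it
  t_grid <- seq(-cfg$baseline, cfg$duration, by = cfg$dt)
  sim <- simulate_global(prot, rep_draw$params, t_grid)
  R_true <- sim$R
  R <- R_true + stats::rnorm(length(R_true), 0, cfg$radius_noise_sd)
  list(trace = tibble::tibble(t = t_grid, R = R, R_true = R_true),
       truth = list(params = rep_draw$params, protocol = prot,
                    L0 = rep_draw$L0, R0 = attr(sim, "R0"),
                    R_baseline = R_true[max(which(t_grid < -1))],
                    bundle_trace = sim))
}

#' Generate a cohort of recruitment intensity traces
#'
#' Emulates the whole-bundle relative intensity response under extension:
#' `DeltaI/I0(t) = alpha * eps * (1 - exp(-t/t_star))` with multiplicative
#' Gaussian noise of the configured coefficient of variation on the
#' intensity, i.e. additive noise of SD `intensity_cv` on the relative
#' trace.
#'
#' @param cfg A [generator_config()].
#' @param eps_levels Strain levels of the cohort.
#' @param n_per Traces per strain level; defaults to `cfg$n_replicates`.
#' @return A list with `traces` (tibble `eps`, `rep`, `t`, `dI_I0`,
#'   `dI_I0_true`) and `truth` (`alpha`, `t_star`).
#' @export
generate_recruitment_cohort <- function(cfg,
                                        eps_levels = c(0.1, 0.2, 0.3, 0.4),
                                        n_per = cfg$n_replicates) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::local_seed(cfg$seed)
  p <- cfg$params
  t_grid <- seq(0, cfg$duration, by = cfg$dt)
  traces <- tidyr::expand_grid(eps = eps_levels, rep = seq_len(n_per)) |>
    dplyr::mutate(data = purrr::map(.data$eps, function(e) {
      y_true <- as.numeric(intensity_model(e, t_grid, p$alpha, p$t_star))
      y <- (1 + y_true) * (1 + stats::rnorm(length(t_grid), 0, cfg$intensity_cv)) - 1
      tibble::tibble(t = t_grid, dI_I0 = y, dI_I0_true = y_true)
    })) |>
    tidyr::unnest("data")
  list(traces = traces, truth = list(alpha = p$alpha, t_star = p$t_star))
}

#' Generate a synthetic intensity kymograph
#'
#' Builds an arc-length x time kymograph with the spatial and temporal
#' structure of stretched peripheral stress fibers: a spatial profile with
#' two focal-adhesion end peaks and a mid-fiber valley (`fa_peaks`
#' template), a global recruitment response following
#' `alpha eps (1 - exp(-t/t_star))`, a difference-of-exponentials overshoot
#' (slow scale `tau_fa`) localised at the FA ends, a saturating gain (scale
#' `tau_msf`) at the mid-fiber, photobleaching decay and multiplicative
#' noise. Amplitudes of the local responses scale with the applied strain.
#' The overshoot functional form is a generator choice; only its slow time
#' scale is constrained by the study.
#'
#' @param cfg A [generator_config()].
#' @param spatial_template `"fa_peaks"`, `"flat"`, or a function of `s`
#'   returning the baseline profile.
#' @param tau_fa,tau_msf FA overshoot slow scale and mid-fiber gain scale (s).
#' @param tau_fa_fast Fast scale of the FA overshoot (s).
#' @param fa_amp_per_strain,msf_amp_per_strain Local response amplitudes
#'   per unit strain.
#' @param peak_amp,valley_depth,peak_width Contrast parameters of the
#'   `fa_peaks` template.
#' @return A list with `kym` (a raw-state [kymograph()]) and `truth`
#'   (noiseless intensity matrix, baseline profile, time scales,
#'   `alpha`, `t_star`, `tau_b`, `epsilon`).
#' @export
generate_kymograph <- function(cfg, spatial_template = "fa_peaks",
                               tau_fa = 178.5, tau_msf = 387.9,
                               tau_fa_fast = 40,
                               fa_amp_per_strain = 1.2,
                               msf_amp_per_strain = 2,
                               peak_amp = 0.8, valley_depth = 0.3,
                               peak_width = 3) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::local_seed(cfg$seed)
  L <- cfg$L0
  s <- seq(0, L, by = cfg$pixel_size)
  t <- seq(-cfg$baseline, cfg$duration, by = cfg$dt)
  eps <- cfg$protocol$epsilon
  p <- cfg$params

  P <- if (is.function(spatial_template)) {
    spatial_template(s)
  } else if (identical(spatial_template, "flat")) {
    rep(100, length(s))
  } else if (identical(spatial_template, "fa_peaks")) {
    100 * (1 + peak_amp * exp(-s^2 / (2 * peak_width^2)) +
             peak_amp * exp(-(s - L)^2 / (2 * peak_width^2)) -
             valley_depth * exp(-(s - L / 2)^2 / (2 * (L / 6)^2)))
  } else {
    stop("unknown spatial template '", spatial_template, "'", call. = FALSE)
  }
  if (any(P <= 0)) stop("template produces non-positive intensities",
                        call. = FALSE)

  tpos <- pmax(t, 0)
  w_fa <- exp(-s^2 / (2 * peak_width^2)) + exp(-(s - L)^2 / (2 * peak_width^2))
  w_msf <- exp(-(s - L / 2)^2 / (2 * (L / 8)^2))
  # difference of exponentials normalised to unit peak
  t_pk <- log(tau_fa / tau_fa_fast) / (1 / tau_fa_fast - 1 / tau_fa)
  pk <- exp(-t_pk / tau_fa) - exp(-t_pk / tau_fa_fast)
  overshoot <- (exp(-tpos / tau_fa) - exp(-tpos / tau_fa_fast)) / pk
  global <- if (eps > 0) p$alpha * eps * (1 - exp(-tpos / p$t_star)) else 0 * tpos
  msf_gain <- (1 - exp(-tpos / tau_msf))

  dyn <- 1 + outer(rep(1, length(s)), global) +
    (eps > 0) * fa_amp_per_strain * eps * outer(w_fa, overshoot) +
    (eps > 0) * msf_amp_per_strain * eps * outer(w_msf, msf_gain)
  dyn[, t < 0] <- 1
  bleach <- if (is.finite(cfg$tau_b)) exp(-(t - t[1]) / cfg$tau_b) else rep(1, length(t))
  I_true <- (P %o% bleach) * dyn
  noise <- matrix(stats::rnorm(length(I_true), 0, cfg$intensity_cv),
                  nrow(I_true))
  I <- pmax(I_true * (1 + noise), 0)

  list(kym = kymograph(I, s, t, cfg$pixel_size, state = "raw"),
       truth = list(I_true = I_true, profile = P, tau_fa = tau_fa,
                    tau_msf = tau_msf, tau_fa_fast = tau_fa_fast,
                    alpha = p$alpha, t_star = p$t_star, tau_b = cfg$tau_b,
                    epsilon = eps,
                    fa_amp = fa_amp_per_strain * max(eps, 0),
                    msf_amp = msf_amp_per_strain * max(eps, 0)))
}

#' Generate a synthetic image stack of a fluorescent arc
#'
#' Renders the bundle as a bright circular arc between two fixed anchor
#' points (the focal adhesions) on a dark background, one frame per entry
#' of the radius series, with Poisson-Gaussian camera noise. Ground-truth
#' edge coordinates (points on the true arc, optionally with measurement
#' noise) accompany the stack, so the geometry operators can be scored
#' without re-running the generator.
#'
#' @param cfg A [generator_config()].
#' @param R_series Radii per frame (um); default: the noiseless radius
#'   trace of the configured protocol.
#' @param n_edge_points Ground-truth edge points per frame.
#' @param line_width Gaussian cross-section of the rendered arc (um).
#' @param peak,background Fluorophore peak and background levels (camera
#'   counts).
#' @param camera_noise Add Poisson-Gaussian noise?
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @return A list with `stack` (`[ny, nx, nt]` array), `edges` (tibble
#'   `frame`, `x`, `y`: noiseless arc points), `edges_noisy` (same with
#'   `edge_noise_sd` coordinate noise), and `truth` (`R_series`, chord
#'   length, pixel size, arc center per frame).
#' @export
generate_arc_stack <- function(cfg, R_series = NULL, n_edge_points = 50,
                               line_width = 0.8, peak = 500, background = 20,
                               camera_noise = TRUE, read_noise_sd = 3) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::local_seed(cfg$seed)
  L <- cfg$L0
  if (is.null(R_series)) {
    t_grid <- seq(0, cfg$duration, by = cfg$dt)
    prot <- cfg$protocol; prot$L0 <- L
    R_series <- simulate_global(prot, cfg$params, t_grid)$R
  }
  if (any(R_series < L / 2)) {
    stop("radius smaller than half the chord: no arc exists", call. = FALSE)
  }
  px <- cfg$pixel_size
  h_max <- max(R_series - sqrt(R_series^2 - (L / 2)^2))
  margin <- 4 * line_width
  wx <- L + 2 * margin
  wy <- h_max + 2 * margin
  nx <- ceiling(wx / px); ny <- ceiling(wy / px)
  if (nx * ny > 4e6) stop("arc exceeds reasonable canvas size", call. = FALSE)
  xc <- (seq_len(nx) - 0.5) * px   # pixel centers, origin lower-left
  yc <- (seq_len(ny) - 0.5) * px
  x0 <- margin + L / 2             # arc chord endpoints at x0 +/- L/2, y = margin

  nt <- length(R_series)
  stack <- array(0, dim = c(ny, nx, nt))
  edges <- vector("list", nt)
  for (k in seq_len(nt)) {
    R <- R_series[k]
    yc_center <- margin - sqrt(R^2 - (L / 2)^2)  # arc bulges upward
    half_ang <- asin((L / 2) / R)
    # distance from each pixel to the arc *segment* (the fiber ends at its
    # anchors): circle distance inside the angular span, endpoint distance
    # outside, so the drawn line has rounded caps rather than a spurious
    # circular tail beyond the adhesions
    dx <- outer(rep(1, ny), xc - x0)
    dy <- outer(yc - yc_center, rep(1, nx))
    d_circ <- abs(sqrt(dx^2 + dy^2) - R)
    within <- abs(atan2(dy, dx) - pi / 2) <= half_ang
    d_end1 <- sqrt(outer(rep(1, ny), xc - (x0 - L / 2))^2 +
                     outer(yc - margin, rep(1, nx))^2)
    d_end2 <- sqrt(outer(rep(1, ny), xc - (x0 + L / 2))^2 +
                     outer(yc - margin, rep(1, nx))^2)
    d <- ifelse(within, d_circ, pmin(d_end1, d_end2))
    img <- background + peak * exp(-d^2 / (2 * line_width^2))
    stack[, , k] <- img
    ang <- seq(pi / 2 - half_ang, pi / 2 + half_ang,
               length.out = n_edge_points)
    edges[[k]] <- tibble::tibble(frame = k,
                                 x = x0 + R * cos(ang),
                                 y = yc_center + R * sin(ang))
  }
  if (camera_noise) {
    shot <- array(stats::rpois(length(stack), lambda = stack), dim = dim(stack))
    stack <- shot + array(stats::rnorm(length(stack), 0, read_noise_sd),
                          dim = dim(stack))
    stack[stack < 0] <- 0
  }
  edges <- dplyr::bind_rows(edges)
  edges_noisy <- edges |>
    dplyr::mutate(x = .data$x + stats::rnorm(dplyr::n(), 0, cfg$edge_noise_sd),
                  y = .data$y + stats::rnorm(dplyr::n(), 0, cfg$edge_noise_sd))
  list(stack = stack, edges = edges, edges_noisy = edges_noisy,
       truth = list(R_series = R_series, chord = L, pixel_size = px,
                    x0 = x0, y_anchor = margin))
}

#' Write a kymograph to CSV with a JSON sidecar
#'
#' The matrix goes to `path` (positions in rows, frames in columns, with
#' `s` as the first column and times in the header); grids, state and pixel
#' size go to `paste0(path, ".json")` when the jsonlite package is
#' available.
#'
#' @param kym A `kymograph`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kym, path) {
  stopifnot(inherits(kym, "kymograph"))
  df <- data.frame(s = kym$s, kym$I)
  names(df) <- c("s_um", paste0("t_", kym$t, "_s"))
  utils::write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(s_um = kym$s, t_s = kym$t, state = kym$state,
                              pixel_size_um = kym$pixel_size, dt_s = kym$dt),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write an image stack as multi-page TIFF
#'
#' Requires the tiff package; intensities are rescaled to `[0, 1]` 16-bit.
#'
#' @param stack `[ny, nx, nt]` array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_arc_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the tiff package is required to write TIFF stacks", call. = FALSE)
  }
  mx <- max(stack)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    stack[dim(stack)[1]:1, , k] / mx  # image row 1 = top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
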