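#' Reproduce the full synthetic analysis chain
#'
#' Runs the canonical end-to-end analysis on synthetic cohorts: generates
#' noisy radius traces at `eps_levels` in extension and compression
#' (`n_per` replicates each), measures the post-step and plateau radii,
#' fits the short- and long-time strain-response slopes and the global
#' relaxation time, generates recruitment intensity cohorts and fits
#' `alpha` and `t_star`, derives the mechanical constants from the slopes,
#' and fits the local segment dynamics on `n_local` synthetic traces to
#' recover the local cortical tension. Every stochastic stage is seeded
#' from `seed`, so reruns are bit-identical.
#'
#' @param seed Integer master seed.
#' @param eps_levels Strain magnitudes of the cohorts.
#' @param n_per Replicates per strain level.
#' @param n_local Local-ODE traces.
#' @param cfg Base [generator_config()] (its seed is overridden).
#' @param local_truth True local parameters for the segment-trace cohort
#'   (a [local_ode_params()]); defaults to the study's fitted central
#'   values with `sigma0 = 0.035` nN/um.
#' @param quiet Suppress stage messages?
#' @return A tibble report with columns `quantity`, `estimate`, `sd`, `n`,
#'   `truth`, `unit` and attribute `manifest` (seed, package version,
#'   timestamp).
#' @export
run_reproduce <- function(seed = 1, eps_levels = c(0.1, 0.2, 0.3, 0.4),
                          n_per = 12, n_local = 20,
                          cfg = generator_config(),
                          local_truth = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1,
                      2 * length(eps_levels) * n_per + n_local + 8)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  p <- cfg$params

  # --- radius cohorts -------------------------------------------------
  say("stage 1/5: radius cohorts (", 2 * length(eps_levels) * n_per,
      " simulated bundles)")
  measure_one <- function(eps, direction) {
    cfg_i <- cfg
    cfg_i$seed <- next_seed()
    cfg_i$protocol <- if (direction == "extension") {
      stretch_protocol(eps, L0 = cfg$L0)
    } else {
      stretch_protocol(-eps, L0 = cfg$L0, prestretch_epsilon = 0.2,
                       prestretch_hold = 3600, direction = "compression")
    }
    g <- generate_radius_trace(cfg_i)
    tr <- g$trace
    base <- mean(tr$R[tr$t < -1])
    R0p <- tr$R[tr$t == 0]
    Rinf <- mean(tr$R[tr$t > max(tr$t) - 120])
    tibble::tibble(direction = direction,
                   eps = if (direction == "extension") eps else -eps,
                   R_base = base, R_step = R0p, R_inf = Rinf,
                   true_R0 = g$truth$R0)
  }
  radius_df <- tidyr::expand_grid(eps = eps_levels,
                                  rep = seq_len(n_per),
                                  direction = c("extension", "compression")) |>
    purrr::pmap(function(eps, rep, direction) measure_one(eps, direction)) |>
    dplyr::bind_rows()

  per_strain <- radius_df |>
    dplyr::group_by(.data$direction, .data$eps) |>
    dplyr::summarise(d_step = mean(.data$R_step - .data$R_base),
                     d_step_sd = stats::sd(.data$R_step - .data$R_base),
                     d_inf = mean(.data$R_inf - .data$R_base),
                     d_inf_sd = stats::sd(.data$R_inf - .data$R_base),
                     .groups = "drop")

  say("stage 2/5: strain-response slopes")
  ext <- dplyr::filter(per_strain, .data$direction == "extension")
  comp <- dplyr::filter(per_strain, .data$direction == "compression")
  fit_short_ext <- fit_linear_strain_response(ext, eps, d_step, d_step_sd)
  fit_short_comp <- fit_linear_strain_response(comp, eps, d_step, d_step_sd)
  fit_long_ext <- fit_linear_strain_response(ext, eps, d_inf, d_inf_sd)

  # global relaxation time from one mid-strain extension cohort trace
  cfg_t <- cfg
  cfg_t$seed <- next_seed()
  cfg_t$protocol <- stretch_protocol(0.2, L0 = cfg$L0)
  gt <- generate_radius_trace(cfg_t)
  post <- dplyr::filter(gt$trace, t >= 0)
  fit_T <- fit_exponential_relax(post, t, R, kind = "decay_to_plateau")

  # --- recruitment ----------------------------------------------------
  say("stage 3/5: recruitment cohorts")
  cfg_r <- cfg
  cfg_r$seed <- next_seed()
  rec <- generate_recruitment_cohort(cfg_r, eps_levels, n_per)
  rec_fits <- rec$traces |>
    dplyr::group_by(.data$eps, .data$rep) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_exponential_relax(d, t, dI_I0, kind = "decay_to_plateau")
      tibble::tibble(plateau = f$estimates$plateau,
                     init_slope = -f$estimates$amplitude / f$estimates$timescale)
    }) |>
    dplyr::ungroup()
  fit_rec <- fit_recruitment(rec_fits)

  # --- derived mechanics ---------------------------------------------
  say("stage 4/5: derived mechanical constants")
  short_slope <- fit_short_ext$estimates$slope
  long_slope <- fit_long_ext$estimates$slope
  mech <- tryCatch(
    derived_mechanics(short_slope, long_slope, p$E, cfg$A, cfg$L0, cfg$R0),
    error = function(e) {
      warning("cohort slopes inadmissible for the mechanical inversion (",
              conditionMessage(e), "); increase n_per. Mechanics reported ",
              "as NA", call. = FALSE)
      NULL
    })
  mval <- function(q) {
    if (is.null(mech)) NA_real_ else mech$value[mech$quantity == q]
  }

  # --- local segment fits --------------------------------------------
  say("stage 5/5: local segment dynamics (", n_local, " traces)")
  if (is.null(local_truth)) {
    local_truth <- local_ode_params(nu = 1 / 320, tau = 240, f = 0.19 * 0.2 / (2 * 0.035),
                                    Gamma = 0.8, sigma0 = 0.035, R0 = cfg$R0)
  }
  # segment traces start from rest (chi0 = 0) and are followed through the
  # plateau: the full-scale transient activates the motor nonlinearity that
  # identifies the parameters, mirroring a segment observed from the moment
  # of stretch. Noise is multiplicative, the intensity noise channel.
  t_loc <- seq(0, 3000, by = cfg$dt)
  clean <- simulate_local_chi(local_truth, chi0 = 0, t_grid = t_loc)
  local_fits <- purrr::map(seq_len(n_local), function(i) {
    withr::local_seed(next_seed())
    y <- clean$xi * (1 + stats::rnorm(length(t_loc), 0, cfg$intensity_cv))
    fit_local_ode(tibble::tibble(t = t_loc, y = y),
                  K0 = 0.19, eps_l = 0.2, R0 = cfg$R0)
  })
  sig0 <- purrr::map_dbl(local_fits, ~ .x$estimates$sigma0_identified)
  sig0_raw <- purrr::map_dbl(local_fits, ~ .x$estimates$sigma0)
  nuinv <- purrr::map_dbl(local_fits, ~ .x$estimates$nu_inv)

  truth_sigma <- p$sigma
  report <- tibble::tibble(
    quantity = c("short_slope_extension", "short_slope_compression",
                 "long_slope_extension", "relaxation_time_T",
                 "alpha", "t_star",
                 "sigma_pN_per_um", "lambda0", "K0", "k", "K0_over_k",
                 "local_sigma0_pN_per_um", "local_sigma0_raw_pN_per_um",
                 "local_nu_inv"),
    estimate = c(short_slope, fit_short_comp$estimates$slope, long_slope,
                 fit_T$estimates$timescale,
                 fit_rec$estimates$alpha, fit_rec$estimates$t_star,
                 mval("sigma_pN_per_um"), mval("lambda0"), mval("K0"),
                 mval("k"), mval("K0_over_k"),
                 1000 * mean(sig0), 1000 * mean(sig0_raw), mean(nuinv)),
    sd = c(fit_short_ext$sd[["slope"]], fit_short_comp$sd[["slope"]],
           fit_long_ext$sd[["slope"]], fit_T$sd[["timescale"]],
           fit_rec$sd[["alpha"]], fit_rec$sd[["t_star"]],
           NA, NA, NA, NA, NA, 1000 * stats::sd(sig0),
           1000 * stats::sd(sig0_raw), stats::sd(nuinv)),
    n = c(rep(length(eps_levels) * n_per, 3), nrow(post),
          rep(length(eps_levels) * n_per, 2), rep(NA, 5),
          n_local, n_local, n_local),
    truth = c(p$K0 * cfg$L0 / p$sigma, p$K0 * cfg$L0 / p$sigma,
              (p$k * p$K0 / (p$k + p$K0)) * cfg$L0 / p$sigma,
              NA,
              p$alpha, p$t_star,
              1000 * truth_sigma, truth_sigma * cfg$R0, p$K0, p$k,
              p$K0 / p$k,
              1000 * local_truth$sigma0, 1000 * local_truth$sigma0,
              1 / local_truth$nu),
    unit = c("um", "um", "um", "s", "1", "s", "pN/um", "nN", "nN/um",
             "nN/um", "1", "pN/um", "pN/um", "s"))
  attr(report, "manifest") <- list(seed = seed,
                                   package = as.character(utils::packageVersion("sfmech")),
                                   timestamp = format(Sys.time(), tz = "UTC"),
                                   eps_levels = eps_levels, n_per = n_per,
                                   n_local = n_local)
  report
}
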