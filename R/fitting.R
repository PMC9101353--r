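new_sf_fit <- function(estimates, sd, residual_norm, n, converged,
                       diagnostics = character(), method = "") {
  structure(list(estimates = estimates, sd = sd,
                 residual_norm = residual_norm, n = n, converged = converged,
                 diagnostics = diagnostics, method = method),
            class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("<sf_fit>", x$method, if (!x$converged) "(not converged)", "\n")
  est <- format(x$estimates, digits = 5)
  sds <- format(x$sd, digits = 3)
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-12s %s (sd %s)\n", nm, est[[nm]], sds[[nm]]))
  }
  cat(sprintf("  residual_norm %.4g, n = %d\n", x$residual_norm, x$n))
  if (length(x$diagnostics)) cat("  ", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a fit result
#'
#' @param x An `sf_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.sf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(unlist(x$estimates)),
                 std.error = unname(x$sd[names(x$estimates)]))
}

#' One-row summary of a fit result
#'
#' @param x An `sf_fit` object.
#' @param ... Unused.
#' @return A tibble with `residual_norm`, `n`, `converged`.
#' @exportS3Method generics::glance
glance.sf_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, n = x$n,
                 converged = x$converged)
}

#' Linear strain-response fit
#'
#' Weighted least-squares line through per-strain responses (for example
#' the radius jump `R0+ - R0` versus applied strain, whose slope estimates
#' `K0 L0 / sigma`).
#'
#' @param data Data frame of per-strain observations.
#' @param eps,y Columns (unquoted) holding strain and response (um).
#' @param errors Optional column of per-point standard deviations; weights
#'   are `1/errors^2`.
#' @return An `sf_fit` with estimates `slope` and `intercept`.
#' @export
#' @examples
#' d <- data.frame(e = c(0.1, 0.2, 0.3), r = 189.5 * c(0.1, 0.2, 0.3) + 66.2)
#' tidy(fit_linear_strain_response(d, e, r))
# vcov via summary.lm warns "essentially perfect fit" on exact data; that
# situation is legitimate here (noise-free synthetic input), so muffle it
vcov_quiet <- function(fit) {
  withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

fit_linear_strain_response <- function(data, eps, y, errors = NULL) {
  e <- rlang::eval_tidy(rlang::enquo(eps), data)
  yy <- rlang::eval_tidy(rlang::enquo(y), data)
  w <- rlang::eval_tidy(rlang::enquo(errors), data)
  if (length(unique(e)) < 2) stop("need at least 2 distinct strain values",
                                  call. = FALSE)
  wts <- if (is.null(w)) NULL else 1 / w^2
  fit <- stats::lm(yy ~ e, weights = wts)
  cf <- stats::coef(fit)
  n <- length(e)
  diagnostics <- character()
  if (n == 2) {
    sds <- c(slope = NA_real_, intercept = NA_real_)
    diagnostics <- "n = 2: exact interpolation, SD undefined"
  } else {
    se <- sqrt(diag(vcov_quiet(fit)))
    sds <- c(slope = unname(se[2]), intercept = unname(se[1]))
  }
  new_sf_fit(list(slope = unname(cf[2]), intercept = unname(cf[1])),
             sds, sum(stats::residuals(fit)^2), n, TRUE, diagnostics,
             "linear strain response (WLS)")
}

#' Exponential relaxation fit
#'
#' Fits either a single-exponential approach to a plateau,
#' `y = y_inf + (y0 - y_inf) exp(-t/T)` (`kind = "decay_to_plateau"`), or a
#' difference-of-exponentials overshoot,
#' `y = a (exp(-t/T1) - exp(-t/T2))` with `T1 > T2`
#' (`kind = "overshoot"`), reporting the slow time scale.
#'
#' @param data Data frame with time and signal columns.
#' @param t,y Columns (unquoted): time (s) and signal.
#' @param kind Model form.
#' @return An `sf_fit`. For `decay_to_plateau` the estimates are
#'   `amplitude` (`y0 - y_inf`), `timescale` (s) and `plateau`; for
#'   `overshoot`, `amplitude` (`a`), `timescale` (the slow `T1`) and
#'   `timescale_fast` (`T2`).
#' @export
fit_exponential_relax <- function(data, t, y,
                                  kind = c("decay_to_plateau", "overshoot")) {
  kind <- match.arg(kind)
  tt <- rlang::eval_tidy(rlang::enquo(t), data)
  yy <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(tt) & is.finite(yy)
  tt <- tt[ok]; yy <- yy[ok]
  n <- length(tt)
  if (n < 10) warning("fewer than 10 samples: time-scale fit is unreliable",
                      call. = FALSE)
  span <- diff(range(tt))
  df <- data.frame(tt = tt - min(tt), yy = yy)

  # nls.lm rather than nlsLM: the latter refuses zero-residual (exact) data
  # with a "singular gradient" error from its final nls() call
  fit_one <- function(resid_fn, start, lower) {
    tryCatch({
      f <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      if (f$info %in% 1:4) f else NULL
    }, error = function(e) NULL)
  }

  if (kind == "decay_to_plateau") {
    tail_n <- max(3, round(n / 5))
    y_inf0 <- mean(utils::tail(yy, tail_n))
    y00 <- yy[1]
    starts <- lapply(c(span / 10, span / 3, span), function(Ts) {
      list(y_inf = y_inf0, y0 = y00, T = Ts)
    })
    resid_fn <- function(p) {
      df$yy - (p$y_inf + (p$y0 - p$y_inf) * exp(-df$tt / p$T))
    }
    best <- NULL
    for (st in starts) {
      f <- fit_one(resid_fn, st, c(-Inf, -Inf, 1e-6))
      if (!is.null(f) &&
          (is.null(best) || stats::deviance(f) < stats::deviance(best))) best <- f
    }
    if (is.null(best)) {
      return(new_sf_fit(list(amplitude = NA_real_, timescale = NA_real_,
                             plateau = NA_real_),
                        c(amplitude = NA, timescale = NA, plateau = NA),
                        Inf, n, FALSE, "all starts failed", "exponential relaxation"))
    }
    cf <- stats::coef(best)
    se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) rep(NA_real_, 3))
    diagnostics <- character()
    if (span < 2 * cf[["T"]]) {
      diagnostics <- "data span under two fitted time scales"
      warning("data span under two fitted time scales", call. = FALSE)
    }
    new_sf_fit(list(amplitude = cf[["y0"]] - cf[["y_inf"]],
                    timescale = cf[["T"]], plateau = cf[["y_inf"]]),
               c(amplitude = sqrt(sum(se[1:2]^2, na.rm = TRUE)),
                 timescale = unname(se[3]), plateau = unname(se[1])),
               stats::deviance(best), n, TRUE, diagnostics,
               "exponential relaxation to plateau")
  } else {
    # overshoot: peak location guides the start values
    ipk <- which.max(abs(yy - yy[1]))
    tpk <- max(df$tt[ipk], span / 50)
    grid <- expand.grid(T1 = c(span / 6, span / 3, span),
                        T2 = c(tpk / 3, tpk, 3 * tpk))
    resid_fn <- function(p) {
      df$yy - p$a * (exp(-df$tt / p$T1) - exp(-df$tt / p$T2))
    }
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      st <- list(a = yy[ipk] / 0.5, T1 = grid$T1[g], T2 = grid$T2[g])
      f <- fit_one(resid_fn, st, c(-Inf, 1e-6, 1e-6))
      if (!is.null(f) &&
          (is.null(best) || stats::deviance(f) < stats::deviance(best))) best <- f
    }
    if (is.null(best)) {
      return(new_sf_fit(list(amplitude = NA_real_, timescale = NA_real_,
                             timescale_fast = NA_real_),
                        c(amplitude = NA, timescale = NA, timescale_fast = NA),
                        Inf, n, FALSE, "all starts failed", "overshoot relaxation"))
    }
    cf <- stats::coef(best)
    se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) rep(NA_real_, 3))
    a <- cf[["a"]]; T1 <- cf[["T1"]]; T2 <- cf[["T2"]]
    seT <- se[2:3]
    if (T1 < T2) {  # reorder so T1 is the slow scale; amplitude flips sign
      tmp <- T1; T1 <- T2; T2 <- tmp; a <- -a; seT <- rev(seT)
    }
    new_sf_fit(list(amplitude = a, timescale = T1, timescale_fast = T2),
               c(amplitude = unname(se[1]), timescale = unname(seT[1]),
                 timescale_fast = unname(seT[2])),
               stats::deviance(best), n, TRUE, character(),
               "difference-of-exponentials overshoot")
  }
}

#' Recruitment kinetics from plateau and initial-slope cohorts
#'
#' The recruitment index `alpha` is the slope of the steady-state intensity
#' gain versus strain through the origin, `(DeltaI/I0)_inf = alpha * eps`;
#' the recruitment rate `alpha/t_star` is the slope of the initial rate
#' versus strain, `d/dt(DeltaI/I0)|_0 = (alpha/t_star) * eps`. The time
#' scale follows as `t_star = alpha / (alpha/t_star)`.
#'
#' @param data Data frame with columns `eps`, `plateau` and `init_slope`
#'   (per strain level or per trace).
#' @return An `sf_fit` with estimates `alpha`, `rate` (1/s) and `t_star` (s).
#' @export
#' @examples
#' d <- data.frame(eps = c(0.1, 0.2, 0.3), plateau = 0.64 * c(0.1, 0.2, 0.3),
#'                 init_slope = 0.64 / 427 * c(0.1, 0.2, 0.3))
#' tidy(fit_recruitment(d))
fit_recruitment <- function(data) {
  stopifnot(all(c("eps", "plateau", "init_slope") %in% names(data)))
  if (length(unique(data$eps)) < 3) {
    stop("need at least 3 strain levels", call. = FALSE)
  }
  f1 <- stats::lm(plateau ~ 0 + eps, data = data)
  f2 <- stats::lm(init_slope ~ 0 + eps, data = data)
  alpha <- unname(stats::coef(f1))
  rate <- unname(stats::coef(f2))
  if (rate <= 0) stop("fitted recruitment rate alpha/t* is non-positive",
                      call. = FALSE)
  sd_a <- sqrt(vcov_quiet(f1)[1, 1])
  sd_r <- sqrt(vcov_quiet(f2)[1, 1])
  t_star <- alpha / rate
  sd_t <- abs(t_star) * sqrt((sd_a / alpha)^2 + (sd_r / rate)^2)
  new_sf_fit(list(alpha = alpha, rate = rate, t_star = t_star),
             c(alpha = sd_a, rate = sd_r, t_star = sd_t),
             sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2),
             nrow(data), TRUE, character(),
             "recruitment index and rate (regressions through the origin)")
}

#' Least-squares fit of the local segment dynamics to an intensity trace
#'
#' Estimates the four dimensionless/time groups `(nu, tau, f, Gamma)` of the
#' local cortical-tension dynamics by least squares between the integrated
#' model (mapped through `xi = chi/tau` and a linear intensity-to-xi
#' proportionality) and a normalised relative intensity trace. The initial
#' condition `chi(0) = tau * xi(0)` and the continuation start for the
#' implicit rate come from smoothed first derivatives of the trace
#' (local quadratic Savitzky-Golay smoothing). A log-spaced multi-start
#' grid over the bounds guards the non-convex objective. The fitted `f` is
#' mapped back to physical estimates via `sigma0 = K0 eps_l / (2 f)` and
#' `lambda0 = sigma0 R0`.
#'
#' @param trace Data frame with columns `t` (s, uniform) and `y`
#'   (normalised relative intensity).
#' @param mapping Intensity-to-xi proportionality constant (default 1).
#' @param K0 Main spring constant used for the back-mapping (nN/um).
#' @param eps_l Local strain used for the back-mapping.
#' @param R0 Unstretched radius used for the back-mapping (um).
#' @param bounds Named list of length-2 ranges for `nu_inv` (s), `tau` (s),
#'   `f`, `Gamma`.
#' @param n_starts Starts per parameter (log-spaced), so `n_starts^4` in all.
#' @param smooth_window Savitzky-Golay window (odd number of samples).
#' @return An `sf_fit` with estimates `nu`, `nu_inv`, `tau`, `f`, `Gamma`,
#'   `sigma0` (nN/um), `lambda0` (nN), plus `f_identified` and
#'   `sigma0_identified`. The latter two replace the raw `f` by the
#'   statistically identified combination `f/(Gamma nu tau)` closed with
#'   the structural identity `Gamma nu tau = 1` (exact for any parameter
#'   set derived from one physical device); in the weak-motor regime where
#'   raw `f` lies in a near-flat likelihood valley, these remain stable.
#'   Diagnostics record the `Gamma*nu*tau` identity value and any bounds
#'   hit.
#' @export
fit_local_ode <- function(trace, mapping = 1, K0 = 0.19, eps_l = 0.2,
                          R0 = 65.6,
                          bounds = list(nu_inv = c(50, 2000),
                                        tau = c(50, 1000),
                                        f = c(0.1, 20),
                                        Gamma = c(0.05, 5)),
                          n_starts = 3, smooth_window = 11) {
  stopifnot(all(c("t", "y") %in% names(trace)))
  tt <- trace$t; yy <- trace$y
  n <- length(tt)
  if (n < 50) stop("trace must have at least 50 samples", call. = FALSE)
  dt <- stats::median(diff(tt))

  # smoothed signal and first derivative for the initial conditions
  win <- min(smooth_window, if (n %% 2 == 1) n else n - 1)
  if (win %% 2 == 0) win <- win - 1
  ys <- signal::sgolayfilt(yy, p = 2, n = win)
  dys <- signal::sgolayfilt(yy, p = 2, n = win, m = 1) / dt
  xi0 <- ys[1] / mapping
  xidot0 <- dys[1] / mapping

  degenerate <- stats::sd(yy) < 1e-12 || abs(xi0) < 1e-12
  lb <- log(c(1 / bounds$nu_inv[2], bounds$tau[1], bounds$f[1], bounds$Gamma[1]))
  ub <- log(c(1 / bounds$nu_inv[1], bounds$tau[2], bounds$f[2], bounds$Gamma[2]))

  t0 <- tt - tt[1]
  objective <- function(lp) {
    nu <- exp(lp[1]); tau <- exp(lp[2]); f <- exp(lp[3]); G <- exp(lp[4])
    chi0 <- tau * xi0
    res <- .cpp_integrate_chi(t0, nu, f, G, chi0, tau * xidot0, 2)
    if (res$failed) return(1e10)
    model <- mapping * res$chi / tau
    sum((yy - model)^2)
  }

  axis_starts <- function(b) exp(seq(log(b[1]), log(b[2]), length.out = n_starts + 2))[2:(n_starts + 1)]
  grid <- expand.grid(nu = 1 / axis_starts(bounds$nu_inv),
                      tau = axis_starts(bounds$tau),
                      f = axis_starts(bounds$f),
                      Gamma = axis_starts(bounds$Gamma))
  # screen the full grid with one objective evaluation per start, then
  # polish only the most promising starts with nlminb
  screen <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(objective(log(as.numeric(grid[i, ]))), error = function(e) Inf)
  }, numeric(1))
  keep <- order(screen)[seq_len(min(6L, nrow(grid)))]
  best <- NULL
  for (i in keep) {
    st <- log(as.numeric(grid[i, ]))
    opt <- tryCatch(
      stats::nlminb(st, objective, lower = lb, upper = ub,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        (is.null(best) || opt$objective < best$objective)) best <- opt
  }
  if (is.null(best)) {
    return(new_sf_fit(list(nu = NA_real_, nu_inv = NA_real_, tau = NA_real_,
                           f = NA_real_, Gamma = NA_real_, sigma0 = NA_real_,
                           lambda0 = NA_real_),
                      stats::setNames(rep(NA_real_, 7),
                                      c("nu", "nu_inv", "tau", "f", "Gamma",
                                        "sigma0", "lambda0")),
                      Inf, n, FALSE, "all starts failed", "local ODE fit"))
  }

  p <- exp(best$par)
  names(p) <- c("nu", "tau", "f", "Gamma")
  ssr <- best$objective

  # covariance from the numerical Jacobian of the model curve
  model_at <- function(lp) {
    nu <- exp(lp[1]); tau <- exp(lp[2]); f <- exp(lp[3]); G <- exp(lp[4])
    res <- .cpp_integrate_chi(t0, nu, f, G, tau * xi0, tau * xidot0, 2)
    mapping * res$chi / tau
  }
  J <- matrix(0, n, 4)
  h <- 1e-5
  m0 <- model_at(best$par)
  for (j in 1:4) {
    lp <- best$par; lp[j] <- lp[j] + h
    J[, j] <- (model_at(lp) - m0) / h   # d model / d log(param)
  }
  sigma2 <- ssr / max(1, n - 4)
  cov_lp <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  sd_log <- if (is.null(cov_lp)) rep(NA_real_, 4) else sqrt(pmax(diag(cov_lp), 0))
  sd_p <- p * sd_log   # delta method back from log scale

  sigma0 <- K0 * eps_l / (2 * p[["f"]])
  lambda0 <- sigma0 * R0
  sd_sigma0 <- sigma0 * sd_log[3]

  # Identified back-mapping. In the weak-motor regime the trace determines
  # the combination f/(Gamma nu tau) (the xi plateau) and nu (the rate)
  # sharply, while f alone sits in a near-flat likelihood valley. For any
  # parameter set derived from one physical device the product
  # Gamma*nu*tau is identically 1, so f_id = f/(Gamma nu tau) is the
  # physically closed, statistically identified estimate of f.
  f_id <- p[["f"]] / (p[["Gamma"]] * p[["nu"]] * p[["tau"]])
  sigma0_id <- K0 * eps_l / (2 * f_id)
  # delta method on log f_id = log f - log Gamma - log nu - log tau
  v_id <- c(-1, -1, 1, -1)  # order (nu, tau, f, Gamma)
  sd_log_fid <- if (is.null(cov_lp)) NA_real_ else
    sqrt(max(0, drop(t(v_id) %*% cov_lp %*% v_id)))
  sd_sigma0_id <- sigma0_id * sd_log_fid

  at_bound <- abs(best$par - lb) < 1e-6 | abs(best$par - ub) < 1e-6
  diagnostics <- sprintf("Gamma*nu*tau = %.4g", p[["Gamma"]] * p[["nu"]] * p[["tau"]])
  if (any(at_bound)) {
    diagnostics <- c(diagnostics, paste("bounds hit:",
                                        paste(names(p)[at_bound], collapse = ", ")))
  }
  if (degenerate) {
    diagnostics <- c(diagnostics,
                     "flat trace: f ~ 0, other parameters unidentifiable")
  }

  new_sf_fit(list(nu = p[["nu"]], nu_inv = 1 / p[["nu"]], tau = p[["tau"]],
                  f = if (degenerate) 0 else p[["f"]], Gamma = p[["Gamma"]],
                  sigma0 = sigma0, lambda0 = lambda0,
                  f_identified = f_id, sigma0_identified = sigma0_id),
             c(nu = sd_p[1], nu_inv = sd_log[1] / p[["nu"]], tau = sd_p[2],
               f = sd_p[3], Gamma = sd_p[4], sigma0 = sd_sigma0,
               lambda0 = sd_sigma0 * R0,
               f_identified = f_id * sd_log_fid,
               sigma0_identified = sd_sigma0_id),
             ssr, n, best$convergence == 0, diagnostics,
             "local ODE least squares (multi-start)")
}

#' Derived mechanical constants from the measured strain-response slopes
#'
#' Combines the short-time slope (`K0 L0 / sigma = E A / sigma`), the
#' long-time extension slope (`k K0/(k + K0) L0 / sigma`) and the printed
#' bundle geometry into the full set of mechanical constants:
#' `sigma = E A / short_slope`, `lambda0 = sigma R0`, `K0 = E A / L0`,
#' `K0/k = short_slope/long_slope - 1`, `k = K0 / (K0/k)`, and the fiber
#' rigidity to surface tension length `lf = E A / sigma` (equal to the
#' short-time slope).
#'
#' @param short_slope Short-time radius-strain slope (um).
#' @param long_slope Long-time extension radius-strain slope (um), must be
#'   smaller than `short_slope`.
#' @param E Young's modulus (nN/um^2).
#' @param A Cross-sectional area (um^2).
#' @param L0 Bundle length (um).
#' @param R0 Unperturbed radius (um).
#' @return A tibble with columns `quantity`, `value`, `unit`: rows `sigma`
#'   (nN/um), `sigma_pN_per_um` (pN/um), `lambda0` (nN), `K0`, `k` (nN/um),
#'   `K0_over_k` (1) and `lf` (um).
#' @export
#' @examples
#' derived_mechanics(189.5, 104.9, 11.3, 0.6, 36.47, 65.60)
derived_mechanics <- function(short_slope, long_slope, E, A, L0, R0) {
  stopifnot(short_slope > 0, long_slope > 0, E > 0, A > 0, L0 > 0, R0 > 0)
  if (long_slope >= short_slope) {
    stop("model inconsistency: long-time slope must be smaller than the ",
         "short-time slope", call. = FALSE)
  }
  sigma <- E * A / short_slope
  K0 <- E * A / L0
  K0_over_k <- short_slope / long_slope - 1
  k <- K0 / K0_over_k
  tibble::tibble(
    quantity = c("sigma", "sigma_pN_per_um", "lambda0", "K0", "k",
                 "K0_over_k", "lf"),
    value = c(sigma, 1000 * sigma, sigma * R0, K0, k, K0_over_k,
              E * A / sigma),
    unit = c("nN/um", "pN/um", "nN", "nN/um", "nN/um", "1", "um"))
}
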