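#' Gaussian motor-element force
#'
#' Averaged force-velocity law of the myosin ensemble in the bundle: the
#' force is maximal (`lambda0`, the stall force) at zero elongation rate and
#' decays as a Gaussian with velocity scale `V`,
#' `F(rate) = lambda0 * exp(-rate^2 / V^2)`.
#'
#' @param rate Signed elongation rate (um/s); may be a vector.
#' @param lambda0 Stall force (nN).
#' @param V Velocity scale (um/s).
#' @return Motor force (nN), in `(0, lambda0]`.
#' @export
#' @examples
#' motor_force(0, 2.3, 0.1)        # stall force
#' motor_force(0.1, 1, 0.1)        # exp(-1)
motor_force <- function(rate, lambda0, V) {
  if (!is.numeric(V) || length(V) != 1 || V <= 0) {
    stop("`V` must be a single positive number", call. = FALSE)
  }
  if (lambda0 <= 0) stop("`lambda0` must be positive", call. = FALSE)
  lambda0 * exp(-(rate / V)^2)
}

#' Solve the implicit elongation-rate equation of the dissipative branch
#'
#' The dashpot/motor branch of the bundle model obeys
#' `k * delta2 + gamma * d(delta2)/dt + lambda0 * exp(-(rate/V)^2) = lambda`
#' with `lambda = K_now * (delta_l - delta2) + lambda0`. This solves the
#' scalar implicit equation for the rate. When the dissipation is weak
#' enough (`gamma * V <= sqrt(2) exp(-1/2) * lambda0`) the equation can have
#' several roots; the one nearest `prev_rate` is returned and a warning is
#' raised.
#'
#' @param delta2 Current elongation of the dissipative branch (um).
#' @param delta_l Total bundle elongation (um).
#' @param params A [mech_params()] object.
#' @param K_now Current main-spring constant (nN/um); defaults to
#'   `params$K0`.
#' @param prev_rate Previous rate, used for root continuation (um/s).
#' @return The rate (um/s), with attribute `multi_root` (logical).
#' @export
solve_rate_implicit <- function(delta2, delta_l, params, K_now = params$K0,
                                prev_rate = 0) {
  validate_mech_params(params)
  if (K_now <= 0) stop("`K_now` must be positive", call. = FALSE)
  rhs <- K_now * (delta_l - delta2) + params$lambda0 - params$k * delta2
  sol <- .cpp_solve_rate(rhs, params$gamma, params$lambda0, params$V, prev_rate)
  if (sol$failed) {
    stop("no real rate root found (rhs = ", format(rhs), ", gamma = ",
         format(params$gamma), ", lambda0 = ", format(params$lambda0),
         ", V = ", format(params$V), ")", call. = FALSE)
  }
  if (sol$multi_root) {
    warning("multiple rate roots; returning the root nearest prev_rate",
            call. = FALSE)
  }
  structure(sol$rate, multi_root = sol$multi_root)
}

#' Strain-gated main elastic constant
#'
#' The main spring softens under extension as fresh actin is recruited:
#' `K(eps, t) = K0 * (1 - alpha * eps * (1 - exp(-t/t_star)))` for
#' `eps > 0`, while under compression it keeps its resting value `K0`. The
#' steady-state value under extension is `K_inf = (1 - alpha * eps) * K0`.
#'
#' @param epsilon Applied strain (signed scalar).
#' @param t Time since the stretch was applied (s); may be a vector.
#' @param params A [mech_params()] object (uses `K0`, `alpha`, `t_star`).
#' @return K at the requested times (nN/um).
#' @export
elastic_constant_t <- function(epsilon, t, params) {
  stopifnot(all(t >= 0))
  if (epsilon <= 0) return(rep(params$K0, length(t)))
  K <- params$K0 * (1 - params$alpha * epsilon * (1 - exp(-t / params$t_star)))
  if (any(K <= 0)) {
    stop("model validity: alpha * epsilon >= 1 drives K non-positive",
         call. = FALSE)
  }
  K
}

#' Radius of curvature immediately after the stretch
#'
#' Short-time elastic limit: before any viscous or recruitment response the
#' whole elongation is carried by the main spring, so
#' `R0+ = (K0 L0 / sigma) * eps + R0`.
#'
#' @param epsilon Applied strain (signed; for compression, measured from the
#'   prestretched radius).
#' @param params A [mech_params()] object.
#' @param L0 Bundle length (um).
#' @param R0 Baseline radius (um) the strain is measured from.
#' @return Predicted radius just after the step (um).
#' @export
radius_short_time <- function(epsilon, params, L0, R0) {
  stopifnot(L0 > 0, R0 > 0)
  (params$K0 * L0 / params$sigma) * epsilon + R0
}

#' Radius of curvature at long times under constant stretch
#'
#' Under compression the bundle relaxes as a Maxwell material back to
#' `R0 = lambda0 / sigma`. Under extension the two springs in series set the
#' plateau; with recruitment softening of the main spring the radius gains a
#' quadratic strain dependence:
#' `R_inf = R0 + (k K0 / (k + K0)) (L0 / sigma) (1 - alpha k / (k + K0) eps) eps`.
#'
#' @inheritParams radius_short_time
#' @return Predicted steady-state radius (um).
#' @export
radius_long_time <- function(epsilon, params, L0, R0) {
  stopifnot(L0 > 0, R0 > 0)
  if (params$k + params$K0 <= 0) stop("k + K0 must be positive", call. = FALSE)
  if (epsilon < 0) return(R0)
  kser <- params$k * params$K0 / (params$k + params$K0)
  frac <- params$k / (params$k + params$K0)
  R0 + kser * (L0 / params$sigma) * (1 - params$alpha * frac * epsilon) * epsilon
}

#' Fractional intensity gain from strain-triggered actin recruitment
#'
#' Under extension the bundle recruits fresh actin with saturating kinetics
#' `DeltaI/I0 = alpha * eps * (1 - exp(-t/t_star))`; the initial rate is
#' `alpha * eps / t_star`. Recruitment is gated off under compression, where
#' the model returns 0 and flags the domain.
#'
#' @param epsilon Applied strain.
#' @param t Time since the stretch (s); may be a vector.
#' @param alpha Recruitment index.
#' @param t_star Recruitment time scale (s).
#' @return `DeltaI/I0` at the requested times; attribute `domain` is
#'   `"compression"` when `epsilon <= 0`.
#' @export
#' @examples
#' intensity_model(0.25, Inf, 0.64, 427)  # plateau alpha * eps = 0.16
intensity_model <- function(epsilon, t, alpha, t_star) {
  stopifnot(all(t >= 0), t_star > 0)
  if (epsilon <= 0) {
    return(structure(rep(0, length(t)), domain = "compression"))
  }
  alpha * epsilon * (1 - exp(-t / t_star))
}

#' Relative change in F-actin linear density
#'
#' The linear density is total intensity per bundle length,
#' `rho = I / L`, so the fractional density change after the response is
#' `rho_inf / rho_0 - 1 = I_ratio / (1 + eps_len) - 1` where `I_ratio` is
#' the total-intensity ratio and `eps_len` the length strain.
#'
#' @param I_ratio Total-intensity ratio `I_inf / I0` (`> 0`).
#' @param eps_len Length strain of the bundle (`1 + eps_len > 0`).
#' @return Fractional density change (dimensionless).
#' @seealso [elastic_reference()] for the purely elastic reference line.
#' @export
density_variation <- function(I_ratio, eps_len) {
  stopifnot(all(I_ratio > 0))
  if (any(1 + eps_len <= 0)) stop("1 + eps_len must be positive", call. = FALSE)
  I_ratio / (1 + eps_len) - 1
}

#' Elastic reference line for the density-strain relation
#'
#' For a purely elastic bundle at constant protein content the linearised
#' density change is `-eps`.
#'
#' @param epsilon Applied strain.
#' @return `-epsilon`.
#' @export
elastic_reference <- function(epsilon) -epsilon

#' Simulate the bundle model through a stretch protocol
#'
#' Integrates the three-element bundle model through the full strain history
#' of `protocol` (optional prestretch ramp and hold, then the main step as a
#' linear ramp at the protocol rate) and samples the response on `t_grid`,
#' where `t = 0` is the end of the main ramp (the start of the observation).
#' At every internal step the implicit elongation-rate equation is solved by
#' root continuation; the step is refined until the trajectory changes by
#' less than `tol` (relative) under grid doubling.
#'
#' With `strain_gate = TRUE` the elastic constants follow the strain-gated
#' law: under compression the secondary spring disengages (`k = 0`,
#' `K = K0`, Maxwell branch); under extension `k` stays engaged and the main
#' spring softens with recruitment, `K(eps, t) = K0 (1 - alpha eps (1 -
#' exp(-t/t_star)))`.
#'
#' @param protocol A [stretch_protocol()].
#' @param params A [mech_params()] object.
#' @param t_grid Observation times (s, strictly increasing). `t = 0` is the
#'   end of the main ramp; negative times sample the strain history
#'   (prestretch and baseline), with equilibrium before it starts.
#' @param strain_gate Apply the strain-dependent gating of `K` and `k`?
#' @param tol Relative convergence tolerance for step refinement.
#' @return A `bundle_trace` tibble with columns `t`, `delta1`, `delta2`,
#'   `delta_l` (um), `lam` (nN), `R` (um), `K_t` (nN/um), and attributes
#'   `R0` (the unperturbed radius `lambda0/sigma`) and `params`.
#' @export
#' @examples
#' tr <- simulate_global(stretch_protocol(0.2), study_params(),
#'                       t_grid = seq(0, 900, by = 10))
#' head(tr)
simulate_global <- function(protocol, params, t_grid, strain_gate = TRUE,
                            tol = 1e-6) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  validate_mech_params(params)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("`t_grid` must be strictly increasing", call. = FALSE)
  }
  L0 <- protocol$L0
  eps_pre <- protocol$prestretch_epsilon
  L_ref <- L0 * (1 + eps_pre)          # compression strain counts from here
  dl_pre <- eps_pre * L0
  dl_step <- protocol$epsilon * L_ref
  d_pre <- if (eps_pre > 0) dl_pre / protocol$rate else 0
  d_main <- abs(dl_step) / protocol$rate

  # timeline, internal clock u with u = 0 at the end of the main ramp
  u_hist_start <- -(d_pre + protocol$prestretch_hold + d_main)
  u_main_start <- -d_main

  delta_l_fun <- function(u) {
    out <- numeric(length(u))
    if (eps_pre > 0) {
      ramp1 <- u <= u_main_start
      u1 <- u[ramp1] - u_hist_start
      out[ramp1] <- pmin(pmax(u1, 0) * protocol$rate, dl_pre)
    }
    main <- u > u_main_start
    out[main] <- dl_pre +
      sign(dl_step) * pmin(u[main] - u_main_start, d_main) * protocol$rate
    out
  }

  K_fun <- function(u) {
    if (!strain_gate) return(rep(params$K0, length(u)))
    out <- rep(params$K0, length(u))
    if (eps_pre > 0) {
      # recruitment softening during the prestretch hold, clock from the
      # end of the prestretch ramp
      hold <- u > (u_hist_start + d_pre) & u <= u_main_start
      th <- u[hold] - (u_hist_start + d_pre)
      out[hold] <- elastic_constant_t(eps_pre, th, params)
    }
    main <- u > u_main_start
    if (protocol$epsilon > 0) {
      tm <- pmax(u[main], 0)
      out[main] <- elastic_constant_t(protocol$epsilon, tm, params)
    }
    out
  }

  k_fun <- function(u) {
    if (!strain_gate) return(rep(params$k, length(u)))
    out <- numeric(length(u))
    if (eps_pre > 0) out[u <= u_main_start] <- params$k
    main <- u > u_main_start
    out[main] <- if (protocol$epsilon > 0) params$k else 0
    out
  }

  u_start <- min(u_hist_start, min(t_grid))
  base_grid <- function(n_ramp, h_hold) {
    u <- c(u_start, u_hist_start)
    if (eps_pre > 0) {
      u <- c(u, seq(u_hist_start, u_hist_start + d_pre, length.out = n_ramp),
             seq(u_hist_start + d_pre, u_main_start,
                 by = max(h_hold, 1e-6)))
    }
    if (d_main > 0) {
      u <- c(u, seq(u_main_start, 0, length.out = n_ramp))
    }
    if (max(t_grid) > 0) {
      u <- c(u, seq(0, max(t_grid), by = max(h_hold, 1e-6)))
    }
    sort(unique(c(u, t_grid, 0, max(t_grid))))
  }

  integrate_on <- function(u) {
    res <- .cpp_integrate_bundle(u, delta_l_fun(u), K_fun(u), k_fun(u),
                                 params$gamma, params$lambda0, params$V,
                                 0, 0)
    if (res$failed) {
      last_ok <- u[max(which(is.finite(res$delta2)))]
      stop("bundle integration failed; last valid time ", format(last_ok),
           " s", call. = FALSE)
    }
    if (res$multi_root) {
      warning("multiple rate roots encountered during integration; ",
              "continuation root used", call. = FALSE)
    }
    stats::approx(u, res$delta2, xout = t_grid)$y
  }

  h <- min(2, 0.02 * params$gamma / params$K0)
  d2 <- integrate_on(base_grid(40, h))
  for (i in 1:8) {
    h <- h / 2
    d2_new <- integrate_on(base_grid(40 * 2^i, h))
    rel <- max(abs(d2_new - d2)) / max(1e-12, max(abs(d2_new)))
    d2 <- d2_new
    if (rel < tol) break
  }

  dl <- delta_l_fun(t_grid)
  Kt <- K_fun(t_grid)
  d1 <- dl - d2
  lam <- Kt * d1 + params$lambda0
  if (any(!is.finite(lam))) stop("non-finite state in simulation", call. = FALSE)
  out <- tibble::tibble(t = t_grid, delta1 = d1, delta2 = d2, delta_l = dl,
                        lam = lam, R = lam / params$sigma, K_t = Kt)
  class(out) <- c("bundle_trace", class(out))
  attr(out, "R0") <- params$lambda0 / params$sigma
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  out
}
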