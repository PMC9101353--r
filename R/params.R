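#' Global mechanical parameters of a stress-fiber bundle
#'
#' Bundles the physical constants of the three-element active bundle model:
#' a main spring (stiffness `K0`) in series with a parallel arrangement of a
#' secondary spring (`k`), a dashpot (`gamma`) and a Gaussian myosin motor
#' element (stall force `lambda0`, velocity scale `V`). The cortical tension
#' `sigma` converts line tension into a radius of curvature through the
#' tension balance R = lambda / sigma. `E` and `A` are the Young's modulus
#' and cross-sectional area of the bundle; `alpha` and `t_star` are the
#' fresh-actin recruitment index and its time scale.
#'
#' Internal units are micrometres, seconds and nanonewtons throughout
#' (so `sigma` is in nN/um; multiply by 1000 for pN/um).
#'
#' @param K0 Main spring constant (nN/um).
#' @param k Secondary spring constant (nN/um), `>= 0`.
#' @param gamma Dissipation constant (nN s/um).
#' @param lambda0 Initial line tension and motor stall force (nN).
#' @param V Motor velocity scale (um/s).
#' @param sigma Cortical tension (nN/um).
#' @param E Young's modulus (nN/um^2).
#' @param A Cross-sectional area (um^2).
#' @param alpha Recruitment index (dimensionless, `>= 0`).
#' @param t_star Recruitment time scale (s).
#' @return An object of class `mech_params` (a named list).
#' @seealso [mech_params_from_EA()] for the `K0 = E A / L0` construction,
#'   [study_params()] for the study's reference values.
#' @export
#' @examples
#' p <- study_params()
#' p$K0
mech_params <- function(K0, k, gamma, lambda0, V, sigma, E, A,
                        alpha = 0, t_star = 427) {
  p <- list(K0 = K0, k = k, gamma = gamma, lambda0 = lambda0, V = V,
            sigma = sigma, E = E, A = A, alpha = alpha, t_star = t_star)
  validate_mech_params(p)
  structure(p, class = "mech_params")
}

validate_mech_params <- function(p) {
  pos <- c("K0", "gamma", "lambda0", "V", "sigma", "E", "A", "t_star")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("`", nm, "` must be a single strictly positive number", call. = FALSE)
    }
  }
  if (!is.numeric(p$k) || p$k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (!is.numeric(p$alpha) || p$alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  invisible(p)
}

#' Construct mechanical parameters from modulus, area and length
#'
#' Sets `K0 = E * A / L0`, the extensional stiffness of a uniform rod of
#' modulus `E`, area `A` and rest length `L0`.
#'
#' @inheritParams mech_params
#' @param L0 Rest length of the bundle (um).
#' @param ... Remaining arguments passed to [mech_params()].
#' @return A `mech_params` object with `K0` consistent with `E A / L0`.
#' @export
mech_params_from_EA <- function(E, A, L0, ...) {
  mech_params(K0 = E * A / L0, E = E, A = A, ...)
}

#' Reference parameter set of the study system
#'
#' Mechanical constants measured for peripheral stress fibers of RPE-1 cells
#' on H-shaped micropatterns: `E = 11.3` nN/um^2, `A = 0.6` um^2,
#' `L0 = 36.47` um (hence `K0 = E A / L0 = 0.186` nN/um), secondary spring
#' `k = 0.23` nN/um, cortical tension `sigma = 0.0357` nN/um, line tension
#' `lambda0 = 2.3` nN, recruitment index `alpha = 0.64` with time scale
#' `t_star = 427` s. The dissipation constant is set by the observed ~300 s
#' passive relaxation time as `gamma = 2 K0 * 300`; the motor velocity scale
#' defaults to 0.1 um/s.
#'
#' @param nu_inv Passive relaxation time scale `gamma / (2 K0)` (s).
#' @param V Motor velocity scale (um/s).
#' @return A `mech_params` object.
#' @export
study_params <- function(nu_inv = 300, V = 0.1) {
  E <- 11.3; A <- 0.6; L0 <- 36.47
  K0 <- E * A / L0
  mech_params(K0 = K0, k = 0.23, gamma = 2 * K0 * nu_inv,
              lambda0 = 2.3, V = V, sigma = 0.0357, E = E, A = A,
              alpha = 0.64, t_star = 427)
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params>\n")
  cat(sprintf("  K0 = %.4g nN/um, k = %.4g nN/um, gamma = %.4g nN s/um\n",
              x$K0, x$k, x$gamma))
  cat(sprintf("  lambda0 = %.4g nN, V = %.4g um/s, sigma = %.4g nN/um\n",
              x$lambda0, x$V, x$sigma))
  cat(sprintf("  E = %.4g nN/um^2, A = %.4g um^2, alpha = %.3g, t* = %.4g s\n",
              x$E, x$A, x$alpha, x$t_star))
  invisible(x)
}

#' Imposed strain history of a stretch experiment
#'
#' Describes the strain protocol applied to the substrate: an optional
#' prestretch phase (strain `prestretch_epsilon` held for `prestretch_hold`
#' seconds, used before compression steps), followed by the main step of
#' signed strain `epsilon` applied as a linear ramp at `rate` um/s.
#' Compression strains are measured from the prestretched length, so
#' `direction = "compression"` requires a positive prestretch and a negative
#' `epsilon`.
#'
#' @param epsilon Signed strain of the main step (dimensionless).
#' @param rate Stretch rate (um/s); the ramp lasts `|epsilon| * L / rate` s.
#' @param L0 Initial bundle length (um).
#' @param prestretch_epsilon Strain of the prestretch phase (`>= 0`).
#' @param prestretch_hold Hold duration of the prestretch before the main
#'   step (s).
#' @param direction `"extension"` or `"compression"`.
#' @return An object of class `stretch_protocol`.
#' @export
#' @examples
#' stretch_protocol(0.2)
#' stretch_protocol(-0.2, prestretch_epsilon = 0.2, prestretch_hold = 3600,
#'                  direction = "compression")
stretch_protocol <- function(epsilon, rate = 100, L0 = 36.47,
                             prestretch_epsilon = 0, prestretch_hold = 0,
                             direction = c("extension", "compression")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, is.finite(epsilon),
            rate > 0, L0 > 0, prestretch_epsilon >= 0, prestretch_hold >= 0)
  if (direction == "compression") {
    if (prestretch_epsilon <= 0 || epsilon >= 0) {
      stop("compression protocols require prestretch_epsilon > 0 and epsilon < 0 ",
           "(compression is measured from the prestretched state)", call. = FALSE)
    }
  } else if (epsilon < 0) {
    stop("extension protocols require epsilon >= 0; use direction = \"compression\" ",
         "with a prestretch for negative strain", call. = FALSE)
  }
  if (abs(epsilon) > 0.4) {
    warning("|epsilon| > 0.4 is outside the experimentally explored strain range",
            call. = FALSE)
  }
  structure(list(epsilon = epsilon, rate = rate, L0 = L0,
                 prestretch_epsilon = prestretch_epsilon,
                 prestretch_hold = prestretch_hold, direction = direction),
            class = "stretch_protocol")
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat(sprintf("<stretch_protocol> %s: epsilon = %+.3g at %.4g um/s, L0 = %.4g um\n",
              x$direction, x$epsilon, x$rate, x$L0))
  if (x$prestretch_epsilon > 0) {
    cat(sprintf("  prestretch %.3g held %.4g s\n", x$prestretch_epsilon,
                x$prestretch_hold))
  }
  invisible(x)
}

#' Dimensionless parameter groups of the local segment dynamics
#'
#' The local cortical-tension dynamics of a 5-um bundle segment are governed
#' by four groups: the passive relaxation rate `nu = 2 K0 / gamma` (1/s),
#' the active motor time scale `tau = sigma0 R0 / (K0 V)` (s), the
#' elasticity-to-cortex ratio `f = K0 eps_l / (2 sigma0)` (dimensionless) and
#' the motor competition number `Gamma = gamma V / (2 sigma0 R0)`
#' (dimensionless). When all four are computed from one physical parameter
#' set the identity `Gamma * nu * tau = 1` holds; parameters obtained by
#' fitting are free and the identity is only a diagnostic.
#'
#' @param nu Passive relaxation rate (1/s).
#' @param tau Active time scale (s).
#' @param f Elasticity-to-cortex ratio (`>= 0`).
#' @param Gamma Motor competition number.
#' @param sigma0 Local cortical tension (nN/um), optional.
#' @param lambda0_local Local line tension (nN), optional.
#' @param R0 Unstretched radius of curvature (um), optional.
#' @return An object of class `local_ode_params`.
#' @seealso [local_params_from_global()]
#' @export
local_ode_params <- function(nu, tau, f, Gamma, sigma0 = NA_real_,
                             lambda0_local = NA_real_, R0 = NA_real_) {
  stopifnot(nu > 0, tau > 0, Gamma > 0, f >= 0)
  if (!is.na(sigma0) && sigma0 <= 0) stop("sigma0 must be positive", call. = FALSE)
  if (!is.na(R0) && R0 <= 0) stop("R0 must be positive", call. = FALSE)
  structure(list(nu = nu, tau = tau, f = f, Gamma = Gamma, sigma0 = sigma0,
                 lambda0_local = lambda0_local, R0 = R0),
            class = "local_ode_params")
}

#' Local parameter groups derived from one global parameter set
#'
#' Computes `nu`, `tau`, `f`, `Gamma` from `(K0, gamma, V)` of a
#' [mech_params()] object plus the local cortical tension `sigma0`, radius
#' `R0` and local strain `eps_l`. By construction `Gamma * nu * tau = 1`.
#'
#' @param params A `mech_params` object.
#' @param sigma0 Local cortical tension (nN/um).
#' @param R0 Unstretched radius (um).
#' @param eps_l Local strain (dimensionless).
#' @return A `local_ode_params` object.
#' @export
#' @examples
#' local_params_from_global(study_params(), sigma0 = 0.035, R0 = 65.6,
#'                          eps_l = 0.2)
local_params_from_global <- function(params, sigma0, R0, eps_l) {
  stopifnot(inherits(params, "mech_params"), sigma0 > 0, R0 > 0)
  local_ode_params(nu = 2 * params$K0 / params$gamma,
                   tau = sigma0 * R0 / (params$K0 * params$V),
                   f = params$K0 * eps_l / (2 * sigma0),
                   Gamma = params$gamma * params$V / (2 * sigma0 * R0),
                   sigma0 = sigma0, lambda0_local = sigma0 * R0, R0 = R0)
}

#' @export
print.local_ode_params <- function(x, ...) {
  cat(sprintf("<local_ode_params> nu^-1 = %.4g s, tau = %.4g s, f = %.4g, Gamma = %.4g\n",
              1 / x$nu, x$tau, x$f, x$Gamma))
  cat(sprintf("  Gamma*nu*tau = %.6g", x$Gamma * x$nu * x$tau))
  if (!is.na(x$sigma0)) cat(sprintf(", sigma0 = %.4g nN/um", x$sigma0))
  cat("\n")
  invisible(x)
}
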