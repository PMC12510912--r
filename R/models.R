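## The two steady-state glymphatic-function models: a two-compartment
## tracer-transport model (extracellular + perivascular concentrations,
## model A) and a seven-network steady poroelastic pressure model (MPET,
## model B).  Units: mm, s, Pa.

MMHG_PA <- 133.322          # 1 mmHg in Pa
ML_MIN_MM3_S <- 1000 / 60   # 1 ml/min in mm^3/s

#' Parameters of the two-compartment tracer model
#'
#' Steady-state diffusion of MRI tracer in the extracellular space (ECS,
#' `c_e`) and perivascular spaces (PVS, `c_p`) with inter-compartment
#' exchange `pi_ep (c_p - c_e)`, clearance from PVS to blood `pi_pb c_p`,
#' and Robin membrane conditions `-n D grad(c) . n = k (c - c_CSF)` on both
#' the pial and ventricle surfaces.  The CSF boundary concentration follows
#' a bi-exponential bolus profile (see [csf_concentration()]) evaluated at
#' `t_eval`.
#'
#' Defaults: ECS volume fraction 0.2, PVS 0.02; diffusion 1.3e-4 (ECS) and
#' 3.9e-4 (PVS) mm^2/s; exchange 2.9e-2 1/s; clearance 2.0e-8 1/s; surface
#' conductivities 1.0e-5 (ECS) and 3.7e-4 (PVS) mm/s; boundary amplitudes
#' 0.52 (pial) and 0.2 (ventricle); CSF volume fraction 0.2; time constants
#' 4.43e4 and 8.5e4 s; evaluation time 16.7 h.
#'
#' @param ... overrides of any default parameter.
#' @return A list of class `grom_model_a_params`.
#' @export
model_a_params <- function(...) {
  p <- list(
    n_e = 0.2, n_p = 0.02,
    D_e = 1.3e-4, D_p = 3.9e-4,
    pi_ep = 2.9e-2, pi_pb = 2.0e-8,
    k_e = 1.0e-5, k_p = 3.7e-4,
    a_pial = 0.52, a_ventricle = 0.2,
    phi_vf = 0.2, tau1 = 4.43e4, tau2 = 8.5e4,
    t_eval = 16.7 * 3600)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown model A parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(all(unlist(p) > 0 | unlist(p) >= 0), p$phi_vf > 0, p$phi_vf <= 1)
  class(p) <- "grom_model_a_params"
  p
}

#' CSF boundary tracer concentration profile
#'
#' The idealized CSF concentration after an intrathecal bolus,
#' \deqn{c^\alpha_{CSF}(t) = (a_\alpha / \phi)\,(e^{-t/\tau_2} - e^{-t/\tau_1}),}
#' with \eqn{\tau_2 > \tau_1}: zero at `t = 0`, a single interior maximum,
#' and decay to zero as `t` grows.
#'
#' @param params a [model_a_params()] list.
#' @param t time(s) in seconds, `t >= 0`.
#' @param surface `"pial"` or `"ventricle"` (selects the amplitude).
#' @return Concentration value(s).
#' @export
csf_concentration <- function(params, t, surface = c("pial", "ventricle")) {
  surface <- match.arg(surface)
  stopifnot(all(t >= 0))
  a <- if (surface == "pial") params$a_pial else params$a_ventricle
  (a / params$phi_vf) * (exp(-t / params$tau2) - exp(-t / params$tau1))
}

#' Peak time of the CSF concentration profile
#'
#' Closed-form argmax of the bi-exponential profile,
#' \deqn{t^* = \frac{\ln(\tau_2/\tau_1)}{1/\tau_1 - 1/\tau_2}.}
#' With the default time constants this is 16.7 h, the evaluation time used
#' for the steady-state tracer model.
#'
#' @param params a [model_a_params()] list.
#' @return Peak time in seconds.
#' @export
peak_time <- function(params) {
  if (!(params$tau2 > params$tau1 && params$tau1 > 0)) {
    stop("peak time requires tau2 > tau1 > 0")
  }
  log(params$tau2 / params$tau1) / (1 / params$tau1 - 1 / params$tau2)
}

#' Assemble the two-compartment tracer system
#'
#' Two fields `(c_e, c_p)` with diffusion `n_e D_e` and `n_p D_p`,
#' dissipative exchange `pi_ep`, PVS-to-blood clearance `pi_pb` (PVS block
#' only), and Robin conditions on both marked surfaces with
#' surface-specific CSF concentrations evaluated at `t_eval`.
#'
#' @param mesh a [grom_mesh()] with pial (1) and ventricle (2) markers.
#' @param params a [model_a_params()] list.
#' @param order Lagrange order (2 by default, matching the model's
#'   reference discretization).
#' @param deformation optional deformation for pulled-back assembly.
#' @return A `grom_system`.
#' @export
assemble_model_a <- function(mesh, params, order = 2L, deformation = NULL) {
  space <- build_space(mesh, order, n_fields = 2L)
  g_pial <- csf_concentration(params, params$t_eval, "pial")
  g_vent <- csf_concentration(params, params$t_eval, "ventricle")
  W <- matrix(c(0, params$pi_ep, params$pi_ep, 0), 2, 2)
  sys <- assemble_operator(
    mesh, space,
    diffusion = c(params$n_e * params$D_e, params$n_p * params$D_p),
    exchange = W, decay = c(0, params$pi_pb),
    robin = list(
      list(field = 1L, marker = 1L, k = params$k_e, g = g_pial),
      list(field = 1L, marker = 2L, k = params$k_e, g = g_vent),
      list(field = 2L, marker = 1L, k = params$k_p, g = g_pial),
      list(field = 2L, marker = 2L, k = params$k_p, g = g_vent)),
    deformation = deformation)
  sys$field_names <- c("c_e", "c_p")
  sys
}

#' Parameters of the seven-network MPET pressure model
#'
#' Steady Darcy-type pressures in seven compartments -- arterial (`a`),
#' capillary (`c`), venous (`v`), their perivascular spaces (`pa`, `pc`,
#' `pv`) and the extracellular space (`e`) -- with symmetric pairwise
#' exchange `omega_ij (p_j - p_i)` and the pre-infusion boundary
#' conditions: arterial Neumann influx `Q_in = B_in / |pial boundary|` on
#' the pial surface, capillary Neumann efflux `-Q_prod / |ventricle
#' boundary|` on the ventricle, and Robin anchors for `v`, `pa`, `pv` on
#' the pial surface; homogeneous Neumann elsewhere.
#'
#' Permeabilities `kappa_i` (printed in m^2) and transfer coefficients
#' `omega_ij` (1/(Pa s)) follow the model's base variant; effective
#' conductivities are `K_i = kappa_i / mu_i`.  The viscosities (blood
#' 2.67e-3 Pa s; CSF 7.0e-4 Pa s), the arterial inflow `B_in` and the CSF
#' reference pressure `p_CSF` are not fixed by the published tables: defaults
#' are chosen so the arterial pressure drop on the reference synthetic
#' geometry is of order 10 mmHg, and must be overridden in config for any
#' quantitative claim.
#'
#' @param ... overrides; `kappa` (m^2, named), `mu` (Pa s, named), `omega`
#'   (7 x 7 symmetric, 1/(Pa s)), `B_in` (mm^3/s), `Q_prod` (mm^3/s),
#'   `p_DS`, `p_CSF` (Pa), `beta1`, `beta2`, `beta3`.
#' @return A list of class `grom_model_b_params`.
#' @export
model_b_params <- function(...) {
  comp <- c("a", "c", "v", "pa", "pc", "pv", "e")
  kappa <- c(a = 3.63e-14, c = 1.44e-15, v = 1.13e-12, e = 2e-17,
             pa = 3e-17, pc = 1.44e-15, pv = 1.95e-14)  # m^2
  mu <- c(a = 2.67e-3, c = 2.67e-3, v = 2.67e-3,
          pa = 7.0e-4, pc = 7.0e-4, pv = 7.0e-4, e = 7.0e-4)  # Pa s
  omega <- matrix(0, 7, 7, dimnames = list(comp, comp))
  pairs <- list(c("a", "c", 1.45e-6), c("c", "v", 8.75e-6),
                c("c", "pc", 8.48e-10), c("pa", "e", 1.86e-7),
                c("pv", "e", 1.65e-7), c("pa", "pc", 1e-6),
                c("pc", "pv", 1e-6), c("pc", "e", 1e-10))
  for (pr in pairs) {
    omega[pr[1], pr[2]] <- as.numeric(pr[3])
    omega[pr[2], pr[1]] <- as.numeric(pr[3])
  }
  p <- list(compartments = comp, kappa = kappa, mu = mu, omega = omega,
            B_in = 2.0,                        # mm^3/s; not fixed by published tables
            Q_prod = 0.33 * ML_MIN_MM3_S,      # 0.33 ml/min
            p_DS = 8.4 * MMHG_PA,              # 8.4 mmHg
            p_CSF = 10 * MMHG_PA,              # not fixed by published tables
            beta1 = 1e-3, beta2 = 1e-3, beta3 = 1e-7)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown model B parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(all(p$kappa > 0), all(p$mu > 0),
            max(abs(p$omega - t(p$omega))) == 0, all(diag(p$omega) == 0))
  class(p) <- "grom_model_b_params"
  p
}

# effective conductivities K_i = kappa_i / mu_i in mm^2/(Pa s)
model_b_conductivities <- function(params) {
  comp <- params$compartments
  (params$kappa[comp] * 1e6) / params$mu[comp]
}

#' Assemble the seven-network MPET system
#'
#' @param mesh a [grom_mesh()] with pial (1) and ventricle (2) markers.
#' @param params a [model_b_params()] list.
#' @param order Lagrange order (1 by default, matching the model's
#'   reference discretization).
#' @param deformation optional deformation for pulled-back assembly.
#' @return A `grom_system`.
#' @export
assemble_model_b <- function(mesh, params, order = 1L, deformation = NULL) {
  comp <- params$compartments
  # the exchange graph must be connected so the Robin anchors fix all levels
  adj <- params$omega > 0
  reach <- logical(7); reach[1] <- TRUE
  for (it in 1:7) reach <- reach | (adj %*% reach > 0)
  if (!all(reach)) {
    stop("exchange graph disconnected; unreachable compartments: ",
         paste(comp[!reach], collapse = ", "))
  }
  space <- build_space(mesh, order, n_fields = 7L)
  K <- model_b_conductivities(params)
  if (is.null(deformation)) {
    len_pial <- boundary_length(mesh, 1L)
    len_vent <- boundary_length(mesh, 2L)
  } else {
    # geometry-dependent normalizations live in the deformed configuration,
    # so pulled-back assembly matches direct assembly on the deformed mesh
    sp1 <- build_space(mesh, 1L, 1L)
    len_pial <- sum(boundary_terms(mesh, sp1, 1L, g = 1,
                                   deformation = deformation)$F)
    len_vent <- sum(boundary_terms(mesh, sp1, 2L, g = 1,
                                   deformation = deformation)$F)
  }
  Q_in <- params$B_in / len_pial
  g_mid <- (params$p_DS + params$p_CSF) / 2
  fidx <- function(nm) match(nm, comp)
  sys <- assemble_operator(
    mesh, space, diffusion = as.numeric(K), exchange = params$omega,
    robin = list(
      list(field = fidx("v"), marker = 1L, k = params$beta1, g = g_mid),
      list(field = fidx("pa"), marker = 1L, k = params$beta2, g = params$p_CSF),
      list(field = fidx("pv"), marker = 1L, k = params$beta3, g = g_mid)),
    neumann = list(
      list(field = fidx("a"), marker = 1L, flux = Q_in),
      list(field = fidx("c"), marker = 2L, flux = -params$Q_prod / len_vent)),
    deformation = deformation)
  sys$field_names <- paste0("p_", comp)
  sys
}

#' Solve a glymphatic model on a mesh
#'
#' Assembles and solves model A (two-compartment tracer, P2 by default) or
#' model B (seven-network MPET, P1 by default) and wraps the result as a
#' field.
#'
#' @param mesh a [grom_mesh()].
#' @param params matching parameter list ([model_a_params()] or
#'   [model_b_params()]).
#' @param which `"A"` or `"B"`.
#' @param order optional Lagrange order override.
#' @return A [fem_field()] with attributes `residual`, `solve_time` and
#'   `dofs`.
#' @export
solve_model <- function(mesh, params, which = c("A", "B"), order = NULL) {
  which <- match.arg(which)
  sys <- if (which == "A") {
    assemble_model_a(mesh, params, order = if (is.null(order)) 2L else order)
  } else {
    assemble_model_b(mesh, params, order = if (is.null(order)) 1L else order)
  }
  sol <- solve_full(sys)
  f <- fem_field(sys$space, mesh, sol$coeffs, sys$field_names)
  attr(f, "residual") <- sol$residual
  attr(f, "solve_time") <- sol$time
  attr(f, "dofs") <- sys$space$n_dofs
  f
}

#' Net boundary fluxes of an MPET solution
#'
#' Computes, per compartment, the net boundary inflow implied by the
#' boundary conditions: the prescribed Neumann totals for the arterial and
#' capillary networks and the Robin fluxes `beta int (g - p) ds` for the
#' anchored compartments.  By pairwise conservation of the exchange terms
#' the seven values must sum to zero (up to solver accuracy).
#'
#' @param mesh the mesh the solution lives on.
#' @param params the [model_b_params()] used.
#' @param field the solved [fem_field()] from `solve_model(..., "B")`.
#' @return Named numeric vector of per-compartment net boundary fluxes
#'   (mm^3/s, 2D analog units).
#' @export
model_b_boundary_fluxes <- function(mesh, params, field) {
  comp <- params$compartments
  space1 <- build_space(mesh, field$space$order, 1L)
  U <- field_matrix(field)
  bt_p <- boundary_terms(mesh, space1, 1L, g = 1)
  len_pial <- sum(bt_p$F)
  g_mid <- (params$p_DS + params$p_CSF) / 2
  robin_flux <- function(beta, g, pcol) {
    beta * (g * len_pial - sum(bt_p$M %*% U[, pcol]))
  }
  out <- c(a = params$B_in, c = -params$Q_prod,
           v = robin_flux(params$beta1, g_mid, match("v", comp)),
           pa = robin_flux(params$beta2, params$p_CSF, match("pa", comp)),
           pc = 0,
           pv = robin_flux(params$beta3, g_mid, match("pv", comp)),
           e = 0)
  out[comp]
}
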