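#' Per-step potential energy of the centre-of-mass oscillation
#'
#' Every step lifts the centre of mass by `delta_y = l (1 - sqrt(1 -
#' 1/(4 k^2)))`, so the oscillation costs `m g delta_y` joules of positive
#' work per step regardless of gradient.
#'
#' @inheritParams compute_geometry
#' @param g Gravitational acceleration, m/s^2. Default 9.81.
#' @return Energy per step in joules (>= 0).
#' @examples
#' oscillation_energy(body_params(mass = 70, leg_length = 0.9),
#'                    gait_params(1.35))
#' @export
oscillation_energy <- function(body, gait, g = 9.81) {
  body <- as_body(body)
  gait <- as_gait(gait)
  check_scalar(g, "g")
  body$mass * g * compute_geometry(body, gait, 0)$delta_y
}

#' Per-step potential energy due to the gradient
#'
#' Climbing a gradient `i` with step length `l/k` gains height
#' `dy = i (l/k) / sqrt(1 + i^2)` per step, costing `m g dy` joules.
#' The function is odd in `i`: descending returns exactly the negative of
#' the ascending cost.
#'
#' @inheritParams oscillation_energy
#' @param gradient Gradient fraction(s); vectorised.
#' @return Energy per step in joules; sign matches the sign of `gradient`.
#' @examples
#' gradient_energy(body_params(mass = 70), gait_params(1.35), -0.10)
#' @export
gradient_energy <- function(body, gait, gradient, g = 9.81) {
  body <- as_body(body)
  gait <- as_gait(gait)
  gradient <- gradient_value(gradient)
  check_scalar(g, "g")
  body$mass * g * gradient * (body$leg_length / gait$k) / sqrt(1 + gradient^2)
}

#' Braking-adjusted cost of a per-step energy balance
#'
#' The piecewise cost function at the heart of the model. A positive
#' per-step potential-energy balance must be supplied as positive muscular
#' work and costs its full value. A negative balance (excess energy
#' received on a descent) must be absorbed by braking (negative, eccentric)
#' work, which is cheaper by the efficiency factor: absorbing 100 J costs
#' about 20 J with the default factor 5. At a zero balance both branches
#' agree and the cost is 0, so the function is continuous, non-negative and
#' V-shaped in the balance.
#'
#' @param u_tot Per-step energy balance(s) in joules; vectorised.
#' @param efficiency_factor Positive-to-negative work cost ratio (> 1),
#'   default 5.
#' @return Non-negative cost in joules, same length as `u_tot`.
#' @examples
#' braking_cost(-100) # 20 J
#' braking_cost(50)   # 50 J
#' @export
braking_cost <- function(u_tot, efficiency_factor = 5) {
  if (!is.numeric(u_tot)) stop("u_tot must be numeric")
  check_scalar(efficiency_factor, "efficiency_factor")
  if (efficiency_factor <= 1) stop("efficiency_factor must be > 1")
  # "+ 0" normalises IEEE negative zero from the -u_tot/factor branch
  ifelse(u_tot > 0, u_tot, -u_tot / efficiency_factor) + 0
}

#' Full per-step energy breakdown on a gradient
#'
#' Combines the oscillation and gradient terms into the total potential
#' energy balance `U_tot = dU_osc + dU_grad` and applies [braking_cost()]
#' to obtain the braking-adjusted cost `epsilon`. At the energy-minimising
#' negative gradient the descent exactly pays for the centre-of-mass lift
#' and `epsilon = 0`.
#'
#' @inheritParams gradient_energy
#' @return An object of class `energy_breakdown`: list with vector fields
#'   `gradient`, `dU_osc`, `dU_grad`, `U_tot`, `epsilon` (joules) and
#'   scalars `g`, `efficiency_factor`, `mass`, `leg_length`, `k`.
#' @examples
#' total_energy(body_params(mass = 70, leg_length = 0.9),
#'              gait_params(1.35), gradient = c(-0.10, 0, 0.10))
#' @export
total_energy <- function(body, gait, gradient, g = 9.81) {
  body <- as_body(body)
  gait <- as_gait(gait)
  gradient <- gradient_value(gradient)
  du_osc <- oscillation_energy(body, gait, g)
  du_grad <- gradient_energy(body, gait, gradient, g)
  u_tot <- du_osc + du_grad
  eps <- braking_cost(u_tot, gait$efficiency_factor)
  structure(list(gradient = gradient,
                 dU_osc = rep(du_osc, length(gradient)),
                 dU_grad = du_grad,
                 U_tot = u_tot,
                 epsilon = eps,
                 g = g,
                 efficiency_factor = gait$efficiency_factor,
                 mass = body$mass, leg_length = body$leg_length,
                 k = gait$k),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "per-step energy (m = %.4g kg, l = %.4g m, k = %.4g, g = %.4g, factor %g)\n",
    x$mass, x$leg_length, x$k, x$g, x$efficiency_factor))
  df <- data.frame(gradient = x$gradient, dU_osc = x$dU_osc,
                   dU_grad = x$dU_grad, U_tot = x$U_tot, epsilon = x$epsilon)
  print(df, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  data.frame(gradient = x$gradient, dU_osc = x$dU_osc, dU_grad = x$dU_grad,
             U_tot = x$U_tot, epsilon = x$epsilon)
}
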