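# Dimensionless per-step energy balance per unit m*g*l:
#   f(i; k) = (i/k) / sqrt(1 + i^2) + (1 - sqrt(1 - 1/(4 k^2)))
# Zero of f on i < 0 is the energy-minimising gradient. Strictly
# increasing in i, so the root is unique.
balance_per_mgl <- function(i, k) {
  (i / k) / sqrt(1 + i^2) + (1 - sqrt(1 - 1 / (4 * k^2)))
}

check_k <- function(k, lower = 0.5, strict = FALSE) {
  if (!is.numeric(k) || length(k) < 1L || anyNA(k))
    stop("k must be numeric and non-missing")
  bad <- if (strict) k <= lower else k < lower
  if (any(bad))
    stop("step parameter k must be ", if (strict) "> " else ">= ", lower,
         " (got ", min(k), ")")
  invisible(k)
}

#' Closed-form energy-minimising gradient for a given step parameter
#'
#' Dropping the near-unity factor `sqrt(1 + i^2)` from the per-step energy
#' balance gives the closed-form optimum
#' `i(k) = k sqrt(1 - 1/(4 k^2)) - k = sqrt(k^2 - 1/4) - k`,
#' the downhill gradient at which the potential energy released by the
#' descent exactly pays for the centre-of-mass lift. The approximation
#' error against the exact root stays below 0.003 (fraction units) over the
#' comfortable range of `k`; see [optimal_gradient_exact()].
#'
#' Typical values: about -12 % for long steps (k ~ 1.10), about -10 % at
#' the comfortable midpoint (k = 1.35) and about -8.6 % for short steps
#' (k ~ 1.5).
#'
#' @param k Step parameter(s), >= 0.5; vectorised.
#' @return Optimal gradient fraction(s) in (-0.5, 0].
#' @examples
#' optimal_gradient_closed_form(c(1.10, 1.35, 1.5))
#' @export
optimal_gradient_closed_form <- function(k) {
  check_k(k)
  sqrt(k^2 - 0.25) - k
}

#' Exact energy-minimising gradient (root of the full balance)
#'
#' Solves the full per-step balance `(i/k)/sqrt(1 + i^2) +
#' (1 - sqrt(1 - 1/(4 k^2))) = 0` for `i < 0`, retaining the
#' `sqrt(1 + i^2)` factor that the closed form drops. The balance is
#' strictly increasing in `i`, so a bracketed root search
#' ([stats::uniroot()] on `(-0.5, 0)`, extended downward for `k` very close
#' to 0.5 where the root falls just below -0.5) finds the unique zero. By
#' construction the braking-adjusted cost at the returned gradient is zero.
#'
#' @param k Step parameter(s), > 0.5; vectorised.
#' @param tol Convergence tolerance on the gradient. Default 1e-12.
#' @return Gradient fraction(s) < 0.
#' @examples
#' optimal_gradient_exact(1.35)
#' @export
optimal_gradient_exact <- function(k, tol = 1e-12) {
  check_k(k, strict = TRUE)
  check_scalar(tol, "tol")
  if (tol <= 0) stop("tol must be > 0")
  vapply(k, function(kk) {
    stats::uniroot(balance_per_mgl, k = kk,
                   lower = -0.5 + 1e-9, upper = -1e-12,
                   extendInt = "upX", tol = tol)$root
  }, numeric(1))
}

#' Numeric argmin of the braking-adjusted cost curve
#'
#' Independent of the root-based solvers: evaluates the braking-adjusted
#' cost on a dense gradient grid, takes the grid argmin and refines it by
#' golden-section search ([stats::optimize()]) on the bracketing interval.
#' Serves as a cross-check oracle for [optimal_gradient_exact()]; results
#' are independent of body mass because the cost scales linearly with it.
#'
#' @inheritParams total_energy
#' @param grid_lo,grid_hi Gradient search interval (fractions). Defaults
#'   -0.5 and 0.5.
#' @param n Number of grid points, >= 1000. Default 10001.
#' @return The minimising gradient fraction, with attribute `on_boundary`
#'   set to `TRUE` when the grid argmin sits on an interval edge (the true
#'   minimum may lie outside the interval).
#' @examples
#' optimal_gradient_numeric(body_params(), gait_params(1.25))
#' @export
optimal_gradient_numeric <- function(body, gait, grid_lo = -0.5,
                                     grid_hi = 0.5, n = 10001, g = 9.81) {
  body <- as_body(body)
  gait <- as_gait(gait)
  check_scalar(grid_lo, "grid_lo")
  check_scalar(grid_hi, "grid_hi")
  check_scalar(n, "n")
  if (grid_lo >= grid_hi) stop("grid_lo must be < grid_hi")
  if (n < 1000) stop("n must be >= 1000 for a reliable grid argmin")
  grid <- seq(grid_lo, grid_hi, length.out = n)
  eps <- total_energy(body, gait, grid, g)$epsilon
  j <- which.min(eps)
  if (j == 1L || j == n) {
    out <- grid[j]
    attr(out, "on_boundary") <- TRUE
    return(out)
  }
  fit <- stats::optimize(
    function(i) total_energy(body, gait, i, g)$epsilon,
    lower = grid[j - 1L], upper = grid[j + 1L], tol = 1e-9)
  out <- fit$minimum
  attr(out, "on_boundary") <- FALSE
  out
}

#' Step parameter that makes a given downhill gradient optimal
#'
#' Algebraic inverse of the closed form: squaring `sqrt(k^2 - 1/4) = k + i`
#' gives `k = -(1/4 + i^2) / (2 i)`, defined for `-0.5 < i < 0`. This
#' inverse is an implementation derivation (the closed form is only stated
#' in the forward direction in the source model); it round-trips with
#' [optimal_gradient_closed_form()] to machine precision.
#'
#' @param i Downhill gradient fraction(s) in (-0.5, 0); vectorised.
#' @return Step parameter(s) `k > 0.5`.
#' @examples
#' optimal_step_parameter(-0.10) # 1.30
#' @export
optimal_step_parameter <- function(i) {
  if (!is.numeric(i) || length(i) < 1L || anyNA(i))
    stop("gradient must be numeric and non-missing")
  if (any(i >= 0) || any(i <= -0.5))
    stop("no step length makes this gradient optimal: require -0.5 < i < 0 ",
         "(got ", i[which(i >= 0 | i <= -0.5)[1]], ")")
  -(0.25 + i^2) / (2 * i)
}

#' Solve the optimal gradient three ways and compare
#'
#' Runs the closed-form expression, the exact root of the full balance and
#' the independent numeric argmin for one step parameter, and reports their
#' maximum pairwise disagreement together with the braking-adjusted cost at
#' the exact optimum (zero up to solver tolerance).
#'
#' @param k Step parameter (> 0.5).
#' @param body A [body_params()] object (mass only scales the cost, not the
#'   optimum). Default unit mass, 0.9 m leg.
#' @param g Gravitational acceleration, m/s^2.
#' @param efficiency_factor Braking efficiency factor (> 1).
#' @param n Grid size for the numeric argmin.
#' @return An object of class `optimal_gradient_result` with fields `k`,
#'   `i_closed_form`, `i_exact`, `i_numeric`, `epsilon_at_optimum`,
#'   `max_pairwise_disagreement`.
#' @examples
#' solve_optimal_gradient(1.35)
#' @export
solve_optimal_gradient <- function(k, body = body_params(), g = 9.81,
                                   efficiency_factor = 5, n = 10001) {
  check_k(k, strict = TRUE)
  check_scalar(k, "k")
  body <- as_body(body)
  gait <- suppressWarnings(gait_params(k, efficiency_factor))
  i_cf <- optimal_gradient_closed_form(k)
  i_ex <- optimal_gradient_exact(k)
  i_nm <- as.numeric(optimal_gradient_numeric(body, gait, n = n, g = g))
  eps_opt <- total_energy(body, gait, i_ex, g)$epsilon
  disag <- max(abs(c(i_cf - i_ex, i_cf - i_nm, i_ex - i_nm)))
  structure(list(k = k, i_closed_form = i_cf, i_exact = i_ex,
                 i_numeric = i_nm, epsilon_at_optimum = eps_opt,
                 max_pairwise_disagreement = disag),
            class = "optimal_gradient_result")
}

#' @export
print.optimal_gradient_result <- function(x, ...) {
  cat(sprintf("optimal gradient at k = %.4g:\n", x$k))
  cat(sprintf("  closed form : %+.4f (%.1f %%)\n",
              x$i_closed_form, 100 * x$i_closed_form))
  cat(sprintf("  exact root  : %+.4f (%.1f %%)\n",
              x$i_exact, 100 * x$i_exact))
  cat(sprintf("  numeric     : %+.4f (%.1f %%)\n",
              x$i_numeric, 100 * x$i_numeric))
  cat(sprintf("  cost at exact optimum: %.3g J; max disagreement %.2g\n",
              x$epsilon_at_optimum, x$max_pairwise_disagreement))
  invisible(x)
}

#' Recommend a step length for a given gradient
#'
#' Inverts the optimal-gradient relation: for a downhill gradient in
#' (-0.5, 0) it returns the step parameter that makes that gradient
#' energy-optimal and the corresponding step length `l / k`, and flags
#' whether the required `k` falls in the comfortable range (default
#' `[1.15, 1.55]`, i.e. 1.35 +/- 0.20). Outside the comfort band, the
#' nearest comfortable `k` is reported as `clamped_k`; for descents steeper
#' than about -13 % the required step (`k` near 1) is too wide to sustain
#' and slowing down is the remaining strategy. Uphill or level gradients
#' have no oscillation-cancelling optimum: the advice is returned with
#' status `"no_optimum"` rather than as an error, so route-profile sweeps
#' degrade gracefully.
#'
#' @param i Gradient fraction (scalar).
#' @param body A [body_params()] object supplying the leg length.
#' @param comfort Comfortable `k` range; default [k_comfort_default].
#' @return An object of class `step_length_advice` with fields `status`
#'   (`"ok"` or `"no_optimum"`), `gradient`, `target_k`, `step_length`
#'   (m), `within_comfort`, `clamped_k` (`NA` when within comfort),
#'   `clamped_step_length`, `note`.
#' @examples
#' recommend_step_length(-0.10, body_params(leg_length = 0.9))
#' @export
recommend_step_length <- function(i, body = body_params(),
                                  comfort = k_comfort_default) {
  check_scalar(i, "i")
  body <- as_body(body)
  if (!is.numeric(comfort) || length(comfort) != 2L || comfort[1] >= comfort[2])
    stop("comfort must be an increasing numeric range of length 2")
  l <- body$leg_length
  if (i >= 0 || i <= -0.5) {
    note <- if (i >= 0)
      "uphill or level gradients have no oscillation-cancelling optimum"
    else
      "descents of 50 % or more are outside the model's optimal-step relation"
    return(structure(list(status = "no_optimum", gradient = i,
                          target_k = NA_real_, step_length = NA_real_,
                          within_comfort = FALSE, clamped_k = NA_real_,
                          clamped_step_length = NA_real_, note = note),
                     class = "step_length_advice"))
  }
  k <- optimal_step_parameter(i)
  within <- k >= comfort[1] && k <= comfort[2]
  clamped <- if (within) NA_real_ else max(comfort[1], min(comfort[2], k))
  note <- if (within) {
    "optimal step length is within the comfortable range"
  } else if (k < comfort[1]) {
    paste0("optimal step is wider than comfortable (k = ", signif(k, 4),
           "); beyond about -13 % the optimal step (k near 1) is too wide ",
           "to sustain -- consider shortening the step and slowing down")
  } else {
    paste0("optimal step is shorter than comfortable (k = ", signif(k, 4), ")")
  }
  structure(list(status = "ok", gradient = i, target_k = k,
                 step_length = l / k, within_comfort = within,
                 clamped_k = clamped,
                 clamped_step_length = if (is.na(clamped)) NA_real_ else l / clamped,
                 note = note),
            class = "step_length_advice")
}

#' @export
print.step_length_advice <- function(x, ...) {
  cat(sprintf("step-length advice for gradient %+.3g (%.1f %%):\n",
              x$gradient, 100 * x$gradient))
  if (x$status == "no_optimum") {
    cat("  no finite optimal step length:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("  target k = %.4g -> step length %.3g m (%s comfort range)\n",
              x$target_k, x$step_length,
              if (x$within_comfort) "within" else "outside"))
  if (!is.na(x$clamped_k))
    cat(sprintf("  nearest comfortable k = %.4g -> step length %.3g m\n",
                x$clamped_k, x$clamped_step_length))
  cat(" ", x$note, "\n")
  invisible(x)
}
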