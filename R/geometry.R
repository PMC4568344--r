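#' Step geometry of the centre of mass on a gradient
#'
#' One walking step is modelled as an inverted-pendulum triangle: in single
#' support the stance leg is straight and the centre of mass is at its
#' highest point `y_max = y0 + l`; in double support the centre of mass is
#' at its lowest point `y_min = y0 + y'`, where the hip height
#' `y' = l * sqrt(1 - 1/(4 k^2))` follows from Pythagoras with half-step
#' `l/(2k)` and leg length `l`. The per-step vertical oscillation is
#' `delta_y = l * (1 - sqrt(1 - 1/(4 k^2)))`, independent of the trunk
#' offset and of the gradient.
#'
#' On a gradient `i` (rise over horizontal run) the step of length `l/k`
#' projects onto a horizontal displacement `dx = (l/k) / sqrt(1 + i^2)` and
#' a height gain `dy = i * dx`, so that `dx^2 + dy^2 = (l/k)^2`.
#'
#' @param body A [body_params()] object.
#' @param gait A [gait_params()] object.
#' @param gradient Gradient fraction(s); vectorised. Default 0 (level).
#' @return An object of class `gait_geometry`: list with `y_max`, `y_min`,
#'   `y_prime`, `delta_y` (scalars, metres) and `dx`, `dy` (same length as
#'   `gradient`, metres).
#' @examples
#' compute_geometry(body_params(leg_length = 0.9), gait_params(1.35))
#' @export
compute_geometry <- function(body, gait, gradient = 0) {
  body <- as_body(body)
  gait <- as_gait(gait)
  gradient <- gradient_value(gradient)
  l <- body$leg_length
  k <- gait$k
  y_prime <- l * sqrt(1 - 1 / (4 * k^2))
  y_max <- body$trunk_offset + l
  y_min <- body$trunk_offset + y_prime
  delta_y <- l * (1 - sqrt(1 - 1 / (4 * k^2)))
  dx <- (l / k) / sqrt(1 + gradient^2)
  dy <- gradient * dx
  structure(list(y_max = y_max, y_min = y_min, y_prime = y_prime,
                 delta_y = delta_y, dx = dx, dy = dy,
                 gradient = gradient),
            class = "gait_geometry")
}

#' @export
print.gait_geometry <- function(x, ...) {
  cat(sprintf("step geometry: y_max %.4g m, y_min %.4g m, delta_y %.4g m\n",
              x$y_max, x$y_min, x$delta_y))
  if (length(x$dx) == 1L)
    cat(sprintf("  at gradient %+.3g: dx %.4g m, dy %+.4g m\n",
                x$gradient, x$dx, x$dy))
  else
    cat(sprintf("  dx, dy over %d gradient values\n", length(x$dx)))
  invisible(x)
}
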