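#' Anthropometric parameters of a walker
#'
#' Bundles the scalar body measurements the step-energetics model uses: body
#' mass, leg length (hip joint to ground) and the vertical offset from the
#' hip joint up to the body centre of mass.
#'
#' The trunk offset shifts the highest and the lowest point of the
#' centre-of-mass trajectory by the same amount, so it cancels from the
#' oscillation amplitude and from every energy quantity; it is retained only
#' so that absolute centre-of-mass heights can be reported.
#'
#' @param mass Body mass in kg (>= 0). Defaults to 1, so that energies come
#'   out per unit mass (J/kg).
#' @param leg_length Leg length `l` in metres (> 0); the hypotenuse of the
#'   step triangle. Default 0.9 m, a typical adult value.
#' @param trunk_offset Vertical distance `y0` in metres (>= 0) from the hip
#'   joint to the centre of mass. Default 0.
#'
#' @return An object of class `body_params`: a list with fields `mass`,
#'   `leg_length`, `trunk_offset`.
#' @seealso [gait_params()], [compute_geometry()]
#' @examples
#' body_params(mass = 70, leg_length = 0.9)
#' @export
body_params <- function(mass = 1, leg_length = 0.9, trunk_offset = 0) {
  check_scalar(mass, "mass")
  check_scalar(leg_length, "leg_length")
  check_scalar(trunk_offset, "trunk_offset")
  if (mass < 0) stop("mass must be >= 0 kg, got ", mass)
  if (leg_length <= 0) stop("leg_length must be > 0 m, got ", leg_length)
  if (trunk_offset < 0) stop("trunk_offset must be >= 0 m, got ", trunk_offset)
  structure(list(mass = mass, leg_length = leg_length,
                 trunk_offset = trunk_offset),
            class = "body_params")
}

#' Gait parameters: step parameter and braking efficiency factor
#'
#' The step parameter `k` is leg length divided by step length (step length
#' = `l/k`); larger `k` means shorter steps. The step geometry requires
#' `k >= 0.5`: below that the half-step would exceed the leg length and
#' `sqrt(1 - 1/(4 k^2))` is not real. Values of `k` outside the comfortable
#' range 1.35 +/- 0.20 are physically valid but trigger an advisory warning.
#'
#' The efficiency factor expresses how much cheaper negative (braking) work
#' is than positive work; the default 5 means absorbing 100 J of excess
#' potential energy costs about 20 J of muscular work.
#'
#' @param k Dimensionless step parameter (>= 0.5).
#' @param efficiency_factor Ratio of positive-work to negative-work cost
#'   (> 1). Default 5.
#' @return An object of class `gait_params`.
#' @examples
#' gait_params(1.35)
#' @export
gait_params <- function(k, efficiency_factor = 5) {
  check_scalar(k, "k")
  check_scalar(efficiency_factor, "efficiency_factor")
  if (k < 0.5)
    stop("step parameter k must be >= 0.5: for k < 0.5 the half-step ",
         "exceeds the leg length and sqrt(1 - 1/(4 k^2)) is not real (k = ",
         k, ")")
  if (efficiency_factor <= 1)
    stop("efficiency_factor must be > 1, got ", efficiency_factor)
  if (k < k_comfort_default[1] || k > k_comfort_default[2])
    warning("k = ", k, " is outside the comfortable range [",
            k_comfort_default[1], ", ", k_comfort_default[2],
            "] (1.35 +/- 0.20); geometry is still valid", call. = FALSE)
  structure(list(k = k, efficiency_factor = efficiency_factor),
            class = "gait_params")
}

#' Gradient as a dimensionless fraction
#'
#' A gradient `i` is vertical rise per unit horizontal displacement;
#' negative means downhill (-0.10 is a 10 % descent). Internally the model
#' always works in fractions; use `percent = TRUE` to convert user input
#' given in percent.
#'
#' @param i Numeric gradient value(s).
#' @param percent If `TRUE`, `i` is given in percent and divided by 100.
#' @return A validated numeric vector of gradient fractions.
#' @examples
#' gradient_value(-10, percent = TRUE) # -0.1
#' @export
gradient_value <- function(i, percent = FALSE) {
  if (!is.numeric(i) || length(i) < 1L || anyNA(i))
    stop("gradient must be numeric and non-missing")
  if (percent) i <- i / 100
  if (any(abs(i) >= 5))
    stop("|gradient| must be < 5 as a fraction (got ", max(abs(i)),
         "); did you pass percent without percent = TRUE?")
  i
}

#' Comfortable step-parameter ranges
#'
#' Two published bounds for the comfortable variation of the step parameter
#' `k`: the default band `[1.15, 1.55]` (1.35 +/- 0.20) and the slightly
#' wider strategy band `[1.10, 1.50]` used when discussing how far the
#' optimal-gradient range can be stretched by adjusting step length.
#'
#' @format Numeric vectors of length 2 (lower, upper).
#' @rdname comfort_ranges
#' @export
k_comfort_default <- c(1.15, 1.55)

#' @rdname comfort_ranges
#' @export
k_comfort_strategy <- c(1.10, 1.50)

# internal: single finite numeric
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  invisible(x)
}

as_body <- function(x) {
  if (!inherits(x, "body_params")) stop("expected a body_params object")
  x
}

as_gait <- function(x) {
  if (!inherits(x, "gait_params")) stop("expected a gait_params object")
  x
}

#' @export
print.body_params <- function(x, ...) {
  cat(sprintf("walker: mass %.3g kg, leg length %.3g m, trunk offset %.3g m\n",
              x$mass, x$leg_length, x$trunk_offset))
  invisible(x)
}

#' @export
print.gait_params <- function(x, ...) {
  cat(sprintf("gait: k = %.4g (step length = l/%.4g), efficiency factor %.3g\n",
              x$k, x$k, x$efficiency_factor))
  invisible(x)
}
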