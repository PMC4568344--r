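test_that("parameter constructors validate their domains", {
  expect_error(body_params(mass = -1), "mass")
  expect_error(body_params(leg_length = 0), "leg_length")
  expect_error(body_params(trunk_offset = -0.1), "trunk_offset")
  expect_error(gait_params(0.49), "k must be >= 0.5")
  expect_error(gait_params(1.35, efficiency_factor = 1), "efficiency_factor")
  expect_warning(gait_params(0.8), "comfortable range")
  expect_silent(gait_params(1.35))
  expect_error(gradient_value(6), "did you pass percent")
  expect_equal(gradient_value(-10, percent = TRUE), -0.1)
})

test_that("step geometry matches limiting cases and the frozen oracle", {
  # widest possible step: k = 0.5 spans 2l, hip drops to the ground
  g0 <- compute_geometry(body_params(leg_length = 1, trunk_offset = 0.5),
                         quiet_gait(0.5), 0)
  expect_equal(g0$y_prime, 0)
  expect_equal(g0$delta_y, 1)
  expect_equal(g0$dy, 0)
  # vanishing step: oscillation disappears
  g1 <- compute_geometry(body_params(leg_length = 0.9), quiet_gait(1e6), 0)
  expect_lt(g1$delta_y, 1e-12)
  # comfortable midpoint, frozen from the pre-build one-line oracle
  g2 <- compute_geometry(body_params(leg_length = 0.9), gait_params(1.35), 0)
  expect_equal(g2$delta_y, 0.06400425, tolerance = 1e-6)
})

test_that("oscillation amplitude is independent of trunk offset and gradient", {
  gait <- gait_params(1.35)
  dys <- vapply(c(0, 0.25, 0.5, 1), function(y0)
    compute_geometry(body_params(leg_length = 0.9, trunk_offset = y0),
                     gait, 0)$delta_y, numeric(1))
  expect_true(all(dys == dys[1]))
  dyg <- vapply(c(-0.3, -0.1, 0, 0.2), function(i)
    compute_geometry(body_params(leg_length = 0.9), gait, i)$delta_y,
    numeric(1))
  expect_true(all(dyg == dyg[1]))
})

test_that("geometry invariants hold across a generated cohort and gradients", {
  cohort <- generate_cohort(40, seed = 101)
  gradients <- seq(-0.4, 0.4, length.out = 17)
  for (r in seq_len(nrow(cohort))) {
    body <- body_params(leg_length = cohort$leg_length[r])
    gait <- quiet_gait(cohort$k[r])
    geo <- compute_geometry(body, gait, gradients)
    expect_gte(geo$y_max, geo$y_min)
    expect_equal(geo$delta_y, geo$y_max - geo$y_min, tolerance = 1e-12)
    expect_true(geo$delta_y >= 0 && geo$delta_y <= body$leg_length)
    # Pythagorean closure of the step triangle
    expect_equal(geo$dx^2 + geo$dy^2,
                 rep((body$leg_length / gait$k)^2, length(gradients)),
                 tolerance = 1e-12)
  }
})

test_that("oscillation energy is m*g*delta_y with the frozen reference value", {
  expect_equal(oscillation_energy(body_params(mass = 0), gait_params(1.35)), 0)
  expect_equal(oscillation_energy(body_params(mass = 1, leg_length = 1),
                                  quiet_gait(0.5)), 9.81)
  e <- oscillation_energy(body_params(mass = 70, leg_length = 0.9),
                          gait_params(1.35))
  expect_equal(e, 43.95172, tolerance = 1e-6)
  geo <- compute_geometry(body_params(mass = 70, leg_length = 0.9),
                          gait_params(1.35))
  expect_identical(e, 70 * 9.81 * geo$delta_y)
})

test_that("gradient energy is odd in the gradient and matches hand value", {
  body <- body_params(mass = 1, leg_length = 1)
  gait <- quiet_gait(1)
  expect_equal(gradient_energy(body, gait, 0), 0)
  expect_equal(gradient_energy(body, gait, 0.1), 0.9761315, tolerance = 1e-6)
  ii <- seq(0.01, 0.45, by = 0.02)
  expect_equal(gradient_energy(body, gait, ii) +
                 gradient_energy(body, gait, -ii),
               rep(0, length(ii)))
  expect_true(all(sign(gradient_energy(body, gait, c(-0.2, 0.3))) ==
                    c(-1, 1)))
})

test_that("braking cost applies the piecewise efficiency rule", {
  expect_identical(braking_cost(50), 50)
  expect_identical(braking_cost(-100), 20)
  expect_identical(braking_cost(0), 0)
  expect_equal(braking_cost(-100, efficiency_factor = 4), 25)
  expect_equal(braking_cost(c(-10, 0, 10)), c(2, 0, 10))
  # continuity at the kink: both branches vanish together
  u <- c(-1e-9, 1e-9)
  expect_true(all(braking_cost(u) < 1e-8))
  expect_error(braking_cost(-1, efficiency_factor = 0.5), "> 1")
})

test_that("total energy decomposes exactly and epsilon is a V with zero minimum", {
  body <- body_params(mass = 70, leg_length = 0.9)
  gait <- gait_params(1.35)
  grid <- seq(-0.5, 0.5, length.out = 4001)
  e <- total_energy(body, gait, grid)
  expect_identical(e$U_tot, e$dU_osc + e$dU_grad)
  expect_true(all(e$epsilon >= 0))
  j <- which.min(e$epsilon)
  expect_true(j > 1 && j < length(grid))
  expect_true(all(diff(e$epsilon[1:j]) < 0))
  expect_true(all(diff(e$epsilon[j:length(grid)]) > 0))
  # the minimum sits at the downhill gradient that zeroes the balance
  expect_lt(abs(grid[j] - oracle_root_algebraic(1.35)), diff(grid[1:2]))
})

test_that("branch slopes near the optimum differ by the efficiency factor", {
  body <- body_params(mass = 1, leg_length = 0.9)
  for (k in c(1.1, 1.35, 1.5)) {
    gait <- quiet_gait(k)
    i0 <- oracle_root_algebraic(k)
    h <- 1e-5
    eps <- function(i) total_energy(body, gait, i)$epsilon
    slope_left <- (eps(i0 - h) - eps(i0 - 2 * h)) / h
    slope_right <- (eps(i0 + 2 * h) - eps(i0 + h)) / h
    expect_equal(abs(slope_left) * gait$efficiency_factor, slope_right,
                 tolerance = 0.02)
  }
})

test_that("epsilon scales linearly with mass and the 100 J descent costs 20 J", {
  gait <- gait_params(1.35)
  e1 <- total_energy(body_params(mass = 1), gait, -0.2)
  e2 <- total_energy(body_params(mass = 2), gait, -0.2)
  expect_equal(e2$epsilon, 2 * e1$epsilon)
  # scale mass so the balance on a steep descent is exactly -100 J
  m <- -100 / e1$U_tot
  e100 <- total_energy(body_params(mass = m), gait, -0.2)
  expect_equal(e100$U_tot, -100)
  expect_equal(e100$epsilon, 20)
})
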