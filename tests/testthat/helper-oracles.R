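# Independent oracles, kept free of the package's solver paths.

# per-step energy balance per unit m*g*l, written out directly
oracle_balance <- function(i, k) {
  (i / k) / sqrt(1 + i^2) + (1 - sqrt(1 - 1 / (4 * k^2)))
}

# dense-grid sign-change scan for the zero of the balance on (-0.5, 0)
oracle_root_scan <- function(k, step = 1e-6) {
  grid <- seq(-0.5 + step, -step, by = step)
  f <- oracle_balance(grid, k)
  j <- which(f[-length(f)] * f[-1] <= 0)[1]
  stopifnot(!is.na(j))
  mean(grid[j:(j + 1L)])
}

# algebraic solution of the full balance: i/sqrt(1+i^2) = -c with
# c = k - sqrt(k^2 - 1/4) gives i = -c / sqrt(1 - c^2)
oracle_root_algebraic <- function(k) {
  cc <- k - sqrt(k^2 - 0.25)
  -cc / sqrt(1 - cc^2)
}

quiet_gait <- function(k, efficiency_factor = 5) {
  suppressWarnings(gait_params(k, efficiency_factor))
}
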