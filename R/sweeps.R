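# Sweep tables backing the cost-vs-gradient and optimum-vs-k figures,
# with CSV/JSON writers that carry full parameter metadata, since the
# absolute scale of the cost curves depends on mass and leg length.

sweep_metadata <- function(mode, body, g, efficiency_factor, grid) {
  list(mode = mode, m = body$mass, l = body$leg_length, g = g,
       efficiency_factor = efficiency_factor,
       grid_lo = grid[1], grid_hi = grid[2], grid_n = grid[3])
}

new_sweep_table <- function(df, metadata) {
  structure(df, metadata = metadata,
            class = c("sweep_table", "data.frame"))
}

#' Braking-adjusted cost versus gradient, one series per step parameter
#'
#' Sweeps the per-step braking-adjusted cost over a gradient grid for each
#' requested step parameter `k`, producing the V-shaped cost curves whose
#' minima (cost zero) sit at each `k`'s optimal negative gradient. Mass
#' scales every curve linearly without moving the minima; the parameter set
#' is recorded in the table metadata.
#'
#' @param ks Step parameters, each >= 0.5. Default `c(1, 1.25, 1.5)`.
#' @param i_lo,i_hi Gradient grid bounds (fractions). Defaults -0.3, 0.3.
#' @param n Number of grid points (>= 2). Default 601.
#' @param body A [body_params()] object. Default unit mass, 0.9 m leg.
#' @param g Gravitational acceleration, m/s^2.
#' @param efficiency_factor Braking efficiency factor (> 1).
#' @return A `sweep_table` (data.frame): column `gradient` plus one
#'   `epsilon_k*` column per step parameter, joules per step; metadata in
#'   `attr(, "metadata")`.
#' @examples
#' head(sweep_epsilon_vs_gradient(n = 61))
#' @export
sweep_epsilon_vs_gradient <- function(ks = c(1, 1.25, 1.5), i_lo = -0.3,
                                      i_hi = 0.3, n = 601,
                                      body = body_params(), g = 9.81,
                                      efficiency_factor = 5) {
  check_k(ks)
  body <- as_body(body)
  check_scalar(i_lo, "i_lo"); check_scalar(i_hi, "i_hi"); check_scalar(n, "n")
  if (i_lo >= i_hi) stop("i_lo must be < i_hi")
  if (n < 2) stop("n must be >= 2")
  grid <- seq(i_lo, i_hi, length.out = n)
  df <- data.frame(gradient = grid)
  for (k in ks) {
    gait <- suppressWarnings(gait_params(k, efficiency_factor))
    df[[sprintf("epsilon_k%g", k)]] <- total_energy(body, gait, grid, g)$epsilon
  }
  new_sweep_table(df, sweep_metadata("epsilon_vs_gradient", body, g,
                                     efficiency_factor, c(i_lo, i_hi, n)))
}

#' Optimal gradient versus step parameter
#'
#' Sweeps the energy-minimising gradient over a range of step parameters,
#' by the closed form, the exact root, the numeric argmin, or all three
#' (with a pairwise-disagreement column). The optimum is monotone
#' increasing in `k`: shorter steps move the optimum toward level.
#'
#' @param k_lo,k_hi Step-parameter bounds, `0.5 <= k_lo < k_hi`.
#' @param n Number of grid points (>= 2). Default 41.
#' @param method One of `"closed_form"`, `"exact"`, `"numeric"`, `"all"`.
#' @param body,g,efficiency_factor As in [sweep_epsilon_vs_gradient()];
#'   only used by the numeric method (they do not move the optimum).
#' @param n_numeric Gradient-grid size for the numeric argmin.
#' @return A `sweep_table` (data.frame): column `k` plus the requested
#'   optimum column(s) (`i_closed_form`, `i_exact`, `i_numeric`) and, for
#'   `method = "all"`, `max_disagreement`.
#' @examples
#' sweep_optimum_vs_k(1.10, 1.50, n = 5)
#' @export
sweep_optimum_vs_k <- function(k_lo = 1.10, k_hi = 1.50, n = 41,
                               method = c("closed_form", "exact", "numeric",
                                          "all"),
                               body = body_params(), g = 9.81,
                               efficiency_factor = 5, n_numeric = 10001) {
  method <- match.arg(method)
  check_scalar(k_lo, "k_lo"); check_scalar(k_hi, "k_hi"); check_scalar(n, "n")
  if (k_lo < 0.5) stop("k_lo must be >= 0.5")
  if (k_lo >= k_hi) stop("k_lo must be < k_hi")
  if (n < 2) stop("n must be >= 2")
  body <- as_body(body)
  ks <- seq(k_lo, k_hi, length.out = n)
  df <- data.frame(k = ks)
  want <- if (method == "all") c("closed_form", "exact", "numeric") else method
  if ("closed_form" %in% want)
    df$i_closed_form <- optimal_gradient_closed_form(ks)
  if ("exact" %in% want)
    df$i_exact <- vapply(ks, function(k)
      if (k > 0.5) optimal_gradient_exact(k) else -0.5, numeric(1))
  if ("numeric" %in% want)
    df$i_numeric <- vapply(ks, function(k) {
      gait <- suppressWarnings(gait_params(k, efficiency_factor))
      as.numeric(optimal_gradient_numeric(body, gait, n = n_numeric, g = g))
    }, numeric(1))
  if (method == "all") {
    im <- as.matrix(df[c("i_closed_form", "i_exact", "i_numeric")])
    df$max_disagreement <- apply(im, 1L, function(r) max(r) - min(r))
  }
  new_sweep_table(df, sweep_metadata("optimum_vs_k", body, g,
                                     efficiency_factor, c(k_lo, k_hi, n)))
}

#' @export
print.sweep_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("sweep table (%s): %d rows; m = %g kg, l = %g m, g = %g, factor %g\n",
              md$mode, nrow(x), md$m, md$l, md$g, md$efficiency_factor))
  print(utils::head(as.data.frame(x), 6L), digits = 5)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Write a sweep table to CSV or JSON
#'
#' CSV output carries the metadata as `# key: value` comment lines before
#' the header row, with values at 12 significant digits; JSON output is a
#' flat object with a `metadata` block and one array per column at full
#' precision. Both formats round-trip through [read_sweep_table()]
#' losslessly to 1e-10.
#'
#' @param table A `sweep_table`.
#' @param path Output file path, or `""` to write to standard output.
#' @param format `"csv"` or `"json"`; by default inferred from the path
#'   extension (falling back to CSV).
#' @return Invisibly, `path`.
#' @examples
#' tab <- sweep_optimum_vs_k(1.1, 1.5, n = 5)
#' f <- tempfile(fileext = ".csv")
#' write_sweep_table(tab, f)
#' @export
write_sweep_table <- function(table, path, format = NULL) {
  if (!inherits(table, "sweep_table")) stop("expected a sweep_table")
  if (nrow(table) == 0L) stop("refusing to write an empty sweep table")
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  md <- attr(table, "metadata")
  df <- as.data.frame(table)
  if (format == "json") {
    txt <- jsonlite::toJSON(c(list(metadata = md),
                              list(columns = as.list(df))),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (identical(path, "")) writeLines(txt) else writeLines(txt, path)
  } else {
    hdr <- vapply(names(md), function(nm)
      sprintf("# %s: %s", nm, format(md[[nm]], digits = 15)), character(1))
    body_rows <- do.call(paste, c(lapply(df, function(col)
      sprintf("%.12g", col)), sep = ","))
    lines <- c(hdr, paste(names(df), collapse = ","), body_rows)
    if (identical(path, "")) writeLines(lines) else writeLines(lines, path)
  }
  invisible(path)
}

#' Read a sweep table written by [write_sweep_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return A `sweep_table` with metadata restored.
#' @export
read_sweep_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    md <- obj$metadata
    df <- as.data.frame(obj$columns)
  } else {
    lines <- readLines(path)
    is_meta <- grepl("^#", lines)
    md <- list()
    for (ln in lines[is_meta]) {
      kv <- sub("^#\\s*", "", ln)
      key <- sub(":.*$", "", kv)
      val <- trimws(sub("^[^:]*:", "", kv))
      num <- suppressWarnings(as.numeric(val))
      md[[key]] <- if (is.na(num)) val else num
    }
    df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  }
  new_sweep_table(df, md)
}

#' Generate a synthetic cohort of walkers
#'
#' Draws a reproducible cohort of leg lengths and step parameters, uniform
#' over ranges that span typical adult anthropometry (legs 0.75-1.00 m) and
#' the comfortable step-parameter band (1.15-1.55). Used as a fixture for
#' property tests: every cohort member has a valid geometry and an optimal
#' gradient in roughly the -13 % to -7 % band. The generator seeds a local
#' RNG stream and restores the caller's random state on exit.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param leg_range Leg-length range in metres. Default `c(0.75, 1.00)`.
#' @param k_range Step-parameter range. Default [k_comfort_default].
#' @return A data.frame with columns `leg_length`, `k` and attributes
#'   `seed`, `leg_range`, `k_range`; class `walker_cohort`.
#' @examples
#' generate_cohort(5, seed = 42)
#' @export
generate_cohort <- function(n, seed, leg_range = c(0.75, 1.00),
                            k_range = k_comfort_default) {
  check_scalar(n, "n")
  check_scalar(seed, "seed")
  if (n < 1) stop("cohort size n must be >= 1")
  ok_range <- function(r, lo) is.numeric(r) && length(r) == 2L &&
    all(is.finite(r)) && r[1] < r[2] && r[1] >= lo
  if (!ok_range(leg_range, lo = 1e-6))
    stop("leg_range must be an increasing positive range of length 2")
  if (!ok_range(k_range, lo = 0.5))
    stop("k_range must be an increasing range of length 2 with lower bound >= 0.5")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  df <- data.frame(
    leg_length = stats::runif(n, leg_range[1], leg_range[2]),
    k = stats::runif(n, k_range[1], k_range[2]))
  structure(df, seed = as.integer(seed), leg_range = leg_range,
            k_range = k_range, class = c("walker_cohort", "data.frame"))
}
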