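# Scaling study: sweep colony size N, collect steady-state kinematics of
# many quenched-disorder raft realizations, and fit power laws
# v_cm ~ N^b_v, |omega| ~ N^b_omega, R ~ N^b_R in log-log space.  The
# model predicts b_v = -1/4, b_omega = -3/4, b_R = +1/2.

#' Predicted scaling exponents of the contour-thrust model
#'
#' From `F_b ~ f sqrt(N_b)`, `T_b ~ r f sqrt(N_b)` with `r ~ N_b`,
#' `D ~ N_b`, `G ~ N_b^3` and `N_b ~ sqrt(N)`:
#' `v_cm ~ N^-0.25`, `omega ~ N^-0.75`, `R ~ N^+0.5`.
#'
#' @return Named list `b_v = -0.25`, `b_omega = -0.75`, `b_R = 0.5`.
#' @export
exponent_predictions <- function() {
  list(b_v = -0.25, b_omega = -0.75, b_R = 0.5)
}

#' Published population statistics used for calibration and comparison
#'
#' Experimental means and fractions measured for single swimmers and
#' microcolony rafts at the air-liquid interface, and the exponents fitted
#' to the experimental size sweeps.  These are fixture constants: they
#' calibrate the synthetic-data generator and anchor comparisons; they are
#' not reproducible from simulation.
#'
#' @return Named list: `single_mean_v` (12.4 um/s), `single_mean_R`
#'   (24.4 um), `single_cw_fraction` (0.14), `raft_mean_v` (2.31 um/s),
#'   `raft_mean_R` (17.68 um), `raft_cw_fraction` (0.49), and the fitted
#'   experimental exponents `b_v`, `b_omega`, `b_R` with their
#'   half-widths `b_v_err`, `b_omega_err`, `b_R_err`.
#' @export
reference_stats <- function() {
  list(single_mean_v = 12.4, single_mean_R = 24.4, single_cw_fraction = 0.14,
       raft_mean_v = 2.31, raft_mean_R = 17.68, raft_cw_fraction = 0.49,
       b_v = -0.31, b_v_err = 0.08,
       b_omega = -0.36, b_omega_err = 0.14,
       b_R = -0.025, b_R_err = 0.010)
}

#' Sweep raft sizes and collect steady-state kinematics
#'
#' For each colony size in `n_grid`, draws `reps` independent raft
#' realizations and records their steady-state kinematics.  Each raft gets
#' a named sub-stream seed derived from `master_seed` and its (size,
#' replicate) index, so the sweep is reproducible row by row.
#'
#' @param n_grid strictly increasing vector of colony sizes N.
#' @param reps replicates per size (>= 1).
#' @param params a [raft_params()] object.
#' @param master_seed integer master seed.
#' @return Data frame with one row per (N, replicate): `n_total`, `rep`,
#'   `seed`, `v_cm`, `omega` (signed), `radius_curv` (`NA` when
#'   undefined), `handedness`.
#' @examples
#' tab <- sweep_raft_sizes(c(16, 64), reps = 5, master_seed = 1)
#' head(tab)
#' @export
sweep_raft_sizes <- function(n_grid, reps, params = raft_params(),
                             master_seed) {
  if (length(n_grid) < 1L) stop("`n_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be strictly increasing", call. = FALSE)
  }
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (missing(master_seed)) stop("`master_seed` is required", call. = FALSE)
  rows <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    v <- om <- rc <- numeric(reps)
    sd_i <- integer(reps)
    hand <- character(reps)
    for (j in seq_len(reps)) {
      s <- spawn_seed(master_seed, i, j)
      kin <- steady_kinematics(build_raft(n, params, seed = s))
      sd_i[j] <- s
      v[j] <- kin$v_cm
      om[j] <- kin$omega
      rc[j] <- kin$radius_curv
      hand[j] <- kin$handedness
    }
    rows[[i]] <- data.frame(n_total = n, rep = seq_len(reps), seed = sd_i,
                            v_cm = v, omega = om, radius_curv = rc,
                            handedness = hand)
  }
  do.call(rbind, rows)
}

#' Fit a power law y = a * x^b by log-log least squares on binned data
#'
#' Bins `x` geometrically (log-spaced edges); when `x` takes at most
#' `n_bins` distinct values (e.g. a size sweep on a fixed grid) each
#' distinct value is its own bin.  Within each bin the chosen central
#' statistic of `y` (arithmetic mean or median) is paired with the
#' geometric mean of `x`, and ordinary least squares is run on
#' `(log10 x_bin, log10 y_bin)`.  Uncertainty comes from a nonparametric
#' bootstrap over the raw `(x, y)` points: each resample is re-binned and
#' re-fit, and the 95% percentile interval of the exponents is reported.
#'
#' @param x,y positive numeric vectors of equal length.
#' @param n_bins number of geometric bins (default 8).
#' @param statistic `"mean"` or `"median"`; use the median for heavy-tailed
#'   quantities such as the radius of curvature, whose mean diverges
#'   because the torque in the denominator is Gaussian around zero.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `power_law_fit`: list with `exponent`,
#'   `prefactor`, `ci_low`, `ci_high`, `n_bins` (non-empty bins used),
#'   `statistic`, `bin_x`, `bin_y`, `n_points`.
#' @examples
#' x <- rep(c(16, 32, 64, 128), each = 50)
#' y <- 3 * x^-0.25
#' fit_power_law(x, y, seed = 1)$exponent
#' @export
fit_power_law <- function(x, y, n_bins = 8L, statistic = c("mean", "median"),
                          n_boot = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0) || any(y <= 0)) {
    stop("all `x` and `y` values must be strictly positive", call. = FALSE)
  }
  if (length(x) != length(y)) stop("`x`, `y` lengths differ", call. = FALSE)
  stat_fun <- if (statistic == "mean") mean else stats::median

  bin_index <- function(x) {
    ux <- sort(unique(x))
    if (length(ux) <= n_bins) {
      match(x, ux)
    } else {
      edges <- 10^seq(log10(min(x)), log10(max(x)), length.out = n_bins + 1L)
      edges[1] <- edges[1] * (1 - 1e-12)
      edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-12)
      findInterval(x, edges, rightmost.closed = TRUE)
    }
  }
  # bin representative for x: geometric mean under the mean statistic,
  # median under the median statistic (so a noiseless power law stays
  # exactly on the fitted line)
  x_rep <- if (statistic == "mean") {
    function(v) exp(mean(log(v)))
  } else {
    stats::median
  }
  one_fit <- function(x, y) {
    idx <- bin_index(x)
    bx <- tapply(x, idx, x_rep)
    by <- tapply(y, idx, stat_fun)
    ok <- is.finite(bx) & is.finite(by) & by > 0
    bx <- bx[ok]; by <- by[ok]
    if (length(bx) < 2L) {
      stop("fewer than 2 non-empty bins; cannot fit a power law",
           call. = FALSE)
    }
    co <- stats::lm.fit(cbind(1, log10(bx)), log10(by))$coefficients
    list(exponent = unname(co[2]), prefactor = 10^unname(co[1]),
         bin_x = as.numeric(bx), bin_y = as.numeric(by))
  }

  fit <- one_fit(x, y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(x)
    bexp <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ii <- sample.int(n, n, replace = TRUE)
        tryCatch(one_fit(x[ii], y[ii])$exponent, error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(bexp, c(0.025, 0.975), na.rm = TRUE))
    # the point estimate always lies inside the reported interval
    ci[1] <- min(ci[1], fit$exponent)
    ci[2] <- max(ci[2], fit$exponent)
  }
  structure(list(exponent = fit$exponent, prefactor = fit$prefactor,
                 ci_low = ci[1], ci_high = ci[2],
                 n_bins = length(fit$bin_x), statistic = statistic,
                 bin_x = fit$bin_x, bin_y = fit$bin_y,
                 n_points = length(x), n_boot = n_boot),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (%s of %d points in %d bins): y = %.4g * x^%.4f\n",
    x$statistic, x$n_points, x$n_bins, x$prefactor, x$exponent))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI for exponent: [%.4f, %.4f]\n",
                x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Compare a fitted exponent with a predicted or reference value
#'
#' @param fit a [fit_power_law()] object.
#' @param predicted a single predicted exponent, or a named list
#'   containing one (e.g. an element of [exponent_predictions()]).
#' @param label optional name for the comparison.
#' @return Data frame with columns `label`, `fitted`, `ci_low`, `ci_high`,
#'   `predicted`, `abs_difference`, `inside_ci`.  No thresholding beyond
#'   the CI-containment flag is applied.
#' @export
compare_exponents <- function(fit, predicted, label = "exponent") {
  stopifnot(inherits(fit, "power_law_fit"))
  p <- as.numeric(predicted)
  if (length(p) != 1L || !is.finite(p)) {
    stop("`predicted` must be a single finite number", call. = FALSE)
  }
  data.frame(label = label, fitted = fit$exponent,
             ci_low = fit$ci_low, ci_high = fit$ci_high,
             predicted = p, abs_difference = abs(fit$exponent - p),
             inside_ci = is.finite(fit$ci_low) &&
               fit$ci_low <= p && p <= fit$ci_high)
}

#' Fit the three scaling laws of a size sweep
#'
#' Convenience wrapper: fits `mean v_cm` vs N, `mean |omega|` vs N and
#' `median R` vs N from a [sweep_raft_sizes()] table and compares each
#' with the model predictions.
#'
#' @param sweep a [sweep_raft_sizes()] data frame.
#' @param n_boot,seed passed to [fit_power_law()].
#' @return List with `fits` (named list of `power_law_fit`) and
#'   `comparison` (stacked [compare_exponents()] rows).
#' @export
fit_sweep_scalings <- function(sweep, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("n_total", "v_cm", "omega", "radius_curv") %in%
                  names(sweep)))
  pred <- exponent_predictions()
  fits <- list(
    v_cm = fit_power_law(sweep$n_total, sweep$v_cm,
                         statistic = "mean", n_boot = n_boot,
                         seed = spawn_seed(seed, 101)),
    omega = fit_power_law(sweep$n_total, abs(sweep$omega),
                          statistic = "mean", n_boot = n_boot,
                          seed = spawn_seed(seed, 102)),
    radius_curv = fit_power_law(sweep$n_total, sweep$radius_curv,
                                statistic = "median", n_boot = n_boot,
                                seed = spawn_seed(seed, 103)))
  comparison <- rbind(
    compare_exponents(fits$v_cm, pred$b_v, "b_v"),
    compare_exponents(fits$omega, pred$b_omega, "b_omega"),
    compare_exponents(fits$radius_curv, pred$b_R, "b_R"))
  list(fits = fits, comparison = comparison)
}
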