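# Contour-thrust raft model: an E. coli microcolony trapped at an
# air-liquid interface is treated as a rigid circular disk ("raft") in the
# overdamped limit.  Only the N_b bacteria on the contour exert thrust;
# each pushes with the same force magnitude f at a random, quenched angle
# fixed in the co-rotating body frame.  The net force and torque are sums
# of iid terms, so their statistics follow the central limit theorem, and
# the steady state is uniform circular motion whose speed, angular
# velocity and radius of curvature inherit power-law scalings in the
# colony size N.

#' Model parameters for the contour-thrust raft
#'
#' All quantities are expressed in nondimensional model units by default
#' (`f = d0 = g0 = cell_size = 1`): the scaling exponents of the model are
#' unit-free, so the prefactors only shift intercepts in log-log space.
#'
#' @param f per-bacterium thrust magnitude (force units).
#' @param d0 translational drag per contour bacterium (force time / length);
#'   total translational drag is `D = d0 * n_contour`.
#' @param g0 rotational drag prefactor (force length time); total rotational
#'   drag is `G = g0 * n_contour^3`.
#' @param cb contour-count coefficient: a disk of N unit-area cells has
#'   perimeter `2 * sqrt(pi * N)`, so the number of contour bacteria is
#'   `max(3, round(cb * sqrt(N)))` with `cb = 2 * sqrt(pi)` by default.
#' @param cell_size length unit per bacterium; the raft radius is
#'   `cell_size * sqrt(N / pi)`.
#' @return An object of class `raft_params`.
#' @examples
#' raft_params()
#' raft_params(f = 2, cell_size = 1.5)
#' @export
raft_params <- function(f = 1, d0 = 1, g0 = 1, cb = 2 * sqrt(pi),
                        cell_size = 1) {
  stop_if_not_scalar_positive(f, "f")
  stop_if_not_scalar_positive(d0, "d0")
  stop_if_not_scalar_positive(g0, "g0")
  stop_if_not_scalar_positive(cb, "cb")
  stop_if_not_scalar_positive(cell_size, "cell_size")
  structure(list(f = f, d0 = d0, g0 = g0, cb = cb, cell_size = cell_size),
            class = "raft_params")
}

#' @export
print.raft_params <- function(x, ...) {
  cat("Contour-thrust raft model parameters\n")
  cat(sprintf("  f = %g, d0 = %g, g0 = %g, cb = %g, cell_size = %g\n",
              x$f, x$d0, x$g0, x$cb, x$cell_size))
  invisible(x)
}

#' Number of contour bacteria for a colony of N cells
#'
#' @param n_total number of bacteria in the colony (N >= 1).
#' @param cb contour-count coefficient (default `2 * sqrt(pi)`).
#' @return Integer `max(3, round(cb * sqrt(n_total)))`; the floor of 3
#'   avoids degenerate rafts.
#' @export
contour_count <- function(n_total, cb = 2 * sqrt(pi)) {
  pmax(3L, as.integer(round(cb * sqrt(n_total))))
}

#' Build one raft realization
#'
#' Draws a single realization of the quenched disorder: `n_contour`
#' bacteria equally spaced on a circle of radius `cell_size * sqrt(N/pi)`,
#' each with a body-frame force angle drawn iid uniform on \[0, 2 pi).
#' The angles are fixed once per raft and co-rotate with the body frame.
#'
#' @param n_total colony size N (positive integer).
#' @param params a [raft_params()] object.
#' @param seed integer RNG seed; the realization is deterministic given
#'   `(n_total, params, seed)`.
#' @return An object of class `raft` with fields `n_total`, `n_contour`,
#'   `radius`, `contour_positions` (`n_contour` x 2 matrix, body frame),
#'   `force_angles`, `params`, `seed`.
#' @examples
#' r <- build_raft(64, raft_params(), seed = 1)
#' r$n_contour # max(3, round(2*sqrt(pi)*8)) = 28
#' @export
build_raft <- function(n_total, params = raft_params(), seed) {
  if (!is.numeric(n_total) || length(n_total) != 1L || !is.finite(n_total) ||
      n_total < 1 || n_total != round(n_total)) {
    stop("`n_total` must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(params, "raft_params"))
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)
  n_b <- contour_count(n_total, params$cb)
  radius <- params$cell_size * sqrt(n_total / pi)
  beta <- 2 * pi * (seq_len(n_b) - 1) / n_b
  pos <- cbind(x = radius * cos(beta), y = radius * sin(beta))
  alpha <- with_seed(seed, stats::runif(n_b, 0, 2 * pi))
  structure(list(n_total = as.integer(n_total), n_contour = n_b,
                 radius = radius, contour_positions = pos,
                 force_angles = alpha, params = params,
                 seed = as.integer(seed)),
            class = "raft")
}

#' @export
print.raft <- function(x, ...) {
  cat(sprintf("Raft realization: N = %d, N_b = %d, radius = %.3f (seed %d)\n",
              x$n_total, x$n_contour, x$radius, x$seed))
  invisible(x)
}

#' Net propulsive force and torque of a raft
#'
#' The net body-frame force is `F_b = sum_i f (cos a_i, sin a_i)` and the
#' net torque about the center is `T_b = sum_i (r_i x f_i) . z`, computed
#' from the cross products of the contour positions with the individual
#' forces.  For the circular raft this equals `r f sum_i sin(phi_i)` with
#' `phi_i` the angle from `r_i` to `f_i`.
#'
#' @param raft a [build_raft()] object.
#' @return List with `force` (length-2 numeric, body frame) and `torque`
#'   (scalar, positive = counterclockwise).
#' @export
net_propulsion <- function(raft) {
  stopifnot(inherits(raft, "raft"))
  f <- raft$params$f
  fx <- f * cos(raft$force_angles)
  fy <- f * sin(raft$force_angles)
  pos <- raft$contour_positions
  list(force = c(sum(fx), sum(fy)),
       torque = sum(pos[, 1] * fy - pos[, 2] * fx))
}

#' Steady-state kinematics of a raft
#'
#' In the overdamped limit the raft's steady motion is uniform rotation:
#' speed `v_cm = |F_b| / D` with `D = d0 * N_b`, signed angular velocity
#' `omega = T_b / G` with `G = g0 * N_b^3`, and radius of curvature
#' `R = v_cm / |omega|`.  A positive `omega` (torque) is counterclockwise.
#'
#' @param raft a [build_raft()] object.
#' @return Object of class `raft_kinematics`: list with `v_cm`, `omega`,
#'   `radius_curv` (`NA` with `radius_defined = FALSE` when `omega == 0`),
#'   `handedness` (`"CCW"`, `"CW"` or `"NONE"`), and the net `force` and
#'   `torque` used.
#' @examples
#' k <- steady_kinematics(build_raft(256, seed = 7))
#' k$v_cm; k$omega; k$handedness
#' @export
steady_kinematics <- function(raft) {
  stopifnot(inherits(raft, "raft"))
  prop <- net_propulsion(raft)
  D <- raft$params$d0 * raft$n_contour
  G <- raft$params$g0 * raft$n_contour^3
  v_cm <- sqrt(sum(prop$force^2)) / D
  omega <- prop$torque / G
  if (omega == 0) {
    rc <- NA_real_
    hand <- "NONE"
    defined <- FALSE
  } else {
    rc <- v_cm / abs(omega)
    hand <- if (omega > 0) "CCW" else "CW"
    defined <- TRUE
  }
  structure(list(v_cm = v_cm, omega = omega, radius_curv = rc,
                 radius_defined = defined, handedness = hand,
                 force = prop$force, torque = prop$torque, D = D, G = G),
            class = "raft_kinematics")
}

#' @export
print.raft_kinematics <- function(x, ...) {
  cat(sprintf("Raft kinematics: v_cm = %.4g, omega = %.4g (%s), R = %.4g\n",
              x$v_cm, x$omega, x$handedness, x$radius_curv))
  invisible(x)
}

#' Propagate a raft trajectory
#'
#' Integrates the overdamped rigid-body motion.  Because the thrust angles
#' co-rotate with the body frame, the lab-frame equations are
#' `dx/dt = R(theta) F_b / D`, `dtheta/dt = T_b / G`, whose exact solution
#' is uniform circular motion.  `dt = "closed_form"` returns that exact
#' solution sampled at `n_steps + 1` instants; a numeric `dt` integrates
#' with a classical 4th-order Runge-Kutta step (requires
#' `|omega| * dt < 0.1`).
#'
#' @param raft a [build_raft()] object.
#' @param duration total time (> 0).
#' @param dt time step, or `"closed_form"` for the exact solution.
#' @param n_steps number of samples for closed-form mode (default 200).
#' @param x0,theta0 initial center position (length 2) and orientation.
#' @return Object of class `raft_trajectory`: data frame with columns
#'   `t`, `x`, `y`, `theta` (theta unwrapped), plus the generating
#'   kinematics as attribute `"kinematics"`.
#' @export
propagate <- function(raft, duration, dt = "closed_form", n_steps = 200L,
                      x0 = c(0, 0), theta0 = 0) {
  stopifnot(inherits(raft, "raft"))
  stop_if_not_scalar_positive(duration, "duration")
  kin <- steady_kinematics(raft)
  D <- kin$D
  fb <- kin$force
  omega <- kin$omega
  if (identical(dt, "closed_form")) {
    tt <- seq(0, duration, length.out = n_steps + 1L)
    theta <- theta0 + omega * tt
    vb <- fb / D # body-frame velocity
    if (omega == 0) {
      v0 <- rot2(theta0) %*% vb
      x <- x0[1] + tt * v0[1]
      y <- x0[2] + tt * v0[2]
    } else {
      # x(t) = x0 - (1/omega) J (R(theta(t)) - R(theta0)) v_b,
      # with J the quarter-turn matrix: exact uniform circular motion
      vx <- cos(theta) * vb[1] - sin(theta) * vb[2]
      vy <- sin(theta) * vb[1] + cos(theta) * vb[2]
      vx0 <- cos(theta0) * vb[1] - sin(theta0) * vb[2]
      vy0 <- sin(theta0) * vb[1] + cos(theta0) * vb[2]
      x <- x0[1] + (vy - vy0) / omega
      y <- x0[2] - (vx - vx0) / omega
    }
  } else {
    stop_if_not_scalar_positive(dt, "dt")
    if (abs(omega) * dt >= 0.1) {
      stop(sprintf(
        "time step too large: |omega| * dt = %.3g >= 0.1; reduce dt",
        abs(omega) * dt), call. = FALSE)
    }
    n <- max(1L, as.integer(ceiling(duration / dt - 1e-9)))
    tt <- seq(0, by = dt, length.out = n + 1L)
    state <- matrix(NA_real_, n + 1L, 3L)
    state[1, ] <- c(x0, theta0)
    deriv <- function(s) {
      th <- s[3]
      v <- c(cos(th) * fb[1] - sin(th) * fb[2],
             sin(th) * fb[1] + cos(th) * fb[2]) / D
      c(v, omega)
    }
    for (i in seq_len(n)) {
      s <- state[i, ]
      k1 <- deriv(s)
      k2 <- deriv(s + dt / 2 * k1)
      k3 <- deriv(s + dt / 2 * k2)
      k4 <- deriv(s + dt * k3)
      state[i + 1L, ] <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x <- state[, 1]; y <- state[, 2]; theta <- state[, 3]
  }
  out <- data.frame(t = tt, x = x, y = y, theta = theta)
  attr(out, "kinematics") <- kin
  class(out) <- c("raft_trajectory", "data.frame")
  out
}

#' Monte-Carlo statistics of the net thrust force and torque
#'
#' Over many independent draws of the `n_contour` uniform force angles the
#' net force components are sums of iid `f cos(a_i)` / `f sin(a_i)` terms
#' with variance `f^2 / 2` each, so their standard deviations are
#' `f * sqrt(N_b / 2)`; the net torque `r f sum(sin phi_i)` likewise has
#' standard deviation `r f * sqrt(N_b / 2)`.  The function returns both
#' the Monte-Carlo estimates and these analytic values for audit.
#'
#' @param n_contour number of contour bacteria (N_b >= 1).
#' @param params a [raft_params()] object; the radius entering the torque
#'   is taken as `r = 1` unless `radius` is supplied.
#' @param n_samples number of Monte-Carlo raft draws (>= 1000).
#' @param seed RNG seed.
#' @param radius raft radius used in the torque (default 1).
#' @return Object of class `thrust_stats`: list with `n_contour`,
#'   `std_fx`, `std_fy`, `std_torque` (Monte-Carlo), `analytic_std_force`
#'   (`f * sqrt(N_b/2)`), `analytic_std_torque` (`r * f * sqrt(N_b/2)`),
#'   `n_samples`, `seed`.
#' @export
thrust_statistics <- function(n_contour, params = raft_params(),
                              n_samples = 1e6, seed, radius = 1) {
  stopifnot(inherits(params, "raft_params"))
  if (n_contour < 1 || n_contour != round(n_contour)) {
    stop("`n_contour` must be a positive integer", call. = FALSE)
  }
  if (n_samples < 1e3) stop("`n_samples` must be >= 1000", call. = FALSE)
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)
  stop_if_not_scalar_positive(radius, "radius")
  f <- params$f
  n_b <- as.integer(n_contour)
  # chunked so the n_samples x N_b angle matrix never exceeds ~40 MB
  chunk <- max(1L, as.integer(5e6 %/% n_b))
  beta <- 2 * pi * (seq_len(n_b) - 1) / n_b # equally spaced contour bearings
  sums <- with_seed(seed, {
    sfx <- numeric(0); sfy <- numeric(0); stq <- numeric(0)
    left <- as.integer(n_samples)
    while (left > 0L) {
      m <- min(chunk, left)
      a <- matrix(stats::runif(m * n_b, 0, 2 * pi), m, n_b)
      sfx <- c(sfx, f * rowSums(cos(a)))
      sfy <- c(sfy, f * rowSums(sin(a)))
      # torque per bacterium is r f sin(phi_i) with phi_i = alpha_i - beta_i
      stq <- c(stq, radius * f * rowSums(sin(sweep(a, 2L, beta, "-"))))
      left <- left - m
    }
    list(fx = sfx, fy = sfy, tq = stq)
  })
  structure(list(
    n_contour = n_b,
    std_fx = stats::sd(sums$fx),
    std_fy = stats::sd(sums$fy),
    std_torque = stats::sd(sums$tq),
    analytic_std_force = f * sqrt(n_b / 2),
    analytic_std_torque = radius * f * sqrt(n_b / 2),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed)), class = "thrust_stats")
}

#' @export
print.thrust_stats <- function(x, ...) {
  cat(sprintf(
    "Thrust statistics (N_b = %d, %d samples)\n", x$n_contour, x$n_samples))
  cat(sprintf("  std F_x = %.4f, std F_y = %.4f (analytic %.4f)\n",
              x$std_fx, x$std_fy, x$analytic_std_force))
  cat(sprintf("  std T_b = %.4f (analytic %.4f)\n",
              x$std_torque, x$analytic_std_torque))
  invisible(x)
}
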