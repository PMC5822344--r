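# Fixtures built in code: exact geometric tracks with known ground truth.

# points on a circle of radius R about `center`, at the given polar angles
circle_points <- function(center, R, angles) {
  cbind(center[1] + R * cos(angles), center[2] + R * sin(angles))
}

# one exact circular-arc leg starting at p0 with heading psi, counter-
# clockwise for h = +1; returns the n positions after p0 and the final
# heading
arc_leg <- function(p0, psi, h, v, R, n, fps) {
  om <- h * v / R
  cc <- c(p0[1] - h * R * sin(psi), p0[2] + h * R * cos(psi))
  phi0 <- atan2(p0[2] - cc[2], p0[1] - cc[1])
  tau <- seq_len(n) / fps
  list(x = cc[1] + R * cos(phi0 + om * tau),
       y = cc[2] + R * sin(phi0 + om * tau),
       psi = psi + om * max(tau))
}

# a trajectory made of two exact circular arcs joined by a tumble:
# `pause` stationary frames and a `turn` heading change at the cusp.
two_arc_track <- function(arc_frames = 60L, pause = 5L, v = 12, R = 24,
                          fps = 50, turn = 2 * pi / 3) {
  leg1 <- arc_leg(c(0, 0), 0, +1, v, R, arc_frames, fps)
  x <- c(0, leg1$x)
  y <- c(0, leg1$y)
  x <- c(x, rep(x[length(x)], pause))
  y <- c(y, rep(y[length(y)], pause))
  leg2 <- arc_leg(c(x[length(x)], y[length(y)]), leg1$psi + turn, +1,
                  v, R, arc_frames, fps)
  x <- c(x, leg2$x)
  y <- c(y, leg2$y)
  n <- length(x)
  list(traj = trajectory("two_arc", seq_len(n) - 1L, x, y, fps),
       cusp_first = arc_frames + 2L, cusp_last = arc_frames + 1L + pause,
       v = v, R = R)
}

# a raft object with contour positions and force angles set by hand,
# bypassing the contour-count rule (for single-bacterium / antipodal
# configurations)
bare_raft <- function(positions, angles, params = raft_params()) {
  positions <- rbind(positions)
  structure(list(n_total = nrow(positions), n_contour = nrow(positions),
                 radius = sqrt(sum(positions[1, ]^2)),
                 contour_positions = positions,
                 force_angles = angles, params = params, seed = NA_integer_),
            class = "raft")
}

# a standard raft whose quenched angles are overridden
forced_raft <- function(n_total, angles, params = raft_params(), seed = 1L) {
  r <- build_raft(n_total, params, seed = seed)
  stopifnot(length(angles) == r$n_contour)
  r$force_angles <- angles
  r
}
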