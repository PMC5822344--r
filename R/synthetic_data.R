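# Synthetic track generator: run-and-tumble circular-arc swimmers and
# rigid raft marker pairs, with per-track ground truth, in the same
# track-table dialect the analysis consumes.  Defaults are calibrated to
# the published population means (single swimmers: mean speed 12.4 um/s,
# mean R 24.4 um, 14% CW; rafts: mean speed 2.31 um/s, mean R 17.68 um,
# 49% CW) so pipeline round trips exercise realistic statistics.

#' Parameters for the single-swimmer track generator
#'
#' @param n_swimmers number of tracks.
#' @param mean_speed mean arc speed, um/s (default 12.4, the published
#'   single-swimmer mean).
#' @param speed_cv coefficient of variation of the lognormal per-arc speed
#'   draw (default 0.4).
#' @param mean_R mean arc radius of curvature, um (default 24.4).
#' @param R_cv coefficient of variation of the per-arc radius (default 0.4).
#' @param p_ccw probability that a swimmer is counterclockwise (default
#'   0.86, i.e. 14% CW); handedness is fixed per swimmer.
#' @param tumble_rate tumbling rate, 1/s (default 0.5; arc durations are
#'   exponential with this rate; 0 disables tumbling).
#' @param tumble_pause stop duration at each tumble, frames (default 5).
#' @param frame_rate frames per second (default 50).
#' @param duration track length, s (default 10).
#' @param noise_sigma Gaussian localization noise, um (default 0.05).
#' @param seed RNG seed.
#' @return Object of class `swimmer_gen_params`.
#' @export
swimmer_gen_params <- function(n_swimmers = 100L, mean_speed = 12.4,
                               speed_cv = 0.4, mean_R = 24.4, R_cv = 0.4,
                               p_ccw = 0.86, tumble_rate = 0.5,
                               tumble_pause = 5L, frame_rate = 50,
                               duration = 10, noise_sigma = 0.05,
                               seed = 1L) {
  stopifnot(p_ccw >= 0, p_ccw <= 1, n_swimmers >= 1, mean_speed > 0,
            mean_R > 0, frame_rate > 0, duration > 0, tumble_rate >= 0,
            noise_sigma >= 0, tumble_pause >= 0)
  structure(as.list(environment()), class = "swimmer_gen_params")
}

#' Parameters for the raft marker-pair track generator
#'
#' Two tracked markers per raft, rigidly attached at `marker_offsets`
#' (body-frame positions, um).  Kinematics come either from lognormal
#' draws around the published raft means (`kinematics = "reference"`) or
#' from contour-thrust raft realizations (`kinematics = "model"`, in
#' model units).
#'
#' @param n_rafts number of rafts.
#' @param kinematics `"reference"` or `"model"`.
#' @param mean_v,v_cv,mean_R,R_cv,p_ccw lognormal calibration used by the
#'   reference mode (defaults: 2.31 um/s, 17.68 um, 51% CCW).
#' @param n_total colony size(s) used by the model mode (recycled across
#'   rafts).
#' @param model_params a [raft_params()] for the model mode.
#' @param marker_offsets 2 x 2 matrix, one body-frame offset per row
#'   (default two points 5 um from the center, 90 degrees apart).
#' @param noise_sigma,frame_rate,duration,seed as in
#'   [swimmer_gen_params()].
#' @return Object of class `raft_gen_params`.
#' @export
raft_gen_params <- function(n_rafts = 50L, kinematics = c("reference", "model"),
                            mean_v = 2.31, v_cv = 0.4, mean_R = 17.68,
                            R_cv = 0.4, p_ccw = 0.51, n_total = 64L,
                            model_params = raft_params(),
                            marker_offsets = rbind(c(5, 0), c(0, 5)),
                            noise_sigma = 0.05, frame_rate = 50,
                            duration = 10, seed = 1L) {
  kinematics <- match.arg(kinematics)
  stopifnot(n_rafts >= 1, mean_v > 0, mean_R > 0, p_ccw >= 0, p_ccw <= 1,
            noise_sigma >= 0, frame_rate > 0, duration > 0,
            is.matrix(marker_offsets), nrow(marker_offsets) == 2L)
  structure(as.list(environment()), class = "raft_gen_params")
}

# lognormal with prescribed arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate run-and-tumble single-swimmer tracks
#'
#' Each swimmer's handedness is drawn once; its trajectory is a sequence
#' of exact circular arcs (per-arc speed and radius lognormal around the
#' configured means) separated by tumbles: a pause of `tumble_pause`
#' frames followed by a uniformly redrawn heading.  Positions are sampled
#' at `frame_rate` and perturbed by isotropic Gaussian noise.
#'
#' @param params a [swimmer_gen_params()] object.
#' @return List with `tracks` (list of [trajectory()]) and `truth`:
#'   a data frame of per-arc ground truth (`track_id`, `arc_index`, `v`,
#'   `R`, `handedness`, `start_frame`, `end_frame`) plus attribute
#'   `swimmer_truth` (per-swimmer handedness table).
#' @export
gen_single_swimmers <- function(params = swimmer_gen_params()) {
  stopifnot(inherits(params, "swimmer_gen_params"))
  p <- params
  n_frames <- as.integer(round(p$duration * p$frame_rate))
  tracks <- list()
  truth_rows <- list()
  swimmer_hand <- character(p$n_swimmers)
  for (s in seq_len(p$n_swimmers)) {
    id <- sprintf("sw%04d", s)
    res <- with_seed(spawn_seed(p$seed, 1, s), {
      h <- if (stats::runif(1) < p$p_ccw) 1 else -1
      x <- numeric(n_frames + 1L)
      y <- numeric(n_frames + 1L)
      x[1] <- stats::runif(1, -100, 100)
      y[1] <- stats::runif(1, -100, 100)
      psi <- stats::runif(1, 0, 2 * pi)
      arcs <- list()
      k <- 1L # current frame index (1-based position sample)
      while (k <= n_frames) {
        v <- rlnorm_mean_cv(1, p$mean_speed, p$speed_cv)
        R <- rlnorm_mean_cv(1, p$mean_R, p$R_cv)
        run_frames <- if (p$tumble_rate > 0) {
          max(2L, as.integer(ceiling(stats::rexp(1, p$tumble_rate) *
                                       p$frame_rate)))
        } else {
          n_frames
        }
        run_frames <- min(run_frames, n_frames - k + 1L)
        # exact circular arc: center sits at distance R on the left
        # (CCW, h = +1) or right (CW) of the heading
        cxc <- x[k] - h * R * sin(psi)
        cyc <- y[k] + h * R * cos(psi)
        phi0 <- atan2(y[k] - cyc, x[k] - cxc)
        om <- h * v / R
        tau <- seq_len(run_frames) / p$frame_rate
        idx <- k + seq_len(run_frames)
        x[idx] <- cxc + R * cos(phi0 + om * tau)
        y[idx] <- cyc + R * sin(phi0 + om * tau)
        psi <- psi + om * tau[run_frames]
        arcs[[length(arcs) + 1L]] <-
          data.frame(track_id = id, arc_index = length(arcs) + 1L,
                     v = v, R = R,
                     handedness = if (h > 0) "CCW" else "CW",
                     start_frame = k - 1L,
                     end_frame = k - 1L + run_frames)
        k <- k + run_frames
        if (k <= n_frames && p$tumble_pause > 0) { # tumble: stop, reorient
          pause <- min(as.integer(p$tumble_pause), n_frames - k + 1L)
          idx <- k + seq_len(pause)
          x[idx] <- x[k]
          y[idx] <- y[k]
          k <- k + pause
        }
        if (k <= n_frames) psi <- stats::runif(1, 0, 2 * pi)
      }
      if (p$noise_sigma > 0) {
        x <- x + stats::rnorm(n_frames + 1L, 0, p$noise_sigma)
        y <- y + stats::rnorm(n_frames + 1L, 0, p$noise_sigma)
      }
      list(x = x, y = y, h = h, arcs = do.call(rbind, arcs))
    })
    tracks[[id]] <- trajectory(id, 0:n_frames, res$x, res$y, p$frame_rate)
    truth_rows[[s]] <- res$arcs
    swimmer_hand[s] <- if (res$h > 0) "CCW" else "CW"
  }
  truth <- do.call(rbind, truth_rows)
  attr(truth, "swimmer_truth") <-
    data.frame(track_id = names(tracks), handedness = swimmer_hand)
  list(tracks = tracks, truth = truth)
}

#' Generate rigid raft marker-pair tracks
#'
#' Each raft undergoes exact uniform circular motion (its center moves on
#' a circle of radius `R = v_cm / |omega|` while the body rotates at
#' `omega`); two markers rigidly attached at the configured body-frame
#' offsets are sampled at `frame_rate` with Gaussian noise.  In
#' `"model"` mode the kinematics of each raft come from a contour-thrust
#' realization via [steady_kinematics()]; in `"reference"` mode they are
#' drawn lognormally around the published raft means.
#'
#' @param params a [raft_gen_params()] object.
#' @return List with `tracks` (two [trajectory()] per raft, ids
#'   `raft<k>_m1` / `raft<k>_m2`) and `truth`: data frame with one row
#'   per raft (`raft_id`, `n_total`, `v_cm`, `omega`, `R`, `handedness`,
#'   `center0_x`, `center0_y`).
#' @export
gen_raft_marker_tracks <- function(params = raft_gen_params()) {
  stopifnot(inherits(params, "raft_gen_params"))
  p <- params
  n_frames <- as.integer(round(p$duration * p$frame_rate))
  tt <- (0:n_frames) / p$frame_rate
  n_tot <- rep_len(p$n_total, p$n_rafts)
  tracks <- list()
  rows <- vector("list", p$n_rafts)
  for (k in seq_len(p$n_rafts)) {
    raft_seed <- spawn_seed(p$seed, 2, k)
    if (p$kinematics == "model") {
      kin <- steady_kinematics(build_raft(n_tot[k], p$model_params,
                                          seed = raft_seed))
      v <- kin$v_cm; om <- kin$omega
      n_rec <- as.integer(n_tot[k])
    } else {
      draws <- with_seed(raft_seed, {
        list(v = rlnorm_mean_cv(1, p$mean_v, p$v_cv),
             R = rlnorm_mean_cv(1, p$mean_R, p$R_cv),
             ccw = stats::runif(1) < p$p_ccw)
      })
      v <- draws$v
      om <- (if (draws$ccw) 1 else -1) * draws$v / draws$R
      n_rec <- NA_integer_
    }
    noise_seed <- spawn_seed(p$seed, 3, k)
    place <- with_seed(noise_seed, {
      list(x0 = stats::runif(1, -100, 100), y0 = stats::runif(1, -100, 100),
           theta0 = stats::runif(1, 0, 2 * pi),
           eps = stats::rnorm(4L * (n_frames + 1L), 0, p$noise_sigma))
    })
    theta <- place$theta0 + om * tt
    # center velocity direction co-rotates with the body: integrating
    # dx/dt = v (cos theta, sin theta) exactly gives a circle of radius
    # v/|omega| (or a straight line when omega = 0)
    if (om == 0) {
      cx <- place$x0 + v * tt * cos(place$theta0)
      cy <- place$y0 + v * tt * sin(place$theta0)
    } else {
      cx <- place$x0 + v / om * (sin(theta) - sin(place$theta0))
      cy <- place$y0 - v / om * (cos(theta) - cos(place$theta0))
    }
    id1 <- sprintf("raft%03d_m1", k)
    id2 <- sprintf("raft%03d_m2", k)
    off <- p$marker_offsets
    m1x <- cx + cos(theta) * off[1, 1] - sin(theta) * off[1, 2]
    m1y <- cy + sin(theta) * off[1, 1] + cos(theta) * off[1, 2]
    m2x <- cx + cos(theta) * off[2, 1] - sin(theta) * off[2, 2]
    m2y <- cy + sin(theta) * off[2, 1] + cos(theta) * off[2, 2]
    if (p$noise_sigma > 0) {
      e <- matrix(place$eps, ncol = 4L)
      m1x <- m1x + e[, 1]; m1y <- m1y + e[, 2]
      m2x <- m2x + e[, 3]; m2y <- m2y + e[, 4]
    }
    tracks[[id1]] <- trajectory(id1, 0:n_frames, m1x, m1y, p$frame_rate)
    tracks[[id2]] <- trajectory(id2, 0:n_frames, m2x, m2y, p$frame_rate)
    rows[[k]] <- data.frame(
      raft_id = sprintf("raft%03d", k), n_total = n_rec, v_cm = v,
      omega = om, R = if (om != 0) v / abs(om) else NA_real_,
      handedness = if (om > 0) "CCW" else if (om < 0) "CW" else "NONE",
      center0_x = cx[1], center0_y = cy[1])
  }
  list(tracks = tracks, truth = do.call(rbind, rows))
}

#' Calibrated generator defaults and reference statistics
#'
#' @return List with `swimmer` ([swimmer_gen_params()] defaults), `raft`
#'   ([raft_gen_params()] defaults) and `reference`
#'   ([reference_stats()]).
#' @export
reference_defaults <- function() {
  list(swimmer = swimmer_gen_params(), raft = raft_gen_params(),
       reference = reference_stats())
}
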