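# Trajectory analysis for tracked swimmers and rafts: filtering, arc
# segmentation at tumbling cusps, circle fitting (algebraic initializer +
# geometric refinement, with a coherence check between the two),
# handedness classification, marker-pair rigid-body kinematics and
# population statistics.
#
# Track tables are delimited text with columns track_id, frame, x, y
# (positions in micrometres; `x_um`/`y_um` accepted as aliases), the
# dialect produced by common particle-tracking plugins.

#' Construct a trajectory object
#'
#' @param track_id identifier (character or numeric).
#' @param frames integer frame indices, strictly increasing.
#' @param x,y positions in micrometres.
#' @param frame_rate frames per second (default 50).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(track_id, frames, x, y, frame_rate = 50) {
  if (length(frames) < 2L) stop("a trajectory needs >= 2 points",
                                call. = FALSE)
  if (length(x) != length(frames) || length(y) != length(frames)) {
    stop("`frames`, `x`, `y` must have equal length", call. = FALSE)
  }
  if (is.unsorted(frames, strictly = TRUE)) {
    stop(sprintf("track '%s': frames must be strictly increasing", track_id),
         call. = FALSE)
  }
  structure(list(track_id = as.character(track_id),
                 frames = as.integer(frames),
                 x = as.numeric(x), y = as.numeric(y),
                 frame_rate = frame_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames (%.2f s at %g fps)\n",
              x$track_id, length(x$frames),
              (max(x$frames) - min(x$frames)) / x$frame_rate, x$frame_rate))
  invisible(x)
}

#' Read a track table
#'
#' Reads a delimited text file (tab, comma or whitespace separated, with a
#' header) containing columns `track_id`, `frame`, `x`, `y` (aliases
#' `x_um`, `y_um` accepted).  Malformed rows are reported with their line
#' numbers and dropped; a missing column or non-monotone frames within a
#' track raise an error.
#'
#' @param source path to the file (or a connection).
#' @param frame_rate frames per second attached to every trajectory.
#' @return Named list of [trajectory()] objects (possibly empty).
#' @export
read_tracks <- function(source, frame_rate = 50) {
  first <- readLines(source, n = 1L)
  if (length(first) == 0L) return(list())
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  tab <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  names(tab) <- sub("^x_um$", "x", sub("^y_um$", "y", names(tab)))
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) return(list())
  frame <- suppressWarnings(as.numeric(tab$frame))
  xs <- suppressWarnings(as.numeric(tab$x))
  ys <- suppressWarnings(as.numeric(tab$y))
  bad <- which(!is.finite(frame) | !is.finite(xs) | !is.finite(ys) |
                 frame != round(frame))
  if (length(bad)) {
    warning(sprintf("dropping %d malformed row(s) at line(s): %s",
                    length(bad),
                    paste(bad + 1L, collapse = ", ")), call. = FALSE)
    keep <- setdiff(seq_len(nrow(tab)), bad)
    tab <- tab[keep, ]; frame <- frame[keep]; xs <- xs[keep]; ys <- ys[keep]
  }
  out <- list()
  for (id in unique(tab$track_id)) {
    sel <- tab$track_id == id
    fr <- frame[sel]
    if (is.unsorted(fr, strictly = TRUE)) {
      stop(sprintf("track '%s': frames are not strictly increasing", id),
           call. = FALSE)
    }
    out[[id]] <- trajectory(id, fr, xs[sel], ys[sel], frame_rate)
  }
  out
}

#' Write trajectories to a track table
#'
#' Positions are serialized with 17 significant digits so that a write /
#' read round trip reproduces the doubles exactly.
#'
#' @param tracks list of [trajectory()] objects.
#' @param path output file path; if `NULL`, the lines are returned.
#' @return Invisibly, the character vector of lines written.
#' @export
write_tracks <- function(tracks, path = NULL) {
  lines <- "track_id\tframe\tx\ty"
  for (tr in tracks) {
    lines <- c(lines, sprintf("%s\t%d\t%.17g\t%.17g",
                              tr$track_id, tr$frames, tr$x, tr$y))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Keep only tracks with at least `min_frames` points
#'
#' Short tracks carry too little of an arc for a reliable circle fit; the
#' default keeps tracks of 70 or more frames (1.4 s at 50 fps), with the
#' boundary included.
#'
#' @param tracks list of [trajectory()] objects.
#' @param min_frames minimum number of tracked points (default 70).
#' @param quiet suppress the kept/discarded message.
#' @return Filtered list; attributes `n_kept` and `n_discarded` record the
#'   counts.
#' @export
filter_tracks <- function(tracks, min_frames = 70L, quiet = FALSE) {
  if (min_frames < 2) stop("`min_frames` must be >= 2", call. = FALSE)
  len <- vapply(tracks, function(tr) length(tr$frames), integer(1))
  keep <- len >= min_frames
  out <- tracks[keep]
  if (!quiet) {
    message(sprintf("filter_tracks: kept %d of %d tracks (min %d frames)",
                    sum(keep), length(tracks), min_frames))
  }
  if (length(out) == 0L && length(tracks) > 0L) {
    warning("all tracks were shorter than the frame threshold",
            call. = FALSE)
  }
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# mean speed from chords spanning `lag` frames; lags of ~0.1 s keep the
# chord shortening from path curvature negligible while suppressing the
# upward bias from frame-to-frame localization noise
chord_speed <- function(pts, frames, frame_rate, lag = NULL) {
  n <- nrow(pts)
  if (is.null(lag)) lag <- max(1L, as.integer(round(frame_rate / 10)))
  lag <- max(1L, min(as.integer(lag), n - 1L))
  i0 <- seq_len(n - lag)
  i1 <- i0 + lag
  d <- sqrt((pts[i1, 1] - pts[i0, 1])^2 + (pts[i1, 2] - pts[i0, 2])^2)
  dt <- (frames[i1] - frames[i0]) / frame_rate
  mean(d / dt)
}

# centred moving average used to smooth velocities before cusp detection
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  sm <- stats::filter(v, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- v[is.na(sm)] # keep raw values at the edges
  sm
}

#' Split a trajectory into tumble-free circular arcs
#'
#' Run-and-tumble tracks are sequences of circular arcs joined by cusps
#' where the swimmer momentarily stops and reorients.  A frame is marked
#' as a cusp when the smoothed turning angle between successive velocity
#' vectors exceeds `turn_threshold_deg`, or when the instantaneous speed
#' falls below `min_speed_fraction` times the track's median speed.
#' Segments between cusps shorter than `min_arc_frames` are dropped; each
#' surviving segment gets a circle fit, a mean speed and a handedness
#' call.
#'
#' @param traj a [trajectory()] object.
#' @param turn_threshold_deg turning-angle cut in degrees (default 50).
#' @param min_speed_fraction speed cut as a fraction of the track median
#'   speed (default 0.3).
#' @param smooth_window centred moving-average window in frames applied to
#'   the velocities before the turning-angle test (default 3).
#' @param min_arc_frames minimum points per arc (default 10).
#' @param coherence_threshold,r_max passed to [fit_circle()].
#' @param image_coords passed to [classify_rotation()].
#' @param speed_lag frame lag for the mean-speed estimate; chords over a
#'   lag of several frames suppress the upward speed bias that
#'   frame-to-frame localization noise would otherwise cause.  Default
#'   `max(1, round(frame_rate / 10))` (0.1 s).
#' @return List of `arc_segment` objects: each has `track_id`,
#'   `arc_index`, `frames`, `x`, `y`, `fit` (a `circle_fit` or `NULL`),
#'   `v` (mean speed, um/s), `handedness`.
#' @export
segment_arcs <- function(traj, turn_threshold_deg = 50,
                         min_speed_fraction = 0.3, smooth_window = 3L,
                         min_arc_frames = 10L, coherence_threshold = 0.2,
                         r_max = Inf, image_coords = FALSE,
                         speed_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$x)
  if (n < 2L * min_arc_frames) return(list())
  dt <- diff(traj$frames) / traj$frame_rate
  vx <- diff(traj$x) / dt
  vy <- diff(traj$y) / dt
  svx <- moving_average(vx, smooth_window)
  svy <- moving_average(vy, smooth_window)
  speed <- sqrt(vx^2 + vy^2)
  med_speed <- stats::median(speed)
  # turning angle between successive smoothed velocity vectors
  dot <- svx[-length(svx)] * svx[-1] + svy[-length(svy)] * svy[-1]
  crs <- svx[-length(svx)] * svy[-1] - svy[-length(svy)] * svx[-1]
  turn <- abs(atan2(crs, dot)) * 180 / pi
  slow <- speed < min_speed_fraction * med_speed          # n - 1 flags
  sharp <- c(FALSE, turn > turn_threshold_deg)            # align to steps
  cusp_step <- slow | sharp
  # point i is inside a cusp if either adjacent step is flagged
  cusp_pt <- c(cusp_step, FALSE) | c(FALSE, cusp_step)
  runs <- rle(!cusp_pt)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- which(runs$values & runs$lengths >= min_arc_frames)
  out <- list()
  for (k in seq_along(segs)) {
    i0 <- starts[segs[k]]; i1 <- ends[segs[k]]
    idx <- i0:i1
    pts <- cbind(traj$x[idx], traj$y[idx])
    fit <- tryCatch(
      fit_circle(pts, coherence_threshold = coherence_threshold,
                 r_max = r_max),
      error = function(e) NULL)
    v <- chord_speed(pts, traj$frames[idx], traj$frame_rate, speed_lag)
    hand <- classify_rotation(pts, image_coords = image_coords,
                              quiet = TRUE)
    out[[length(out) + 1L]] <- structure(
      list(track_id = traj$track_id, arc_index = length(out) + 1L,
           frames = traj$frames[idx], x = pts[, 1], y = pts[, 2],
           fit = fit, v = v, handedness = hand),
      class = "arc_segment")
  }
  out
}

#' Least-squares circle fit with coherence check
#'
#' Fits a circle twice: first algebraically (linear least squares on the
#' form `x^2 + y^2 = 2 a x + 2 b y + c`), then geometrically, minimizing
#' the sum of squared radial residuals `(|p - c| - R)^2` by Gauss-Newton
#' iteration started from the algebraic solution.  The relative
#' disagreement between the two radii is the coherence statistic; fits
#' where the two methods disagree by more than `coherence_threshold` are
#' flagged as not accepted (circular motion is not apparent).
#'
#' @param points two-column matrix or data frame of (x, y) positions, at
#'   least 5 points, not all collinear.
#' @param coherence_threshold maximum relative difference between the
#'   algebraic and geometric radii for acceptance (default 0.2).
#' @param r_max maximum accepted radius (default `Inf`; population-level
#'   radius filtering is done by [apply_R_filter()]).
#' @return Object of class `circle_fit`: `center`, `radius`,
#'   `radius_algebraic`, `rms_residual`, `method_agreement`, `accepted`,
#'   `n_points`.
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' fit_circle(cbind(1 + 10 * cos(th), 2 + 10 * sin(th)))
#' @export
fit_circle <- function(points, coherence_threshold = 0.2, r_max = Inf) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("`points` must have two columns", call. = FALSE)
  pts <- pts[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 5L) stop("circle fitting needs at least 5 points", call. = FALSE)
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qr_A <- qr(A)
  if (qr_A$rank < 3L) {
    stop("degenerate circle fit: points are collinear", call. = FALSE)
  }
  sol <- qr.coef(qr_A, b)
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit: non-positive squared radius",
         call. = FALSE)
  }
  r_alg <- sqrt(r2)
  # Gauss-Newton refinement of (cx, cy, R) on the radial residuals
  p <- c(cx, cy, r_alg)
  for (it in 1:100) {
    dx <- x - p[1]; dy <- y - p[2]
    d <- sqrt(dx^2 + dy^2)
    d[d < .Machine$double.eps] <- .Machine$double.eps
    e <- d - p[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.coef(qr(J), -e), error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    p <- p + step
    if (max(abs(step)) < 1e-12 * max(1, abs(p[3]))) break
  }
  if (p[3] <= 0) {
    stop("degenerate circle fit: geometric refinement collapsed",
         call. = FALSE)
  }
  d <- sqrt((x - p[1])^2 + (y - p[2])^2)
  rms <- sqrt(mean((d - p[3])^2))
  agreement <- abs(r_alg - p[3]) / p[3]
  structure(list(center = c(p[1], p[2]), radius = p[3],
                 radius_algebraic = r_alg, rms_residual = rms,
                 method_agreement = agreement,
                 accepted = agreement <= coherence_threshold &&
                   p[3] <= r_max,
                 n_points = n), class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "Circle fit: center (%.3f, %.3f), R = %.3f um (alg. %.3f, agr. %.3g)%s\n",
    x$center[1], x$center[2], x$radius, x$radius_algebraic,
    x$method_agreement, if (x$accepted) "" else " [rejected]"))
  invisible(x)
}

# radius / accepted accessors for circle fits and arc segments
.fit_of <- function(obj) {
  if (inherits(obj, "circle_fit")) obj else obj$fit
}

#' Discard fits with implausibly large radius of curvature
#'
#' Trajectories fitted with a radius above `R_max` (or whose algebraic and
#' geometric fits disagreed) correspond to tracks without a univocal
#' rotation direction and are removed; about 10% of real cases fall in
#' this class at the default 50 um cut.
#'
#' @param fits list of `circle_fit` objects or of `arc_segment` objects
#'   carrying a `$fit`.
#' @param R_max radius cut in micrometres (default 50; `Inf` keeps every
#'   accepted fit).
#' @param quiet suppress the discard-fraction message.
#' @return Filtered list with attribute `discard_fraction`.
#' @export
apply_R_filter <- function(fits, R_max = 50, quiet = FALSE) {
  keep <- vapply(fits, function(obj) {
    f <- .fit_of(obj)
    !is.null(f) && f$accepted && f$radius <= R_max
  }, logical(1))
  out <- fits[keep]
  frac <- if (length(fits)) mean(!keep) else 0
  if (!quiet) {
    message(sprintf(
      "apply_R_filter: discarded %d of %d fits (%.1f%%) at R_max = %g um",
      sum(!keep), length(fits), 100 * frac, R_max))
  }
  attr(out, "discard_fraction") <- frac
  out
}

#' Classify the rotation sense of a track segment
#'
#' Uses the sign of the mean z-component of the cross products of
#' successive displacement vectors.  Positive means counterclockwise
#' under the mathematical y-up convention; set `image_coords = TRUE` for
#' y-down pixel coordinates, which inverts the call.
#'
#' @param points an `arc_segment`, a [trajectory()], or a two-column
#'   matrix of positions.
#' @param image_coords logical; `TRUE` if y grows downwards.
#' @param quiet suppress the warning on unclassifiable input.
#' @param lag frame lag between the positions whose displacements are
#'   crossed.  The per-frame turning signal grows as `lag^3` while the
#'   localization-noise contribution grows only as `lag^1.5`, so a lag of
#'   about a tenth of the segment (the default) makes the sign call
#'   robust at realistic noise; `lag = 1` reproduces the frame-by-frame
#'   version.
#' @return `"CCW"`, `"CW"`, or `NA` (unclassifiable: zero mean cross
#'   product).
#' @export
classify_rotation <- function(points, image_coords = FALSE, quiet = FALSE,
                              lag = NULL) {
  if (inherits(points, "arc_segment") || inherits(points, "trajectory")) {
    points <- cbind(points$x, points$y)
  }
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (is.null(lag)) lag <- max(1L, as.integer(floor(n / 10)))
  lag <- max(1L, min(as.integer(lag), max(1L, (n - 1L) %/% 2L)))
  pts <- pts[seq(1L, n, by = lag), , drop = FALSE]
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  if (length(dx) < 2L) return(NA_character_)
  cz <- dx[-length(dx)] * dy[-1] - dy[-length(dy)] * dx[-1]
  s <- mean(cz)
  if (s == 0) {
    if (!quiet) warning("rotation sense unclassifiable: zero mean cross product",
                        call. = FALSE)
    return(NA_character_)
  }
  if (image_coords) s <- -s
  if (s > 0) "CCW" else "CW"
}

#' Rigid-body raft kinematics from a tracked marker pair
#'
#' Reconstructs the planar rigid motion of a raft from two tracked
#' bacteria on it.  The raft orientation is the unwrapped bearing of the
#' marker2 - marker1 vector; the raft center is expressed once in the
#' marker pair's body frame at the first frame and re-projected at every
#' frame (a 2D rigid transform).  The angular velocity is the
#' least-squares slope of orientation against time; center speed and
#' radius of curvature come from the reconstructed center path.
#'
#' @param marker1,marker2 [trajectory()] objects spanning identical
#'   frames.
#' @param center0 raft center position (length 2, um) at the first frame.
#' @param image_coords logical, as in [classify_rotation()].
#' @param speed_lag frame lag for the center-speed chords; rafts move
#'   slowly, so the default spans 0.5 s (`round(frame_rate / 2)`) to keep
#'   localization noise from biasing the speed.
#' @return Object of class `raft_track_kinematics`: `t`, `center`
#'   (matrix), `theta` (unwrapped), `omega` (signed rad/s), `v_cm`
#'   (um/s), `radius_curv` (um or `NA`), `handedness`, `fit` (circle fit
#'   of the center path or `NULL`).
#' @export
raft_kinematics_from_markers <- function(marker1, marker2, center0,
                                         image_coords = FALSE,
                                         speed_lag = NULL) {
  stopifnot(inherits(marker1, "trajectory"), inherits(marker2, "trajectory"))
  if (!identical(marker1$frames, marker2$frames)) {
    stop("marker tracks must span the same frames", call. = FALSE)
  }
  if (image_coords) { # convert y-down pixel coordinates to y-up
    marker1$y <- -marker1$y
    marker2$y <- -marker2$y
    center0[2] <- -center0[2]
  }
  ex <- marker2$x - marker1$x
  ey <- marker2$y - marker1$y
  sep <- sqrt(ex^2 + ey^2)
  if (any(sep < 1e-9)) {
    stop("markers coincide at some frame; rigid pose is degenerate",
         call. = FALSE)
  }
  theta <- unwrap_angle(atan2(ey, ex))
  tt <- (marker1$frames - marker1$frames[1]) / marker1$frame_rate
  # body coordinates of the center in the frame-0 marker pose
  e1 <- c(ex[1], ey[1]) / sep[1]
  e2 <- c(-e1[2], e1[1])
  d0 <- c(center0[1] - marker1$x[1], center0[2] - marker1$y[1])
  u <- c(sum(d0 * e1), sum(d0 * e2))
  rot <- theta - theta[1]
  # re-project: body axes at frame t are R(rot) applied to (e1, e2)
  e1x <- cos(rot) * e1[1] - sin(rot) * e1[2]
  e1y <- sin(rot) * e1[1] + cos(rot) * e1[2]
  e2x <- -e1y
  e2y <- e1x
  cx <- marker1$x + u[1] * e1x + u[2] * e2x
  cy <- marker1$y + u[1] * e1y + u[2] * e2y
  omega <- unname(stats::lm.fit(cbind(1, tt), theta)$coefficients[2])
  if (is.null(speed_lag)) {
    speed_lag <- max(1L, as.integer(round(marker1$frame_rate / 2)))
  }
  v_cm <- chord_speed(cbind(cx, cy), marker1$frames, marker1$frame_rate,
                      speed_lag)
  fit <- tryCatch(fit_circle(cbind(cx, cy)), error = function(e) NULL)
  rc <- if (!is.null(fit)) fit$radius else NA_real_
  hand <- classify_rotation(cbind(cx, cy), quiet = TRUE)
  structure(list(t = tt, center = cbind(x = cx, y = cy), theta = theta,
                 omega = omega, v_cm = v_cm, radius_curv = rc,
                 handedness = hand, fit = fit),
            class = "raft_track_kinematics")
}

# unwrap a phase signal so consecutive jumps stay within (-pi, pi]
unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Tabulate arc segments
#'
#' @param arcs list of `arc_segment` objects.
#' @return Data frame with one row per arc: `track_id`, `arc_index`,
#'   `v_um_s`, `R_um`, `handedness`, `accepted`.
#' @export
arcs_table <- function(arcs) {
  if (length(arcs) == 0L) {
    return(data.frame(track_id = character(), arc_index = integer(),
                      v_um_s = numeric(), R_um = numeric(),
                      handedness = character(), accepted = logical()))
  }
  do.call(rbind, lapply(arcs, function(a) {
    data.frame(track_id = a$track_id, arc_index = a$arc_index,
               v_um_s = a$v,
               R_um = if (!is.null(a$fit)) a$fit$radius else NA_real_,
               handedness = a$handedness,
               accepted = !is.null(a$fit) && a$fit$accepted)
  }))
}

#' Population statistics for single swimmers and rafts
#'
#' Computes group means of speed and radius of curvature, clockwise
#' fractions, Welch two-sample tests between CW and CCW subpopulations
#' and between singles and rafts, and an exact binomial test of the CW
#' fraction against 1/2.
#'
#' @param single_results,raft_results data frames with columns `v_um_s`,
#'   `R_um`, `handedness` (e.g. from [arcs_table()]); `raft_results` may
#'   be `NULL`.
#' @return Object of class `population_summary`: nested list of means,
#'   fractions and p-values; tests on groups with fewer than 2
#'   observations are skipped with a notice (`NA` p-value).
#' @export
summarize_population <- function(single_results, raft_results = NULL) {
  group_stats <- function(d, label) {
    hand <- d$handedness[!is.na(d$handedness)]
    n_cw <- sum(hand == "CW")
    n_tot <- length(hand)
    binom_p <- if (n_tot >= 1) {
      stats::binom.test(n_cw, n_tot, p = 0.5)$p.value
    } else NA_real_
    welch <- function(col) {
      a <- d[[col]][d$handedness == "CW"]
      b <- d[[col]][d$handedness == "CCW"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) {
        message(sprintf("%s: CW/CCW %s test skipped (group too small)",
                        label, col))
        return(NA_real_)
      }
      stats::t.test(a, b)$p.value
    }
    list(n = nrow(d), mean_v = mean(d$v_um_s, na.rm = TRUE),
         mean_R = mean(d$R_um, na.rm = TRUE),
         cw_fraction = if (n_tot) n_cw / n_tot else NA_real_,
         p_binom_cw_half = binom_p,
         p_v_cw_vs_ccw = welch("v_um_s"),
         p_R_cw_vs_ccw = welch("R_um"))
  }
  out <- list(single = group_stats(single_results, "single"))
  if (!is.null(raft_results)) {
    out$raft <- group_stats(raft_results, "raft")
    cross <- function(col) {
      a <- single_results[[col]]; b <- raft_results[[col]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      stats::t.test(a, b)$p.value
    }
    out$single_vs_raft <- list(p_v = cross("v_um_s"), p_R = cross("R_um"))
  }
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  show <- function(g, name) {
    cat(sprintf(
      "%s: n = %d, mean v = %.3f um/s, mean R = %.3f um, CW fraction = %.3f\n",
      name, g$n, g$mean_v, g$mean_R, g$cw_fraction))
    cat(sprintf("  binomial p (CW vs 0.5) = %.3g; Welch p CW-vs-CCW: v %.3g, R %.3g\n",
                g$p_binom_cw_half, g$p_v_cw_vs_ccw, g$p_R_cw_vs_ccw))
  }
  show(x$single, "singles")
  if (!is.null(x$raft)) {
    show(x$raft, "rafts")
    cat(sprintf("singles vs rafts: Welch p: v %.3g, R %.3g\n",
                x$single_vs_raft$p_v, x$single_vs_raft$p_R))
  }
  invisible(x)
}
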