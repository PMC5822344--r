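# Track I/O, filtering, arc segmentation, circle fitting, handedness and
# marker-pair kinematics.

test_that("track tables round-trip losslessly through text", {
  tr1 <- trajectory("a", 0:9, rnorm(10), rnorm(10))
  tr2 <- trajectory("b", 5:14, rnorm(10, 50), rnorm(10, -3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(list(tr1, tr2), path)
  back <- read_tracks(path)
  expect_identical(names(back), c("a", "b"))
  expect_identical(back$a$frames, tr1$frames)
  expect_identical(back$a$x, tr1$x) # exact doubles, not rounded
  expect_identical(back$b$y, tr2$y)
})

test_that("track reading validates structure and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("track_id\tframe\tx\ty", path)
  expect_identical(read_tracks(path), list())
  # malformed numeric cell: dropped with a line-number warning
  writeLines(c("track_id\tframe\tx\ty",
               "t1\t0\t1.0\t2.0", "t1\t1\toops\t2.5", "t1\t2\t1.2\t2.6",
               "t1\t3\t1.3\t2.7"), path)
  expect_warning(tr <- read_tracks(path), "line")
  expect_identical(length(tr$t1$frames), 3L)
  # missing column
  writeLines(c("track_id\tframe\tx", "t1\t0\t1.0"), path)
  expect_error(read_tracks(path), "missing column")
  # non-monotone frames
  writeLines(c("track_id\tframe\tx\ty",
               "t1\t2\t1\t1", "t1\t1\t2\t2", "t1\t3\t3\t3"), path)
  expect_error(read_tracks(path), "increasing")
  # comma-separated dialect with x_um/y_um aliases
  writeLines(c("track_id,frame,x_um,y_um",
               "t9,0,1.5,2.5", "t9,1,1.6,2.6", "t9,2,1.7,2.7"), path)
  tr <- read_tracks(path)
  expect_identical(length(tr$t9$x), 3L)
})

test_that("the 70-frame rule keeps the boundary track", {
  mk <- function(id, n) trajectory(id, seq_len(n) - 1L, seq_len(n),
                                   rep(0, n))
  tracks <- list(mk("short", 69), mk("edge", 70), mk("long", 100))
  kept <- filter_tracks(tracks, quiet = TRUE)
  expect_identical(vapply(kept, `[[`, "", "track_id"), c("edge", "long"))
  expect_identical(attr(kept, "n_discarded"), 1L)
  # min_frames = 2 keeps everything
  expect_identical(length(filter_tracks(tracks, 2, quiet = TRUE)), 3L)
  expect_warning(filter_tracks(list(mk("s", 10)), 70, quiet = TRUE),
                 "shorter")
  expect_error(filter_tracks(tracks, 1), ">= 2")
})

test_that("a noiseless circular track yields one full-span arc", {
  leg <- arc_leg(c(0, 0), 0, +1, 12, 24, 120, 50)
  tr <- trajectory("c", 0:120, c(0, leg$x), c(0, leg$y), 50)
  arcs <- segment_arcs(tr)
  expect_identical(length(arcs), 1L)
  expect_identical(length(arcs[[1]]$x), 121L)
  expect_equal(arcs[[1]]$fit$radius, 24, tolerance = 1e-9)
  expect_identical(arcs[[1]]$handedness, "CCW")
})

test_that("tumbling cusps split tracks within two frames of the truth", {
  tk <- two_arc_track(arc_frames = 60, pause = 5)
  arcs <- segment_arcs(tk$traj)
  expect_identical(length(arcs), 2L)
  # first arc must end within +-2 frames of the cusp start
  end1 <- max(arcs[[1]]$frames)
  start2 <- min(arcs[[2]]$frames)
  expect_lte(abs(end1 - (tk$cusp_first - 2L)), 2)
  expect_lte(abs(start2 - tk$cusp_last), 2)
  expect_equal(arcs[[1]]$fit$radius, tk$R, tolerance = 1e-6)
  expect_equal(arcs[[2]]$fit$radius, tk$R, tolerance = 1e-6)
})

test_that("pure positional jitter produces no accepted arcs", {
  set.seed(8)
  tr <- trajectory("noise", 0:199, rnorm(200, 0, 0.5), rnorm(200, 0, 0.5))
  arcs <- segment_arcs(tr)
  ok <- Filter(function(a) !is.null(a$fit) && a$fit$accepted, arcs)
  expect_identical(length(ok), 0L)
})

test_that("circle fits recover exact circles and reject degenerate input", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  fit <- fit_circle(circle_points(c(1, 2), 10, th))
  expect_equal(fit$center, c(1, 2), tolerance = 1e-9)
  expect_equal(fit$radius, 10, tolerance = 1e-9)
  expect_lt(fit$method_agreement, 1e-9)
  expect_true(fit$accepted)
  expect_error(fit_circle(cbind(1:10, 2 * (1:10) + 3)), "collinear")
  expect_error(fit_circle(cbind(1:4, c(1, 2, 1, 2))), "at least 5")
})

test_that("a noisy quarter arc at the typical swimmer radius fits within 5%", {
  set.seed(12)
  th <- seq(0, pi / 2, length.out = 30)
  pts <- circle_points(c(5, -3), 24.4, th) + rnorm(60, 0, 0.1)
  fit <- fit_circle(pts)
  expect_equal(fit$radius, 24.4, tolerance = 0.05)
})

test_that("circle fitting is translation- and rotation-equivariant", {
  set.seed(13)
  th <- seq(0.2, 2.1, length.out = 40)
  pts <- circle_points(c(0, 0), 7, th) + rnorm(80, 0, 0.05)
  f0 <- fit_circle(pts)
  shift <- c(11, -4)
  f1 <- fit_circle(sweep(pts, 2, -shift, "-"))
  expect_equal(f1$center, f0$center + shift, tolerance = 1e-8)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-10)
  expect_equal(f1$method_agreement, f0$method_agreement, tolerance = 1e-8)
  a <- 0.8
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  f2 <- fit_circle(t(Rm %*% t(pts)))
  expect_equal(f2$center, as.numeric(Rm %*% f0$center), tolerance = 1e-8)
  expect_equal(f2$radius, f0$radius, tolerance = 1e-10)
  expect_equal(f2$rms_residual, f0$rms_residual, tolerance = 1e-8)
})

test_that("the 50 um radius filter removes exactly the oversized fits", {
  mk <- function(R) structure(list(center = c(0, 0), radius = R,
                                   radius_algebraic = R, rms_residual = 0,
                                   method_agreement = 0, accepted = TRUE,
                                   n_points = 10L), class = "circle_fit")
  fits <- list(mk(10), mk(49), mk(60))
  kept <- apply_R_filter(fits, quiet = TRUE)
  expect_equal(vapply(kept, `[[`, 0, "radius"), c(10, 49))
  expect_equal(attr(kept, "discard_fraction"), 1 / 3)
  # infinite cut keeps all accepted fits
  expect_identical(length(apply_R_filter(fits, Inf, quiet = TRUE)), 3L)
  # rejected fits are dropped regardless of radius
  bad <- mk(10); bad$accepted <- FALSE
  expect_identical(length(apply_R_filter(list(bad), quiet = TRUE)), 0L)
})

test_that("rotation sense follows the cross-product sign convention", {
  t <- seq(0, 3, by = 0.05)
  expect_identical(classify_rotation(cbind(cos(t), sin(t))), "CCW")
  expect_identical(classify_rotation(cbind(cos(-t), sin(-t))), "CW")
  # y-axis reflection flips the call
  expect_identical(classify_rotation(cbind(cos(t), -sin(t))), "CW")
  expect_identical(
    classify_rotation(cbind(cos(t), sin(t)), image_coords = TRUE), "CW")
  # straight line: no rotation signal
  expect_warning(h <- classify_rotation(cbind(t, 2 * t)), "unclassifiable")
  expect_true(is.na(h))
})

test_that("marker pairs recover rigid rotations and translations exactly", {
  fps <- 50
  tt <- (0:200) / fps
  om <- 1
  # pure rotation about the origin
  m1 <- trajectory("m1", 0:200, 3 * cos(om * tt), 3 * sin(om * tt), fps)
  m2 <- trajectory("m2", 0:200, 5 * cos(om * tt + 1), 5 * sin(om * tt + 1),
                   fps)
  kin <- raft_kinematics_from_markers(m1, m2, center0 = c(0, 0))
  expect_equal(kin$omega, 1, tolerance = 1e-10)
  expect_equal(kin$v_cm, 0, tolerance = 1e-10)
  expect_equal(max(abs(kin$center)), 0, tolerance = 1e-10)
  expect_identical(kin$handedness, "CCW")
  # pure translation
  m1t <- trajectory("m1", 0:200, 1 + 2 * tt, rep(0, 201), fps)
  m2t <- trajectory("m2", 0:200, 4 + 2 * tt, rep(1, 201), fps)
  kint <- raft_kinematics_from_markers(m1t, m2t, center0 = c(2, 0.5))
  expect_equal(kint$omega, 0, tolerance = 1e-12)
  expect_equal(kint$v_cm, 2, tolerance = 1e-10)
  expect_equal(kint$center[, "x"], 2 + 2 * tt, tolerance = 1e-10,
               ignore_attr = TRUE)
  # degeneracies
  expect_error(raft_kinematics_from_markers(m1t, m1t, c(0, 0)), "coincide")
  m3 <- trajectory("m3", 1:201, 4 + 2 * tt, rep(1, 201), fps)
  expect_error(raft_kinematics_from_markers(m1t, m3, c(0, 0)),
               "same frames")
})

test_that("population summaries compute group stats and tests", {
  set.seed(20)
  g <- data.frame(v_um_s = rnorm(40, 10), R_um = rnorm(40, 20),
                  handedness = rep(c("CW", "CCW"), 20))
  s <- summarize_population(g, g)
  expect_equal(s$single$mean_v, mean(g$v_um_s))
  expect_equal(s$single$cw_fraction, 0.5)
  expect_gt(s$single_vs_raft$p_v, 0.99) # identical groups
  # singles at 12.4 um/s vs rafts at 2.31 um/s separate decisively
  singles <- data.frame(v_um_s = rnorm(100, 12.4, 1.5),
                        R_um = rnorm(100, 24.4, 3),
                        handedness = sample(c("CW", "CCW"), 100, TRUE,
                                            c(0.14, 0.86)))
  rafts <- data.frame(v_um_s = rnorm(100, 2.31, 0.5),
                      R_um = rnorm(100, 17.68, 3),
                      handedness = sample(c("CW", "CCW"), 100, TRUE))
  s2 <- summarize_population(singles, rafts)
  expect_lt(s2$single_vs_raft$p_v, 1e-6)
  # too-small groups skip the Welch test with a notice
  tiny <- data.frame(v_um_s = c(1, 2, 3), R_um = c(1, 2, 3),
                     handedness = c("CW", "CCW", "CCW"))
  expect_message(s3 <- summarize_population(tiny), "skipped")
  expect_true(is.na(s3$single$p_v_cw_vs_ccw))
})

test_that("handedness p-values are well calibrated under a fair coin", {
  set.seed(30)
  pv <- replicate(300, {
    d <- data.frame(v_um_s = rnorm(100, 10), R_um = rnorm(100, 20),
                    handedness = sample(c("CW", "CCW"), 100, TRUE))
    summarize_population(d)$single$p_binom_cw_half
  })
  # the exact test is conservative on discrete data: small p-values must
  # not be over-produced under the null
  expect_lt(mean(pv <= 0.05), 0.08)
  expect_gt(mean(pv <= 0.5), 0.3)
})
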