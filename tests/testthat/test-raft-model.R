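# Contour-thrust raft model: construction, net propulsion, steady-state
# kinematics, propagation and thrust statistics.

test_that("raft construction follows the contour-count and radius rules", {
  r <- build_raft(4, raft_params(), seed = 1)
  expect_identical(r$n_contour, 7L) # max(3, round(2*sqrt(pi)*2))
  expect_equal(r$radius, sqrt(4 / pi))
  expect_equal(sqrt(rowSums(r$contour_positions^2)),
               rep(r$radius, r$n_contour))
  expect_true(all(r$force_angles >= 0 & r$force_angles < 2 * pi))
  # floor of 3 contour bacteria (binds at small cb)
  expect_identical(build_raft(1, raft_params(cb = 1), seed = 1)$n_contour, 3L)
  expect_error(build_raft(0, seed = 1), "positive integer")
  expect_error(build_raft(10), "seed")
})

test_that("raft realizations are deterministic given (N, params, seed)", {
  a <- build_raft(100, seed = 123)
  b <- build_raft(100, seed = 123)
  expect_identical(a$force_angles, b$force_angles)
  c <- build_raft(100, seed = 124)
  expect_false(identical(a$force_angles, c$force_angles))
})

test_that("force angles are uniform on [0, 2pi) across seeded realizations", {
  # pooled first and fifth angle over many independent rafts
  a1 <- vapply(1:400, function(s) build_raft(100, seed = s)$force_angles[1],
               numeric(1))
  a5 <- vapply(1:400, function(s) build_raft(100, seed = s)$force_angles[5],
               numeric(1))
  expect_gt(stats::ks.test(a1 / (2 * pi), "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(a5 / (2 * pi), "punif")$p.value, 0.01)
})

test_that("net propulsion handles radial thrust and antipodal cancellation", {
  # single bacterium at (r, 0) pushing radially outward: no torque
  r1 <- bare_raft(c(2, 0), 0)
  p1 <- net_propulsion(r1)
  expect_equal(p1$force, c(1, 0))
  expect_equal(p1$torque, 0)
  # two antipodal bacteria with opposite angles: forces cancel
  r2 <- bare_raft(rbind(c(2, 0), c(-2, 0)), c(0, pi))
  p2 <- net_propulsion(r2)
  expect_equal(p2$force, c(0, 0))
  # torque equals r f sum(sin(alpha_i - beta_i)) on the circular raft
  set.seed(5)
  r3 <- build_raft(200, seed = 9)
  beta <- atan2(r3$contour_positions[, 2], r3$contour_positions[, 1])
  expect_equal(net_propulsion(r3)$torque,
               r3$radius * sum(sin(r3$force_angles - beta)))
})

test_that("Monte-Carlo spread of net force and torque follows sqrt(N_b/2)", {
  n_b <- 100L
  set.seed(11)
  fx <- tq <- numeric(4000)
  for (i in seq_len(4000)) {
    r <- build_raft(810, seed = 100000 + i) # N_b = round(2 sqrt(pi*810)) = 101
    p <- net_propulsion(r)
    fx[i] <- p$force[1]
    tq[i] <- p$torque / r$radius
  }
  n_b <- build_raft(810, seed = 1)$n_contour
  expect_equal(stats::sd(fx), sqrt(n_b / 2), tolerance = 0.05)
  expect_equal(stats::sd(tq), sqrt(n_b / 2), tolerance = 0.05)
})

test_that("steady kinematics implements v = |F|/D, omega = T/G, R = v/|omega|", {
  # zero torque (antipodal pair, parallel thrust): straight motion
  r <- bare_raft(rbind(c(1, 0), c(-1, 0)), c(0, 0))
  k <- steady_kinematics(r)
  expect_equal(k$v_cm, 2 / 2) # |F| = 2 f, D = d0 * 2
  expect_identical(k$handedness, "NONE")
  expect_false(k$radius_defined)
  expect_true(is.na(k$radius_curv))
  # composition identity on a random raft
  r2 <- build_raft(512, seed = 21)
  k2 <- steady_kinematics(r2)
  p2 <- net_propulsion(r2)
  D <- r2$n_contour; G <- r2$n_contour^3
  expect_equal(k2$radius_curv,
               sqrt(sum(p2$force^2)) * G / (abs(p2$torque) * D))
  expect_identical(k2$handedness, if (p2$torque > 0) "CCW" else "CW")
})

test_that("negating all force angles flips handedness but not speeds", {
  r <- build_raft(300, seed = 31)
  rneg <- r
  rneg$force_angles <- (r$force_angles + pi) %% (2 * pi)
  k <- steady_kinematics(r)
  kn <- steady_kinematics(rneg)
  pn <- net_propulsion(rneg)
  p <- net_propulsion(r)
  expect_equal(pn$force, -p$force)
  expect_equal(pn$torque, -p$torque)
  expect_equal(kn$v_cm, k$v_cm)
  expect_equal(abs(kn$omega), abs(k$omega))
  expect_equal(kn$radius_curv, k$radius_curv)
  expect_true(kn$handedness != k$handedness)
})

test_that("rotating the quenched disorder rotates the force, fixes the rest", {
  r <- build_raft(300, seed = 33)
  beta <- 0.7
  rrot <- r
  rrot$force_angles <- r$force_angles + beta
  th <- atan2(r$contour_positions[, 2], r$contour_positions[, 1]) + beta
  rrot$contour_positions <- cbind(r$radius * cos(th), r$radius * sin(th))
  p <- net_propulsion(r)
  pr <- net_propulsion(rrot)
  Rm <- matrix(c(cos(beta), sin(beta), -sin(beta), cos(beta)), 2, 2)
  expect_equal(pr$force, as.numeric(Rm %*% p$force))
  expect_equal(pr$torque, p$torque)
  k <- steady_kinematics(r); kr <- steady_kinematics(rrot)
  expect_equal(kr$v_cm, k$v_cm)
  expect_equal(kr$omega, k$omega)
  expect_equal(kr$radius_curv, k$radius_curv)
})

test_that("closed-form propagation is uniform circular motion", {
  r <- build_raft(64, seed = 3)
  k <- steady_kinematics(r)
  tr <- propagate(r, duration = 4 * 2 * pi / abs(k$omega), n_steps = 400)
  # the path is a circle of radius R = v_cm / |omega|
  fit <- fit_circle(cbind(tr$x, tr$y))
  expect_equal(fit$radius, k$radius_curv, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9 * k$radius_curv)
  # orientation advances linearly
  expect_equal(diff(tr$theta), rep(diff(tr$theta)[1], nrow(tr) - 1))
})

test_that("zero torque propagates to a straight line at speed v_cm", {
  r <- bare_raft(rbind(c(1, 0), c(-1, 0)), c(0.3, 0.3))
  k <- steady_kinematics(r)
  expect_identical(k$handedness, "NONE")
  tr <- propagate(r, duration = 10, n_steps = 100)
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t)
  expect_equal(d, rep(k$v_cm, 100))
  # collinearity: successive displacements never turn
  cz <- diff(tr$x)[-100] * diff(tr$y)[-1] - diff(tr$y)[-100] * diff(tr$x)[-1]
  expect_equal(cz, rep(0, 99))
})

test_that("numeric integration matches the closed form to high precision", {
  for (s in 1:10) {
    r <- build_raft(128, seed = 700 + s)
    k <- steady_kinematics(r)
    period <- 2 * pi / abs(k$omega)
    dt <- period / 500
    num <- propagate(r, duration = 4 * period, dt = dt)
    cf <- propagate(r, duration = 4 * period, n_steps = nrow(num) - 1L)
    dev <- max(sqrt((num$x - cf$x)^2 + (num$y - cf$y)^2))
    expect_lt(dev, 1e-6 * k$radius_curv)
  }
  # oversized step is rejected
  r <- build_raft(16, seed = 1)
  k <- steady_kinematics(r)
  expect_error(propagate(r, duration = 1, dt = 0.2 / abs(k$omega)),
               "step")
})

test_that("thrust statistics match the analytic sqrt(N_b/2) law", {
  st <- thrust_statistics(50, n_samples = 2e5, seed = 4, radius = 2)
  expect_equal(st$analytic_std_force, sqrt(25))
  expect_equal(st$analytic_std_torque, 2 * sqrt(25))
  expect_equal(st$std_fx, st$analytic_std_force, tolerance = 0.02)
  expect_equal(st$std_fy, st$analytic_std_force, tolerance = 0.02)
  expect_equal(st$std_torque, st$analytic_std_torque, tolerance = 0.02)
  # isotropy: x and y spreads agree within Monte-Carlo error
  expect_equal(st$std_fx, st$std_fy, tolerance = 0.02)
  # single-bacterium case: std = f / sqrt(2)
  st1 <- thrust_statistics(1, n_samples = 1e3, seed = 5)
  expect_equal(st1$analytic_std_force, 1 / sqrt(2))
  expect_error(thrust_statistics(10, n_samples = 10, seed = 1), "1000")
})
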