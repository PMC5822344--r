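# End-to-end drivers: the size-sweep scaling experiment and the
# synthetic-data round-trip validation.  Both are pure functions of
# (config, seed) so every run is reproducible; the analysis/ scripts are
# thin wrappers around them.

#' Run the raft scaling experiment
#'
#' Sweeps colony size, fits the three power laws (mean `v_cm`, mean
#' `|omega|`, median `R` against N) and compares the fitted exponents
#' with the model predictions (-0.25, -0.75, +0.5) and with the
#' experimentally fitted reference exponents.
#'
#' @param n_grid colony sizes (default `2^(4:12)`, i.e. 16 ... 4096).
#' @param reps replicates per size (default 1000).
#' @param params a [raft_params()] object.
#' @param n_boot bootstrap resamples for the exponent CIs (default 1000).
#' @param seed master seed.
#' @return Object of class `scaling_report`: list with `sweep` (raw
#'   table), `fits`, `comparison` (vs model predictions),
#'   `reference_comparison` (vs experimental exponents), `seed`,
#'   `n_grid`, `reps`.
#' @examples
#' \donttest{
#' rep <- run_scaling_experiment(n_grid = 2^(4:8), reps = 100, seed = 1)
#' rep$comparison
#' }
#' @export
run_scaling_experiment <- function(n_grid = 2^(4:12), reps = 1000L,
                                   params = raft_params(), n_boot = 1000L,
                                   seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (reps == 1L) {
    warning("reps = 1: exponent fits will have very wide uncertainty",
            call. = FALSE)
  }
  sweep <- sweep_raft_sizes(n_grid, reps, params,
                            master_seed = spawn_seed(seed, 10))
  sc <- fit_sweep_scalings(sweep, n_boot = n_boot,
                           seed = spawn_seed(seed, 11))
  ref <- reference_stats()
  reference_comparison <- rbind(
    compare_exponents(sc$fits$v_cm, ref$b_v, "b_v (experiment)"),
    compare_exponents(sc$fits$omega, ref$b_omega, "b_omega (experiment)"),
    compare_exponents(sc$fits$radius_curv, ref$b_R, "b_R (experiment)"))
  structure(list(sweep = sweep, fits = sc$fits,
                 comparison = sc$comparison,
                 reference_comparison = reference_comparison,
                 seed = seed, n_grid = n_grid, reps = reps),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf("Raft scaling experiment: N in {%s}, %d reps, seed %d\n",
              paste(x$n_grid, collapse = ", "), x$reps, x$seed))
  cat("\nFitted exponents vs model predictions:\n")
  print(x$comparison, row.names = FALSE)
  cat("\nFitted exponents vs experimental reference fits:\n")
  print(x$reference_comparison, row.names = FALSE)
  invisible(x)
}

#' Serialize a scaling report to JSON
#'
#' @param report a [run_scaling_experiment()] result.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
scaling_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "scaling_report"))
  obj <- list(
    seed = report$seed, n_grid = report$n_grid, reps = report$reps,
    exponents = lapply(report$fits, function(f) {
      list(exponent = f$exponent, prefactor = f$prefactor,
           ci_low = f$ci_low, ci_high = f$ci_high,
           statistic = f$statistic)
    }),
    comparison = report$comparison,
    reference_comparison = report$reference_comparison)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# analyze generated swimmer tracks and match accepted arcs to their
# ground-truth rows
analyze_swimmers <- function(gen, min_frames = 70L, r_max = 50,
                             noiseless = FALSE) {
  tracks <- filter_tracks(gen$tracks, min_frames = min_frames, quiet = TRUE)
  rows <- list()
  for (tr in tracks) {
    arcs <- segment_arcs(tr)
    arcs <- apply_R_filter(arcs, R_max = r_max, quiet = TRUE)
    if (length(arcs) == 0L) next
    tab <- arcs_table(arcs)
    # match each arc to the truth arc containing its midpoint frame
    mids <- vapply(arcs, function(a) stats::median(a$frames), numeric(1))
    tru <- gen$truth[gen$truth$track_id == tr$track_id, , drop = FALSE]
    mi <- vapply(mids, function(m) {
      hit <- which(tru$start_frame <= m & m <= tru$end_frame)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    tab$true_v <- tru$v[mi]
    tab$true_R <- tru$R[mi]
    tab$true_handedness <- tru$handedness[mi]
    rows[[length(rows) + 1L]] <- tab
  }
  if (length(rows) == 0L) {
    return(data.frame(track_id = character(), arc_index = integer(),
                      v_um_s = numeric(), R_um = numeric(),
                      handedness = character(), accepted = logical(),
                      true_v = numeric(), true_R = numeric(),
                      true_handedness = character()))
  }
  do.call(rbind, rows)
}

# analyze generated raft marker tracks against their ground truth
analyze_rafts <- function(gen) {
  tru <- gen$truth
  out <- vector("list", nrow(tru))
  for (k in seq_len(nrow(tru))) {
    id <- tru$raft_id[k]
    kin <- raft_kinematics_from_markers(
      gen$tracks[[paste0(id, "_m1")]], gen$tracks[[paste0(id, "_m2")]],
      center0 = c(tru$center0_x[k], tru$center0_y[k]))
    out[[k]] <- data.frame(
      raft_id = id, v_cm = kin$v_cm, omega = kin$omega,
      R = kin$radius_curv, handedness = kin$handedness,
      true_v = tru$v_cm[k], true_omega = tru$omega[k], true_R = tru$R[k],
      true_handedness = tru$handedness[k])
  }
  do.call(rbind, out)
}

#' Round-trip validation of the generator / analysis pair
#'
#' Generates synthetic swimmer tracks and raft marker-pair tracks,
#' analyzes them with the full pipeline, and checks that the ground
#' truth is recovered: population mean speed within `tol_v`, mean radius
#' within `tol_R`, per-arc handedness confusion below `tol_hand`, and
#' raft `omega`, `v_cm`, `R` each within `tol_raft` (mean relative
#' error).
#'
#' @param swimmer_params a [swimmer_gen_params()]; defaults with
#'   `n_swimmers = 200`.
#' @param raft_params_gen a [raft_gen_params()].
#' @param tol_v,tol_R,tol_hand,tol_raft relative tolerances (defaults
#'   0.02, 0.05, 0.01, 0.05).
#' @param seed master seed overriding the generator seeds.
#' @return Object of class `roundtrip_report`: list of per-property
#'   measured deviations and pass flags, plus the matched result tables.
#' @export
run_roundtrip_validation <- function(swimmer_params = NULL,
                                     raft_params_gen = NULL,
                                     tol_v = 0.02, tol_R = 0.05,
                                     tol_hand = 0.01, tol_raft = 0.05,
                                     seed = 1L) {
  if (is.null(swimmer_params)) {
    swimmer_params <- swimmer_gen_params(n_swimmers = 200L,
                                         seed = spawn_seed(seed, 21))
  }
  if (is.null(raft_params_gen)) {
    raft_params_gen <- raft_gen_params(n_rafts = 50L,
                                       seed = spawn_seed(seed, 22))
  }
  sw <- gen_single_swimmers(swimmer_params)
  sw_res <- analyze_swimmers(sw)
  ok <- is.finite(sw_res$true_v)
  sw_res <- sw_res[ok, , drop = FALSE]
  dev_v <- abs(mean(sw_res$v_um_s) - mean(sw_res$true_v)) /
    mean(sw_res$true_v)
  dev_R <- abs(mean(sw_res$R_um) - mean(sw_res$true_R)) /
    mean(sw_res$true_R)
  confusion <- mean(sw_res$handedness != sw_res$true_handedness,
                    na.rm = TRUE)

  rf <- gen_raft_marker_tracks(raft_params_gen)
  rf_res <- analyze_rafts(rf)
  rel <- function(a, b) abs(a - b) / abs(b)
  dev_omega <- mean(rel(rf_res$omega, rf_res$true_omega))
  dev_vcm <- mean(rel(rf_res$v_cm, rf_res$true_v))
  dev_Rr <- mean(rel(rf_res$R, rf_res$true_R), na.rm = TRUE)

  checks <- data.frame(
    property = c("swimmer mean speed", "swimmer mean radius",
                 "swimmer handedness confusion", "raft omega",
                 "raft v_cm", "raft radius"),
    deviation = c(dev_v, dev_R, confusion, dev_omega, dev_vcm, dev_Rr),
    tolerance = c(tol_v, tol_R, tol_hand, tol_raft, tol_raft, tol_raft))
  checks$pass <- checks$deviation <= checks$tolerance
  structure(list(checks = checks, swimmer_results = sw_res,
                 raft_results = rf_res, seed = seed,
                 all_pass = all(checks$pass)),
            class = "roundtrip_report")
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat(sprintf("Round-trip validation (seed %d): %s\n", x$seed,
              if (x$all_pass) "all properties PASS" else "FAILURES present"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
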