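#' Default synthetic atrial / torso geometry
#'
#' Ellipsoidal icosphere stand-ins for the anatomical surfaces, at two
#' scales: `"tiny"` (162-node atria, 42-lead torso) for fast tests, and
#' `"small"` (642 / 162) for benchmark runs. Atrial semi-axes 40 x 35 x 50
#' mm and torso 120 x 100 x 160 mm approximate adult proportions.
#'
#' @param scale `"tiny"` or `"small"`
#' @return a `tri_mesh`
#' @export
default_atrial_mesh <- function(scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  build_ellipsoid_mesh(c(40, 35, 50), if (scale == "tiny") 2L else 3L)
}

#' @rdname default_atrial_mesh
#' @export
default_torso_mesh <- function(scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  build_ellipsoid_mesh(c(120, 100, 160), if (scale == "tiny") 1L else 2L)
}

model_filter_band <- function(model) {
  if (model == "SR") c(0, 30) else c(3, 30)
}

model_df_band <- function(model) {
  # the fibrillatory DF band would exclude the 1.2 Hz sinus pacing rate
  if (model == "SR") c(0.5, 15) else c(3, 15)
}

#' Benchmark configuration
#'
#' Declares the experimental grid: solvers x SNRs x activity models x
#' seeds, the signal timing, and the metric families to score. Validated
#' eagerly so misconfigurations fail before any simulation runs.
#'
#' @param solvers character vector of [solver_registry()] names
#' @param snr_db numeric SNR grid in dB (default `c(10, 20, 30, 40)`)
#' @param models subset of `c("SR", "SAF", "CAF")`
#' @param duration_s,fs phantom length (s) and sampling rate (Hz)
#' @param estimation_window length-2 window (s) the inverse solution is
#'   computed on
#' @param training_window length-2 window (s), disjoint from the estimation
#'   window, from which the Bayes prior covariance is sampled
#' @param n_prior_samples time samples drawn for the prior (default 150)
#' @param metrics subset of `c("potentials", "df", "phase", "sp")`
#' @param seeds integer vector, one complete grid pass per seed
#' @return a validated `bench_config`
#' @export
bench_config <- function(solvers = c("Tik-i0", "Tik-g0", "Bayes"),
                         snr_db = c(10, 20, 30, 40),
                         models = c("SAF", "CAF"),
                         duration_s = 8, fs = 500,
                         estimation_window = c(4, 8),
                         training_window = c(0, 1),
                         n_prior_samples = 150,
                         metrics = c("potentials", "df"),
                         seeds = 1L) {
  reg <- solver_registry()
  bad <- setdiff(solvers, reg$name)
  if (length(bad)) stop("unknown solver(s): ", paste(bad, collapse = ", "))
  if (!all(models %in% c("SR", "SAF", "CAF"))) stop("unknown model name")
  if (!all(metrics %in% c("potentials", "df", "phase", "sp"))) {
    stop("unknown metric family")
  }
  if (length(seeds) < 1L) stop("at least one seed is required")
  if (diff(estimation_window) <= 0) stop("empty estimation window")
  if ("Bayes" %in% solvers) {
    if (is.null(training_window)) {
      stop("Bayes requires a `training_window` for its prior covariance")
    }
    if (training_window[2] > estimation_window[1] &&
        training_window[1] < estimation_window[2]) {
      stop("training window must be disjoint from the estimation window")
    }
  }
  if (estimation_window[2] > duration_s + 1e-9) {
    stop("estimation window exceeds the simulated duration")
  }
  structure(list(solvers = solvers, snr_db = snr_db, models = models,
                 duration_s = duration_s, fs = fs,
                 estimation_window = estimation_window,
                 training_window = training_window,
                 n_prior_samples = n_prior_samples,
                 metrics = metrics, seeds = as.integer(seeds)),
            class = "bench_config")
}

# deterministic per-cell seed below 2^31
derive_seed <- function(seed, model, snr_db) {
  base <- (seed * 131L + match(model, c("SR", "SAF", "CAF")) * 17L) %% 100000L
  base * 1000L + (round(snr_db) %% 1000L)
}

#' Run the benchmark grid
#'
#' For every (model, seed, SNR, solver) cell: simulate the phantom, project
#' through the referenced transfer matrix, add calibrated noise, band-filter
#' (0-30 Hz for SR, 3-30 Hz for fibrillatory models), reconstruct on the
#' estimation window, extract the requested targets and score them against
#' the gold standard — the true epicardial potentials passed through the
#' same band filter as the torso signals. A solver failure marks the cell
#' failed and the run continues.
#'
#' @param config a [bench_config()]
#' @param atria atrial `tri_mesh`
#' @param torso torso `tri_mesh` (ignored when `A` is supplied)
#' @param A optional referenced `transfer_matrix`; default builds the
#'   monopole-kernel operator from the meshes and WCT-references it
#' @param verbose print one status line per cell
#' @return an `ecgi_benchmark` tibble: columns `solver`, `model`, `snr_db`,
#'   `seed`, `metric`, `value`, `status`
#' @export
run_benchmark <- function(config, atria, torso = NULL, A = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "bench_config"))
  if (is.null(A)) {
    if (is.null(torso)) stop("supply either `torso` or a transfer matrix `A`")
    A <- apply_wct_reference(kernel_transfer_matrix(atria, torso))
  } else if (!inherits(A, "transfer_matrix")) {
    A <- transfer_matrix(A, referenced = TRUE)
  }
  reg <- solver_registry()
  orders_needed <- unique(stats::na.omit(
    reg$order[reg$name %in% config$solvers]))
  ctx <- solver_context(A, atria, orders = orders_needed)
  dist <- if ("sp" %in% config$metrics) geodesic_distance(atria) else NULL
  areas <- node_areas(atria)

  rows <- list()
  push <- function(solver, model, snr, seed, metric, value, status = "ok") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      solver = solver, model = model, snr_db = snr, seed = seed,
      metric = metric, value = value, status = status)
  }

  for (model in config$models) {
    band <- model_filter_band(model)
    df_band <- model_df_band(model)
    for (seed in config$seeds) {
      pattern <- activity_pattern(model, seed = seed)
      phantom <- simulate_pattern(atria, pattern, config$duration_s, config$fs)
      gold_full <- bandpass_filter(phantom$field, band[1], band[2])
      gold_est <- field_window(gold_full, config$estimation_window[1],
                               config$estimation_window[2])
      Y0 <- forward_project(A, phantom$field)
      p_sig <- mean(Y0$values^2)
      C_x <- if ("Bayes" %in% config$solvers) {
        estimate_prior_covariance(
          field_window(gold_full, config$training_window[1],
                       config$training_window[2]),
          n_samples = config$n_prior_samples, seed = seed)
      } else NULL
      gold_cache <- new.env()
      for (snr in config$snr_db) {
        cell_seed <- derive_seed(seed, model, snr)
        Yn <- add_noise(Y0, snr, seed = cell_seed)
        Yf <- bandpass_filter(Yn, band[1], band[2])
        Yw <- field_window(Yf, config$estimation_window[1],
                           config$estimation_window[2])
        sigma_n2 <- p_sig / 10^(snr / 10)
        for (solver in config$solvers) {
          if (verbose) {
            message(sprintf("[%s seed %d SNR %g dB] %s", model, seed, snr, solver))
          }
          sol <- tryCatch(
            ecgi_solve(A, Yw, solver, mesh = atria, context = ctx,
                       C_x = C_x, sigma_n2 = sigma_n2),
            error = function(e) e)
          if (inherits(sol, "error")) {
            for (met in config$metrics) {
              push(solver, model, snr, seed, met, NA_real_,
                   status = conditionMessage(sol))
            }
            next
          }
          est <- sol$estimate
          if ("potentials" %in% config$metrics) {
            g <- glance(potential_metrics(gold_est, est))
            push(solver, model, snr, seed, "cc", g$cc_mean)
            push(solver, model, snr, seed, "cc_sd", g$cc_sd)
            push(solver, model, snr, seed, "rdms", g$rdms_mean)
            push(solver, model, snr, seed, "rdms_sd", g$rdms_sd)
          }
          needs_df <- any(c("df", "phase", "sp") %in% config$metrics)
          if (needs_df) {
            if (is.null(gold_cache$df_true)) {
              gold_cache$df_true <- df_map(gold_est, band = df_band)
            }
            df_true <- gold_cache$df_true
            df_est <- df_map(est, band = df_band)
          }
          if ("df" %in% config$metrics) {
            push(solver, model, snr, seed, "rae", rae(df_true, df_est))
          }
          if (any(c("phase", "sp") %in% config$metrics)) {
            if (is.null(gold_cache$pm_true)) {
              gold_cache$pm_true <- phase_map(gold_est, df_true)
            }
            pm_true <- gold_cache$pm_true
            pm_est <- phase_map(est, df_est)
          }
          if ("phase" %in% config$metrics) {
            both <- pm_true$valid & pm_est$valid
            g <- glance(potential_metrics(pm_true$phase[both, , drop = FALSE],
                                          pm_est$phase[both, , drop = FALSE]))
            push(solver, model, snr, seed, "phase_cc", g$cc_mean)
            push(solver, model, snr, seed, "phase_rdms", g$rdms_mean)
          }
          if ("sp" %in% config$metrics) {
            if (is.null(gold_cache$smf_true)) {
              tr_true <- track_sps(detect_sps(atria, pm_true), atria, df_true,
                                   config$fs, dist = dist)
              gold_cache$smf_true <- sp_smf(tr_true, atria$n_vertices)
            }
            tr_est <- track_sps(detect_sps(atria, pm_est), atria, df_est,
                                config$fs, dist = dist)
            smf_true <- gold_cache$smf_true
            smf_est <- sp_smf(tr_est, atria$n_vertices)
            push(solver, model, snr, seed, "wui", wui(smf_true, smf_est, areas))
            push(solver, model, snr, seed, "woi", woi(smf_true, smf_est, areas))
            push(solver, model, snr, seed, "cc_smf", cc_smf(smf_true, smf_est))
            push(solver, model, snr, seed, "md",
                 mode_distance(smf_true, smf_est, atria))
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ecgi_benchmark", class(out))
  attr(out, "config") <- config
  out
}

#' Write benchmark fixture files
#'
#' Generates the synthetic study inputs as plain-text files: atrial and
#' torso meshes (OFF), the WCT-referenced kernel transfer matrix
#' (MatrixMarket array), and 8-s phantoms for the three activity models
#' (CSV + JSON sidecar), all reproducible from `seed`.
#'
#' @param out_dir writable output directory (created if missing)
#' @param scale `"tiny"` (162-node atria / 42-lead torso) or `"small"`
#'   (642 / 162)
#' @param seed integer seed for the phantoms
#' @param duration_s,fs phantom timing
#' @return invisibly, the vector of files written
#' @export
make_fixtures <- function(out_dir, scale = c("tiny", "small"), seed = 1L,
                          duration_s = 8, fs = 500) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atria <- default_atrial_mesh(scale)
  torso <- default_torso_mesh(scale)
  files <- character(0)
  wr <- function(f) { files <<- c(files, f); f }
  write_mesh(atria, wr(file.path(out_dir, "atria.off")))
  write_mesh(torso, wr(file.path(out_dir, "torso.off")))
  A <- apply_wct_reference(kernel_transfer_matrix(atria, torso))
  write_transfer_matrix(A, wr(file.path(out_dir, "transfer.mtx")))
  for (model in c("SR", "SAF", "CAF")) {
    ph <- simulate_pattern(atria, activity_pattern(model, seed = seed),
                           duration_s, fs)
    write_potential_field(ph$field,
                          wr(file.path(out_dir, paste0(tolower(model), ".csv"))))
  }
  jsonlite::write_json(
    list(scale = scale, seed = seed, duration_s = duration_s, fs = fs,
         atria_nodes = atria$n_vertices, torso_leads = torso$n_vertices),
    wr(file.path(out_dir, "fixtures.json")), auto_unbox = TRUE)
  invisible(files)
}
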