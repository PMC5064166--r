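#' Activity pattern specifications
#'
#' Kinematic descriptions of the three epicardial propagation regimes the
#' phantom generator can produce:
#'
#' * `"SR"` — sinus rhythm: a plane wave sweeping the atria, every node
#'   activating at the pacing rate (default 1.2 Hz).
#' * `"SAF"` — simple AF: one functional reentry (rotor) spinning at
#'   `rotor_rate_hz` (default 7.3 Hz) inside a geodesic ball around the core,
#'   with the remaining tissue paced at `remote_rate_hz` (default 4.7 Hz),
#'   giving a two-level dominant-frequency gradient.
#' * `"CAF"` — complex AF: as SAF but at 6.8 / 5.4 Hz and with a fraction of
#'   nodes (default 25%) under fibrotic conditions, emulated by amplitude
#'   dropout (x 0.1) and activation-time jitter up to 10% of cycle length.
#'
#' @param kind `"SR"`, `"SAF"` or `"CAF"`
#' @param rate_hz pacing rate for SR / remote tissue rate for AF kinds (Hz)
#' @param rotor_rate_hz rotor rotation rate (Hz; AF kinds only)
#' @param rotor_center 3-D point for the rotor core; snapped to the nearest
#'   mesh node (default: node of largest x, a right-atrial stand-in)
#' @param rotor_radius_mm geodesic radius of the rotor-driven region
#' @param fibrotic_fraction fraction of nodes under fibrotic dropout (CAF)
#' @param boundary `"hard"` (default) or `"smooth"` (logistic blend over 5 mm)
#' @param seed integer seed driving the fibrotic node draw and jitter
#' @return an `activity_pattern` object
#' @export
activity_pattern <- function(kind = c("SR", "SAF", "CAF"),
                             rate_hz = NULL, rotor_rate_hz = NULL,
                             rotor_center = NULL, rotor_radius_mm = 25,
                             fibrotic_fraction = NULL,
                             boundary = c("hard", "smooth"),
                             seed = 1L) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  defaults <- switch(kind,
    SR  = list(rate = 1.2, rotor = NA_real_, fib = 0),
    SAF = list(rate = 4.7, rotor = 7.3, fib = 0),
    CAF = list(rate = 5.4, rotor = 6.8, fib = 0.25)
  )
  rate_hz <- if (is.null(rate_hz)) defaults$rate else rate_hz
  rotor_rate_hz <- if (is.null(rotor_rate_hz)) defaults$rotor else rotor_rate_hz
  fibrotic_fraction <- if (is.null(fibrotic_fraction)) defaults$fib else fibrotic_fraction
  if (rate_hz <= 0) stop("`rate_hz` must be > 0")
  if (kind != "SR") {
    if (is.na(rotor_rate_hz) || rotor_rate_hz <= 0) stop("`rotor_rate_hz` must be > 0")
    if (rotor_rate_hz < rate_hz) stop("rotor rate must be >= remote rate")
  }
  if (kind != "CAF" && fibrotic_fraction != 0) {
    stop("`fibrotic_fraction` must be 0 unless kind = \"CAF\"")
  }
  if (fibrotic_fraction < 0 || fibrotic_fraction >= 1) {
    stop("`fibrotic_fraction` must be in [0, 1)")
  }
  structure(
    list(kind = kind, rate_hz = rate_hz, rotor_rate_hz = rotor_rate_hz,
         rotor_center = rotor_center, rotor_radius_mm = rotor_radius_mm,
         fibrotic_fraction = fibrotic_fraction, boundary = boundary,
         seed = as.integer(seed)),
    class = "activity_pattern"
  )
}

#' Action-potential waveform template
#'
#' Maps phase to a normalized transmembrane-potential-like shape: a sharp
#' depolarization upstroke over the first `upstroke_fraction` of the cycle
#' followed by a slow repolarization. Built from two matched half-cosine
#' arcs, so it is 2-pi-periodic, continuously differentiable, and spans
#' exactly \[-1, 1\].
#'
#' @param phase numeric vector/matrix of phase in radians
#' @param upstroke_fraction fraction of the cycle spent depolarizing
#' @return values in \[-1, 1\], same shape as `phase`
#' @export
action_potential_waveform <- function(phase, upstroke_fraction = 0.2) {
  a <- 2 * pi * upstroke_fraction
  p <- phase %% (2 * pi)
  up <- p < a
  out <- numeric(length(p))
  out[up] <- -cos(pi * p[up] / a)
  out[!up] <- cos(pi * (p[!up] - a) / (2 * pi - a))
  dim(out) <- dim(p)
  out
}

#' Simulate an epicardial activity phantom
#'
#' Produces the prescribed-phase ("kinematic") activity field for a pattern:
#' each node carries a phase trajectory `phi(n, t)` and the potential is
#' `amplitude * action_potential_waveform(phi)`. SR is a plane wave along the
#' pacing axis; SAF/CAF place one phase singularity at the rotor core (phase
#' advances with the azimuthal angle about the core in its tangent plane)
#' inside a geodesic ball, with a plane wave at the remote rate outside.
#' CAF additionally draws a fibrotic node set (amplitude x 0.1, activation
#' jitter up to 10% of local cycle length).
#'
#' This generator is not an ionic/reaction-diffusion model: it provides
#' ground-truth signals with the prescribed spectral and phase structure so
#' the inverse/target/metric chain can be benchmarked against known answers.
#'
#' @param mesh atrial `tri_mesh`
#' @param pattern an `activity_pattern`
#' @param duration_s signal length, s (>= 4 so 2-s Welch windows fit)
#' @param fs sampling rate, Hz (>= 100)
#' @param pacing_axis unit 3-vector for the plane-wave direction
#' @param amplitude_mv peak amplitude, mV
#' @return an `activity_phantom`: list with `field` (`potential_field`),
#'   `phase` (true node x time phase, wrapped), `df_true` (per-node rate,
#'   Hz), `core_node` (rotor core index or `NA`), `region_nodes`,
#'   `fibrotic_nodes`, `boundary_nodes` (within 5 mm of the region edge),
#'   and `pattern`.
#' @export
simulate_pattern <- function(mesh, pattern, duration_s = 8, fs = 500,
                             pacing_axis = c(0, 0, 1), amplitude_mv = 1) {
  if (duration_s < 4) stop("`duration_s` must be >= 4 s (2-s Welch windows with overlap)")
  if (fs < 100) stop("`fs` must be >= 100 Hz")
  n <- mesh$n_vertices
  nt <- round(duration_s * fs)
  tt <- (seq_len(nt) - 1L) / fs
  axis <- pacing_axis / sqrt(sum(pacing_axis^2))
  s <- as.vector(mesh$vertices %*% axis)
  s <- (s - min(s)) / (max(s) - min(s))  # one wavelength across the mesh

  amp <- rep(amplitude_mv, n)
  jitter <- numeric(n)
  fibrotic <- integer(0)
  core <- NA_integer_
  region <- integer(0)
  boundary_nodes <- integer(0)

  if (pattern$kind == "SR") {
    rate <- rep(pattern$rate_hz, n)
    phase_space <- 2 * pi * s
  } else {
    core <- if (is.null(pattern$rotor_center)) {
      which.max(mesh$vertices[, 1])
    } else {
      d2 <- colSums((t(mesh$vertices) - pattern$rotor_center)^2)
      cand <- which.min(d2)
      if (d2[cand] > 1e-12) warning("rotor core not on mesh; snapped to node ", cand)
      cand
    }
    gdist <- geodesic_distance(mesh, src = core)[1, ]
    region <- which(gdist <= pattern$rotor_radius_mm)
    boundary_nodes <- which(abs(gdist - pattern$rotor_radius_mm) <= 5)
    rate <- rep(pattern$rate_hz, n)
    rate[region] <- pattern$rotor_rate_hz
    # azimuth of each node about the core, in the core's tangent plane
    nrm <- vertex_normals(mesh)[core, ]
    e1 <- c(1, 0, 0)
    if (abs(sum(e1 * nrm)) > 0.9) e1 <- c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    rel <- sweep(mesh$vertices, 2L, mesh$vertices[core, ], `-`)
    theta <- atan2(rel %*% e2, rel %*% e1)[, 1]
    theta[core] <- 0
    phase_space <- 2 * pi * s        # remote plane wave offset
    phase_space[region] <- theta[region]
    if (pattern$fibrotic_fraction > 0) {
      set.seed(pattern$seed)
      n_fib <- round(pattern$fibrotic_fraction * n)
      fibrotic <- sort(sample.int(n, n_fib))
      amp[fibrotic] <- amp[fibrotic] * 0.1
      # activation-time jitter up to 10% of the local cycle length
      jitter[fibrotic] <- stats::runif(n_fib, -0.1, 0.1) / rate[fibrotic]
    }
  }

  if (pattern$kind != "SR" && pattern$boundary == "smooth") {
    # logistic blend of the two phase fields over ~5 mm around the boundary
    w <- 1 / (1 + exp((gdist - pattern$rotor_radius_mm) / (5 / 4)))
    phase <- outer(rep(1, n), 2 * pi * tt) * (w * pattern$rotor_rate_hz +
                                                (1 - w) * pattern$rate_hz) -
      (w * phase_space + (1 - w) * 2 * pi * s)
  } else {
    phase <- outer(rate, 2 * pi * tt) - phase_space +
      outer(2 * pi * rate * jitter, rep(1, nt))
  }
  values <- amp * action_potential_waveform(phase)

  structure(
    list(field = potential_field(values, fs),
         phase = wrap_phase(phase),
         df_true = rate,
         core_node = core,
         region_nodes = region,
         fibrotic_nodes = fibrotic,
         boundary_nodes = boundary_nodes,
         pattern = pattern),
    class = "activity_phantom"
  )
}

#' @export
print.activity_phantom <- function(x, ...) {
  cat("<activity_phantom> ", x$pattern$kind, ", ",
      nrow(x$field$values), " nodes x ", ncol(x$field$values), " samples @ ",
      x$field$fs, " Hz", sep = "")
  if (!is.na(x$core_node)) cat(", rotor core at node ", x$core_node, sep = "")
  cat("\n")
  invisible(x)
}
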