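#' Transfer matrix container
#'
#' Dense leads x nodes linear operator mapping epicardial potentials to
#' body-surface potentials, with a flag recording whether Wilson-Central-
#' Terminal referencing has been applied.
#'
#' @param entries M x N numeric matrix
#' @param referenced logical; has WCT referencing been applied
#' @param lead_positions optional M x 3 electrode coordinates (mm)
#' @return an object of class `transfer_matrix`
#' @export
transfer_matrix <- function(entries, referenced = FALSE, lead_positions = NULL) {
  entries <- as.matrix(entries)
  if (any(!is.finite(entries))) stop("transfer matrix entries must be finite")
  if (nrow(entries) < 1L || ncol(entries) < 1L) stop("empty transfer matrix")
  structure(list(entries = entries, referenced = referenced,
                 lead_positions = lead_positions),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("<transfer_matrix> ", nrow(x$entries), " leads x ", ncol(x$entries),
      " nodes, ", if (x$referenced) "WCT-referenced" else "unreferenced",
      "\n", sep = "")
  invisible(x)
}

#' Infinite-medium monopole-kernel transfer matrix
#'
#' Pluggable stand-in for a boundary-element volume-conductor operator: each
#' entry is the potential at electrode m of a unit monopole at atrial node n
#' in an infinite homogeneous medium, weighted by the node's barycentric
#' area: `A'[m, n] = area_n / (4 pi sigma r_mn)`. Any externally computed
#' matrix (e.g. a BEM matrix) can be loaded with [read_transfer_matrix()]
#' instead; downstream code is agnostic to the origin of the operator.
#'
#' @param atria,torso `tri_mesh` objects; torso vertices act as electrodes
#' @param conductivity_s_m medium conductivity, S/m
#' @return an unreferenced `transfer_matrix`
#' @export
kernel_transfer_matrix <- function(atria, torso, conductivity_s_m = 0.2) {
  if (conductivity_s_m <= 0) stop("`conductivity_s_m` must be > 0")
  an <- node_areas(atria)
  # enclosure check: every atrial vertex within the torso bounding box
  lo <- apply(torso$vertices, 2, min); hi <- apply(torso$vertices, 2, max)
  inside <- sweep(atria$vertices, 2, lo, `>=`) & sweep(atria$vertices, 2, hi, `<=`)
  if (!all(inside)) warning("atrial vertices fall outside the torso bounding hull")
  M <- nrow(torso$vertices); N <- nrow(atria$vertices)
  A <- matrix(0, M, N)
  for (m in seq_len(M)) {
    r <- sqrt(colSums((t(atria$vertices) - torso$vertices[m, ])^2))
    if (any(r < 1e-9)) stop("electrode ", m, " coincides with an atrial node")
    A[m, ] <- an / (4 * pi * conductivity_s_m * r)
  }
  transfer_matrix(A, referenced = FALSE, lead_positions = torso$vertices)
}

#' Apply Wilson-Central-Terminal referencing to a transfer matrix
#'
#' Re-references the raw operator so modelled body-surface potentials are
#' measured against the mean of the WCT lead set:
#' `A = (I - (1/|W|) 1 w^T) A'`, with `w` the indicator of the WCT leads.
#' For any source `x` the mean of `A x` over the WCT leads is exactly zero.
#'
#' @param A_raw an unreferenced `transfer_matrix`
#' @param wct_leads integer indices of the leads forming the WCT
#'   (default: all leads)
#' @return a referenced `transfer_matrix`
#' @export
apply_wct_reference <- function(A_raw, wct_leads = NULL) {
  if (!inherits(A_raw, "transfer_matrix")) A_raw <- transfer_matrix(A_raw)
  if (A_raw$referenced) stop("transfer matrix is already WCT-referenced")
  M <- nrow(A_raw$entries)
  if (is.null(wct_leads)) wct_leads <- seq_len(M)
  if (length(wct_leads) == 0L || any(wct_leads < 1L) || any(wct_leads > M)) {
    stop("invalid WCT lead indices")
  }
  wct_mean <- colMeans(A_raw$entries[wct_leads, , drop = FALSE])
  A <- sweep(A_raw$entries, 2L, wct_mean, `-`)
  transfer_matrix(A, referenced = TRUE, lead_positions = A_raw$lead_positions)
}

#' Project epicardial potentials to the body surface
#' @param A a referenced `transfer_matrix`
#' @param X epicardial `potential_field` (N nodes x T samples)
#' @return torso `potential_field` (M leads x T samples)
#' @export
forward_project <- function(A, X) {
  if (!inherits(A, "transfer_matrix")) A <- transfer_matrix(A, referenced = TRUE)
  if (ncol(A$entries) != nrow(X$values)) {
    stop("transfer matrix has ", ncol(A$entries), " columns but field has ",
         nrow(X$values), " nodes")
  }
  potential_field(A$entries %*% X$values, X$fs, X$t0)
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise variance is calibrated against the global signal power (mean square
#' over all leads and samples): `10 log10(P_signal / P_noise) = snr_db`.
#'
#' @param Y a `potential_field`
#' @param snr_db target signal-to-noise ratio, dB; `Inf` returns `Y` unchanged
#' @param seed integer seed (noise is bit-reproducible)
#' @return a `potential_field`
#' @export
add_noise <- function(Y, snr_db, seed = 1L) {
  if (is.infinite(snr_db) && snr_db > 0) return(Y)
  p_sig <- mean(Y$values^2)
  if (p_sig == 0) stop("zero-power signal: finite SNR is undefined")
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(Y$values), sd = sigma),
                  nrow(Y$values), ncol(Y$values))
  potential_field(Y$values + noise, Y$fs, Y$t0)
}

#' Zero-phase Butterworth band filtering
#'
#' Fourth-order Butterworth applied forward-backward (`signal::filtfilt`)
#' per lead, so the filter is zero-phase: phase maps computed downstream are
#' not biased by group delay. `low_hz = 0` selects a pure low-pass.
#'
#' @param Y a `potential_field`
#' @param low_hz,high_hz passband edges, Hz (`0 <= low < high < fs/2`)
#' @param order filter order (default 4)
#' @return a filtered `potential_field`
#' @export
bandpass_filter <- function(Y, low_hz, high_hz, order = 4) {
  nyq <- Y$fs / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("band must satisfy 0 <= low < high < fs/2 = ", nyq)
  }
  bf <- if (low_hz == 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  out <- t(apply(Y$values, 1L, function(x) signal::filtfilt(bf, x)))
  potential_field(out, Y$fs, Y$t0)
}

#' Perturb a transfer matrix at a prescribed per-row SER
#'
#' Adds i.i.d. Gaussian error to each row with power calibrated so the row's
#' signal-to-error ratio `10 log10(P_row / P_error)` equals `ser_db`; used to
#' probe sensitivity to imperfect knowledge of the volume conductor.
#'
#' @param A a `transfer_matrix`
#' @param ser_db target per-row signal-to-error ratio, dB; `Inf` returns `A`
#' @param seed integer seed
#' @return a perturbed `transfer_matrix` (same referencing state)
#' @export
perturb_transfer_matrix <- function(A, ser_db, seed = 1L) {
  if (!inherits(A, "transfer_matrix")) A <- transfer_matrix(A)
  if (is.infinite(ser_db) && ser_db > 0) return(A)
  E <- A$entries
  row_p <- rowMeans(E^2)
  if (any(row_p == 0)) stop("all-zero row: finite SER is undefined")
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(E)), nrow(E), ncol(E)) *
    sqrt(row_p / 10^(ser_db / 10))
  transfer_matrix(E + noise, referenced = A$referenced,
                  lead_positions = A$lead_positions)
}
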