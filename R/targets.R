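#' Welch power spectral density
#'
#' Welch's averaged periodogram with 2-s Hamming segments and 50% overlap,
#' zero-padded so the frequency grid is fine enough (0.05 Hz by default) to
#' represent fibrillatory rates exactly — the raw 2-s window alone only
#' resolves 0.5 Hz. Accepts a vector (one signal) or a node x time matrix
#' (one PSD per row, computed in a single FFT pass).
#'
#' @param x numeric vector or matrix (rows = channels), or `potential_field`
#' @param fs sampling rate, Hz (taken from the field if one is given)
#' @param window_s segment length in seconds (default 2)
#' @param overlap fractional overlap between segments (default 0.5)
#' @param grid_hz target frequency-grid spacing; the FFT is zero-padded to
#'   `ceiling(fs / grid_hz)` points (default 0.05 Hz)
#' @return list with `freq` (Hz) and `psd` (vector, or channels x freq
#'   matrix)
#' @export
welch_psd <- function(x, fs = NULL, window_s = 2, overlap = 0.5,
                      grid_hz = 0.05) {
  if (inherits(x, "potential_field")) { fs <- x$fs; x <- x$values }
  if (is.null(fs)) stop("`fs` is required")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else as.matrix(x)
  L <- round(window_s * fs)
  if (ncol(X) < L) stop("signal shorter than one ", window_s, "-s Welch window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, ncol(X) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hamming
  nfft <- max(L, ceiling(fs / grid_hz))
  nfreq <- nfft %/% 2 + 1L
  acc <- matrix(0, nrow(X), nfreq)
  for (s0 in starts) {
    seg <- X[, s0:(s0 + L - 1L), drop = FALSE] *
      matrix(w, nrow(X), L, byrow = TRUE)
    segp <- cbind(seg, matrix(0, nrow(X), nfft - L))
    F <- t(stats::mvfft(t(segp)))[, seq_len(nfreq), drop = FALSE]
    acc <- acc + Mod(F)^2
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  psd <- acc * scale
  # one-sided: double all bins except DC (and Nyquist when nfft is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nfreq] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  freq <- (seq_len(nfreq) - 1L) * fs / nfft
  list(freq = freq, psd = if (vec) drop(psd) else psd)
}

find_peaks <- function(psd) {
  n <- length(psd)
  if (n < 3L) return(integer(0))
  which(psd[2:(n - 1)] > psd[1:(n - 2)] & psd[2:(n - 1)] >= psd[3:n]) + 1L
}

#' Dominant frequency with harmonic discard
#'
#' Finds local spectral maxima inside the search band and discards a peak at
#' `f` as a harmonic whenever another peak exists within `harmonic_tol` of
#' `f/2` carrying at least `harmonic_ratio` of its power (the subharmonic
#' check searches the full spectrum, not just the band); the highest
#' surviving peak's frequency is the DF.
#'
#' @param psd,freq PSD and frequency grid (as from [welch_psd()])
#' @param band length-2 search band in Hz (default `c(3, 15)`; sinus-rhythm
#'   analyses should widen this below the pacing rate)
#' @param harmonic_tol half-frequency matching tolerance, Hz (default 0.25)
#' @param harmonic_ratio minimum subharmonic power fraction (default 0.3)
#' @param min_rel_power noise-floor guard: local maxima carrying less than
#'   this fraction of the strongest spectral peak (default 1%) are leakage
#'   ripple, not peaks
#' @return dominant frequency in Hz, or `NA_real_` if no peak lies in band
#' @export
dominant_frequency <- function(psd, freq, band = c(3, 15),
                               harmonic_tol = 0.25, harmonic_ratio = 0.3,
                               min_rel_power = 0.01) {
  pk_all <- find_peaks(psd)
  pk_all <- pk_all[psd[pk_all] >= min_rel_power * max(psd[pk_all], 0)]
  in_band <- pk_all[freq[pk_all] >= band[1] & freq[pk_all] <= band[2]]
  if (length(in_band) == 0L) return(NA_real_)
  keep <- logical(length(in_band))
  for (i in seq_along(in_band)) {
    f <- freq[in_band[i]]
    p <- psd[in_band[i]]
    half <- pk_all[abs(freq[pk_all] - f / 2) <= harmonic_tol]
    keep[i] <- !any(psd[half] >= harmonic_ratio * p)
  }
  surv <- in_band[keep]
  if (length(surv) == 0L) return(NA_real_)
  freq[surv[which.max(psd[surv])]]
}

#' Per-node dominant frequency map
#'
#' Runs the Welch + harmonic-discard DF estimator on every node of a
#' potential field.
#'
#' @param field a `potential_field`
#' @param band DF search band, Hz
#' @param ... passed to [welch_psd()]
#' @return a `df_map`: list with `df` (Hz per node, `NA` where no peak) and
#'   `grid_hz` (spectral grid spacing)
#' @export
df_map <- function(field, band = c(3, 15), ...) {
  w <- welch_psd(field, ...)
  df <- apply(w$psd, 1L, dominant_frequency, freq = w$freq, band = band)
  structure(list(df = df, grid_hz = w$freq[2] - w$freq[1], band = band),
            class = "df_map")
}

#' @export
print.df_map <- function(x, ...) {
  cat("<df_map> ", length(x$df), " nodes, grid ", x$grid_hz, " Hz; ",
      sum(is.na(x$df)), " undetermined\n", sep = "")
  invisible(x)
}

analytic_phase <- function(x) {
  # analytic signal via the frequency-domain Hilbert construction, per row
  X <- if (is.null(dim(x))) matrix(x, 1L) else x
  n <- ncol(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  F <- t(stats::mvfft(t(X)))
  Z <- t(stats::mvfft(t(F * matrix(h, nrow(X), n, byrow = TRUE)),
                      inverse = TRUE)) / n
  ph <- Arg(Z)
  if (is.null(dim(x))) drop(ph) else ph
}

#' Instantaneous phase map
#'
#' Per node: zero-phase band-pass around the node's dominant frequency
#' (passband 3 Hz to `DF + 2` Hz; for slow nodes where that band would
#' collapse the low edge drops to half the DF), then the analytic-signal
#' (Hilbert) phase, wrapped to (-pi, pi].
#'
#' @param field a `potential_field`
#' @param df a `df_map` (or numeric per-node DF vector)
#' @param low_hz lower passband edge (default 3 Hz)
#' @return a `phase_map`: list with `phase` (node x time, radians), `fs`,
#'   `valid` (nodes with a usable DF)
#' @export
phase_map <- function(field, df, low_hz = 3) {
  dfv <- if (inherits(df, "df_map")) df$df else df
  X <- field$values
  if (length(dfv) != nrow(X)) stop("DF vector length must match node count")
  ph <- matrix(NA_real_, nrow(X), ncol(X))
  valid <- !is.na(dfv)
  for (f in unique(dfv[valid])) {
    nodes <- which(valid & dfv == f)
    lo <- if (f + 2 <= low_hz + 0.5) max(0.25, f / 2) else low_hz
    hi <- min(f + 2, field$fs / 2 * 0.99)
    bf <- signal::butter(4, c(lo, hi) / (field$fs / 2), type = "pass")
    filt <- t(apply(X[nodes, , drop = FALSE], 1L,
                    function(x) signal::filtfilt(bf, x)))
    ph[nodes, ] <- analytic_phase(filt)
  }
  structure(list(phase = wrap_phase(ph), fs = field$fs, valid = valid),
            class = "phase_map")
}

ring_edge_table <- function(mesh, rings = NULL) {
  if (is.null(rings)) rings <- one_ring_cycles(mesh)
  from <- integer(0); to <- integer(0); owner <- integer(0)
  for (v in seq_along(rings)) {
    r <- rings[[v]]
    if (is.null(r)) next
    from <- c(from, r)
    to <- c(to, c(r[-1], r[1]))
    owner <- c(owner, rep(v, length(r)))
  }
  list(from = from, to = to, owner = owner)
}

#' Topological charge of every node's one-ring
#'
#' Sums wrapped phase differences along each node's ordered one-ring cycle;
#' the result is a multiple of 2 pi (+/- 2 pi surrounds one phase
#' singularity of the corresponding chirality).
#'
#' @param mesh a `tri_mesh`
#' @param phase per-node phase vector, or node x time matrix
#' @param ring_table precomputed [ring_edge_table] (internal reuse)
#' @return charge vector (or node x time matrix), radians
#' @export
ring_charge <- function(mesh, phase, ring_table = NULL) {
  rt <- if (is.null(ring_table)) ring_edge_table(mesh) else ring_table
  if (is.null(dim(phase))) {
    d <- wrap_phase(phase[rt$to] - phase[rt$from])
    ch <- rowsum(d, rt$owner, reorder = TRUE)
    out <- numeric(length(phase))
    out[as.integer(rownames(ch))] <- ch
    out
  } else {
    D <- wrap_phase(phase[rt$to, , drop = FALSE] - phase[rt$from, , drop = FALSE])
    ch <- rowsum(D, rt$owner, reorder = TRUE)
    out <- matrix(0, nrow(phase), ncol(phase))
    out[as.integer(rownames(ch)), ] <- ch
    out
  }
}

#' Detect phase singularities in one phase frame
#'
#' A node is charged when the wrapped phase differences along its ordered
#' one-ring sum to +/- 2 pi — the discrete formalization of "a point
#' surrounded by phases from 0 to 2 pi". Adjacent charged nodes of equal
#' chirality (the ring of nodes around the singular face) are merged into
#' one detection, represented by the node nearest the cluster centroid.
#'
#' @param mesh a `tri_mesh`
#' @param phase_t per-node phase at one instant (radians); `NA` nodes skipped
#' @param charge_tol acceptance half-width around 2 pi (default 0.5 rad)
#' @param ring_table,adjacency internal precomputation hooks
#' @return data frame with columns `node`, `chirality` (one row per SP;
#'   zero rows when none)
#' @export
detect_sps_frame <- function(mesh, phase_t, charge_tol = 0.5,
                             ring_table = NULL, adjacency = NULL) {
  ok <- !is.na(phase_t)
  ph <- phase_t
  ph[!ok] <- 0
  charge <- ring_charge(mesh, ph, ring_table)
  # invalidate nodes whose ring touches an invalid node
  rt <- if (is.null(ring_table)) ring_edge_table(mesh) else ring_table
  bad_owner <- unique(rt$owner[!ok[rt$from] | !ok[rt$to]])
  charge[bad_owner] <- 0
  charge[!ok] <- 0
  chir <- integer(length(charge))
  chir[abs(charge - 2 * pi) < charge_tol] <- 1L
  chir[abs(charge + 2 * pi) < charge_tol] <- -1L
  cluster_detections(mesh, chir, adjacency)
}

cluster_detections <- function(mesh, chir, adjacency = NULL) {
  hit <- which(chir != 0L)
  if (length(hit) == 0L) {
    return(data.frame(node = integer(0), chirality = integer(0)))
  }
  if (is.null(adjacency)) adjacency <- mesh_adjacency_list(mesh)
  visited <- logical(length(chir))
  out_node <- integer(0); out_chir <- integer(0)
  for (v in hit) {
    if (visited[v]) next
    comp <- v; queue <- v; visited[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adjacency[[u]]
      nb <- nb[!visited[nb] & chir[nb] == chir[v]]
      visited[nb] <- TRUE
      comp <- c(comp, nb)
      queue <- c(queue, nb)
    }
    ctr <- colMeans(mesh$vertices[comp, , drop = FALSE])
    d2 <- colSums((t(mesh$vertices[comp, , drop = FALSE]) - ctr)^2)
    rep_node <- comp[order(d2, comp)[1]]
    out_node <- c(out_node, rep_node)
    out_chir <- c(out_chir, chir[v])
  }
  data.frame(node = out_node, chirality = out_chir)
}

mesh_adjacency_list <- function(mesh) {
  e <- mesh_edges(mesh)
  adj <- vector("list", mesh$n_vertices)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

#' Detect phase singularities in every frame of a phase map
#'
#' @param mesh a `tri_mesh`
#' @param pm a `phase_map` (or node x time phase matrix)
#' @param charge_tol see [detect_sps_frame()]
#' @return tibble with columns `frame`, `node`, `chirality`
#' @export
detect_sps <- function(mesh, pm, charge_tol = 0.5) {
  phase <- if (inherits(pm, "phase_map")) pm$phase else pm
  rt <- ring_edge_table(mesh)
  adj <- mesh_adjacency_list(mesh)
  ok <- !is.na(phase)
  ph0 <- phase; ph0[!ok] <- 0
  charge <- ring_charge(mesh, ph0, rt)
  invalid_nodes <- which(!ok[, 1])
  if (length(invalid_nodes)) {
    bad_owner <- unique(rt$owner[rt$from %in% invalid_nodes |
                                   rt$to %in% invalid_nodes])
    charge[bad_owner, ] <- 0
    charge[invalid_nodes, ] <- 0
  }
  chir_m <- matrix(0L, nrow(charge), ncol(charge))
  chir_m[abs(charge - 2 * pi) < charge_tol] <- 1L
  chir_m[abs(charge + 2 * pi) < charge_tol] <- -1L
  frames <- which(colSums(chir_m != 0L) > 0L)
  res <- lapply(frames, function(t) {
    d <- cluster_detections(mesh, chir_m[, t], adj)
    if (nrow(d)) cbind(frame = t, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    tibble::tibble(frame = integer(0), node = integer(0), chirality = integer(0))
  } else {
    tibble::as_tibble(out)
  }
}

#' Track phase singularities across frames
#'
#' Greedy nearest-neighbor linking of per-frame detections: a detection
#' joins the open track of matching chirality whose last position is within
#' the geodesic `linking_radius`; gaps up to `max_gap` frames are tolerated.
#' A finished track is kept only if it persisted for at least
#' `min_rotations` full rotations at the local dominant frequency of its
#' core.
#'
#' @param detections tibble from [detect_sps()] (`frame`, `node`,
#'   `chirality`), time-ordered
#' @param mesh a `tri_mesh`
#' @param df a `df_map` or per-node DF vector (Hz), for the rotation-count
#'   persistence rule
#' @param fs frame rate, Hz
#' @param linking_radius_mm geodesic linking radius (default 10 mm)
#' @param min_rotations persistence threshold in rotations (default 2)
#' @param max_gap tolerated missing frames inside a track (default 2)
#' @param dist optional precomputed N x N geodesic distance matrix
#' @return list of `sp_track` objects: `frames`, `nodes`, `chirality`,
#'   `start`, `end`, `duration_s`, `core_node` (modal node), `core_df`
#' @export
track_sps <- function(detections, mesh, df, fs, linking_radius_mm = 10,
                      min_rotations = 2, max_gap = 2, dist = NULL) {
  dfv <- if (inherits(df, "df_map")) df$df else df
  if (nrow(detections) == 0L) return(list())
  if (is.null(dist)) dist <- geodesic_distance(mesh)
  det <- detections[order(detections$frame), ]
  open <- list()   # each: list(frames, nodes, chir, last_frame)
  done <- list()
  for (fr in unique(det$frame)) {
    rows <- which(det$frame == fr)
    # expire stale tracks
    if (length(open)) {
      stale <- vapply(open, function(tr) fr - tr$last_frame > max_gap + 1L,
                      logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    unmatched <- rows
    if (length(open)) {
      # greedy: repeatedly take the closest (track, detection) pair in radius
      repeat {
        if (!length(unmatched) || !length(open)) break
        dm <- matrix(Inf, length(open), length(unmatched))
        for (i in seq_along(open)) {
          tr <- open[[i]]
          if (tr$last_frame == fr) next   # already extended this frame
          for (j in seq_along(unmatched)) {
            if (det$chirality[unmatched[j]] == tr$chir) {
              dm[i, j] <- dist[tr$nodes[length(tr$nodes)],
                               det$node[unmatched[j]]]
            }
          }
        }
        best <- which.min(dm)
        if (!length(best) || !is.finite(dm[best]) ||
            dm[best] > linking_radius_mm) break
        i <- (best - 1L) %% length(open) + 1L
        j <- (best - 1L) %/% length(open) + 1L
        open[[i]]$frames <- c(open[[i]]$frames, fr)
        open[[i]]$nodes <- c(open[[i]]$nodes, det$node[unmatched[j]])
        open[[i]]$last_frame <- fr
        unmatched <- unmatched[-j]
      }
    }
    for (j in unmatched) {
      open[[length(open) + 1L]] <- list(frames = fr, nodes = det$node[j],
                                        chir = det$chirality[j],
                                        last_frame = fr)
    }
  }
  done <- c(done, open)
  tracks <- lapply(done, function(tr) {
    core <- as.integer(names(which.max(table(tr$nodes))))
    core_df <- dfv[core]
    duration <- (tr$frames[length(tr$frames)] - tr$frames[1] + 1L) / fs
    structure(list(frames = tr$frames, nodes = tr$nodes,
                   chirality = tr$chir,
                   start = tr$frames[1], end = tr$frames[length(tr$frames)],
                   duration_s = duration, core_node = core, core_df = core_df),
              class = "sp_track")
  })
  keep <- vapply(tracks, function(tr) {
    !is.na(tr$core_df) && tr$duration_s >= min_rotations / tr$core_df
  }, logical(1))
  tracks[keep]
}

#' Spatial mass function of singularity location
#'
#' Normalized spatial histogram of all per-frame SP locations over the kept
#' tracks: `p(n)` is the probability of finding the singularity at node `n`
#' during the observation window.
#'
#' @param tracks list of `sp_track` (from [track_sps()])
#' @param n_nodes mesh node count
#' @return an `smf`: list with `p` (length N, sums to 1) and `no_sp` flag
#'   (`TRUE`, with all-zero `p`, when no SP was kept)
#' @export
sp_smf <- function(tracks, n_nodes) {
  p <- numeric(n_nodes)
  nodes <- unlist(lapply(tracks, `[[`, "nodes"))
  if (length(nodes)) {
    if (any(nodes > n_nodes)) stop("track node index exceeds n_nodes")
    tab <- table(nodes)
    p[as.integer(names(tab))] <- as.numeric(tab) / length(nodes)
  }
  structure(list(p = p, no_sp = length(nodes) == 0L), class = "smf")
}

#' @export
print.smf <- function(x, ...) {
  if (x$no_sp) cat("<smf> no SP detected (zero mass)\n")
  else cat("<smf> support ", sum(x$p > 0), " / ", length(x$p),
           " nodes, mode at node ", which.max(x$p), "\n", sep = "")
  invisible(x)
}

#' Dominant singularity point
#'
#' Among kept tracks, the one whose core sits in the highest-DF area (ties:
#' longest duration, then earliest start); `NULL` when no track exists —
#' the "no SP detected" outcome.
#'
#' @param tracks list of `sp_track`
#' @param df a `df_map` or per-node DF vector
#' @return the dominant `sp_track`, or `NULL`
#' @export
dominant_sp <- function(tracks, df) {
  if (!length(tracks)) return(NULL)
  dfv <- if (inherits(df, "df_map")) df$df else df
  score <- vapply(tracks, function(tr) mean(dfv[tr$nodes], na.rm = TRUE),
                  numeric(1))
  dur <- vapply(tracks, `[[`, numeric(1), "duration_s")
  st <- vapply(tracks, `[[`, numeric(1), "start")
  ord <- order(-score, -dur, st)
  tracks[[ord[1]]]
}
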