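test_that("Welch PSD localizes tones, is flat for white noise, and conserves power", {
  fs <- 500
  tt <- seq(0, 8, by = 1 / fs)[-1]
  w <- welch_psd(sin(2 * pi * 6 * tt), fs = fs)
  expect_lte(abs(w$freq[which.max(w$psd)] - 6), w$freq[2] - w$freq[1])
  expect_lte(w$freq[2] - w$freq[1], 0.1)
  set.seed(21)
  x <- rnorm(fs * 60)
  wn <- welch_psd(x, fs = fs)
  band <- wn$freq > 1 & wn$freq < 50
  # averaged over 1-Hz bins the spectrum is flat
  bins <- cut(wn$freq[band], breaks = seq(1, 50, by = 1))
  bp <- tapply(wn$psd[band], bins, mean)
  expect_lt(max(bp) / min(bp), 3)
  # integral of the PSD recovers the variance
  pow <- sum(wn$psd) * (wn$freq[2] - wn$freq[1])
  expect_lt(abs(pow - stats::var(x)) / stats::var(x), 0.05)
  expect_error(welch_psd(rnorm(100), fs = fs), "window")
})

test_that("dominant frequency applies the harmonic-discard rule", {
  fs <- 500
  tt <- seq(0, 8, by = 1 / fs)[-1]
  w <- welch_psd(sin(2 * pi * 7 * tt), fs = fs)
  expect_equal(dominant_frequency(w$psd, w$freq), 7, tolerance = 0.051)
  # 3.5 Hz fundamental with a stronger 7 Hz harmonic: the harmonic is
  # discarded because a >= 30% peak sits at half its frequency
  x <- sin(2 * pi * 3.5 * tt) + sqrt(2) * sin(2 * pi * 7 * tt)
  w2 <- welch_psd(x, fs = fs)
  expect_equal(dominant_frequency(w2$psd, w2$freq), 3.5, tolerance = 0.051)
  # no peak in band -> NA sentinel
  slow <- welch_psd(sin(2 * pi * 1 * tt), fs = fs)
  expect_true(is.na(dominant_frequency(slow$psd, slow$freq, band = c(3, 15))))
  # SAF phantom fast region recovers the rotor rate
  saf <- test_phantom("SAF")
  dfm <- df_map(saf$field, band = c(3, 15))
  expect_equal(as.numeric(names(which.max(table(dfm$df[saf$region_nodes])))),
               7.3, tolerance = 0.051)
})

test_that("phase maps have the analytic-signal properties", {
  fs <- 500
  tt <- seq(0, 8, by = 1 / fs)[-1]
  f <- 6
  X <- rbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt),
             3 * cos(2 * pi * f * tt))
  pm <- phase_map(potential_field(X, fs), rep(f, 3))
  trim <- 500:(length(tt) - 500)
  # unwrapped slope = 2 pi f within 1%
  dph <- ecgibench:::wrap_phase(diff(pm$phase[1, trim]))
  expect_lt(abs(mean(dph) * fs - 2 * pi * f) / (2 * pi * f), 0.01)
  # sine lags cosine by pi/2
  dd <- ecgibench:::wrap_phase(pm$phase[1, trim] - pm$phase[2, trim])
  expect_lt(abs(abs(mean(dd)) - pi / 2), 0.02)
  # phase is amplitude-invariant (up to filter round-off)
  dd3 <- ecgibench:::wrap_phase(pm$phase[3, trim] - pm$phase[1, trim])
  expect_lt(max(abs(dd3)), 1e-3)
})

test_that("singularity detection sees vortices and ignores plane waves", {
  disk <- disk_mesh()
  tt <- seq(0, 0.5, by = 1 / 500)
  # plane wave: no charge anywhere
  s <- disk$vertices[, 1]
  plane <- ecgibench:::wrap_phase(outer(rep(1, disk$n_vertices), 2 * pi * 7 * tt) -
                                    outer(2 * pi * (s - min(s)) / diff(range(s)), rep(1, length(tt))))
  expect_equal(nrow(detect_sps(disk, plane)), 0L)
  # vortex at the center: exactly one SP per frame at/next to the center
  ph <- vortex_phase(disk, c(0, 0), tt)
  det <- detect_sps(disk, ph)
  per_frame <- table(factor(det$frame, levels = seq_along(tt)))
  expect_gte(mean(per_frame == 1), 0.95)
  d2c <- sqrt(rowSums(disk$vertices[det$node, , drop = FALSE]^2))
  edge_max <- max(mesh_edges(disk)$length)
  expect_gte(mean(d2c <= edge_max), 0.95)
  # negating the phase flips every chirality
  det_neg <- detect_sps(disk, -ph)
  expect_equal(nrow(det_neg), nrow(det))
  merged <- merge(as.data.frame(det), as.data.frame(det_neg),
                  by = c("frame", "node"))
  expect_true(all(merged$chirality.x == -merged$chirality.y))
})

test_that("track persistence, linking and the SMF obey their rules", {
  m <- test_atria()
  D <- geodesic_distance(m)
  dfv <- rep(7, m$n_vertices)
  fs <- 100
  mk <- function(frames, node, chir = 1L) {
    tibble::tibble(frame = frames, node = node, chirality = chir)
  }
  # 3 rotations at 7 Hz needs > 2/7 s = 0.286 s -> 43 frames at 100 Hz
  det3 <- mk(1:45, 10L)
  tr <- track_sps(det3, m, dfv, fs, dist = D)
  expect_length(tr, 1)
  # 1 rotation only -> discarded
  det1 <- mk(1:12, 10L)
  expect_length(track_sps(det1, m, dfv, fs, dist = D), 0)
  # two simultaneous distant SPs -> two tracks
  far <- which(D[10, ] > 40)[1]
  det2 <- dplyr::bind_rows(mk(1:45, 10L), mk(1:45, far))
  tr2 <- track_sps(det2, m, dfv, fs, dist = D)
  expect_length(tr2, 2)
  # SMF: counts normalized over kept tracks
  smf1 <- sp_smf(tr, m$n_vertices)
  expect_equal(smf1$p[10], 1)
  expect_equal(sum(smf1$p), 1)
  smf2 <- sp_smf(tr2, m$n_vertices)
  expect_equal(smf2$p[c(10, far)], c(0.5, 0.5))
  none <- sp_smf(list(), m$n_vertices)
  expect_true(none$no_sp)
  expect_equal(sum(none$p), 0)
})

test_that("the dominant SP is the one in the fastest region", {
  m <- test_atria()
  D <- geodesic_distance(m)
  fs <- 100
  dfv <- rep(5, m$n_vertices)
  fast <- which(D[10, ] > 40)[1]
  dfv[fast] <- 7
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:60, node = 10L, chirality = 1L),
    tibble::tibble(frame = 1:45, node = fast, chirality = -1L))
  tr <- track_sps(det, m, dfv, fs, dist = D)
  expect_length(tr, 2)
  expect_equal(dominant_sp(tr, dfv)$core_node, fast)
  expect_null(dominant_sp(list(), dfv))
  # single track is returned as-is
  expect_equal(dominant_sp(tr[1], dfv)$core_node, tr[[1]]$core_node)
})
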