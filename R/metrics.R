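#' Relative difference measurement star (RDMS)
#'
#' Euclidean distance between the unit-normalized signals,
#' `|| x/||x|| - xhat/||xhat|| ||_2`: 0 for proportional vectors, sqrt(2)
#' for orthogonal ones, 2 for antiparallel ones.
#'
#' @param x,x_hat numeric vectors (both nonzero)
#' @return value in \[0, 2\]
#' @export
rdms <- function(x, x_hat) {
  nx <- sqrt(sum(x^2)); nh <- sqrt(sum(x_hat^2))
  if (nx == 0 || nh == 0) stop("RDMS is undefined for a zero vector")
  sqrt(sum((x / nx - x_hat / nh)^2))
}

#' Pearson correlation coefficient
#' @param x,x_hat numeric vectors (both non-constant)
#' @return CC in \[-1, 1\], or `NA_real_` for constant input
#' @export
correlation <- function(x, x_hat) {
  if (stats::sd(x) == 0 || stats::sd(x_hat) == 0) return(NA_real_)
  stats::cor(x, x_hat)
}

#' Potential reconstruction metrics (CC and RDMS)
#'
#' Temporal mode (the default): CC and RDMS per node over all time
#' instants, summarized as mean and standard deviation across nodes.
#' Spatial mode: per instant over nodes, summarized across instants. The
#' temporal version is the more stable of the two and is what the summary
#' reports.
#'
#' @param X,X_hat true and estimated fields (`potential_field` or matrix,
#'   equal shapes)
#' @param mode `"temporal"` or `"spatial"`
#' @return a `potential_metrics` object; [tidy()] returns the per-unit
#'   values, [glance()] the mean/sd summary row
#' @export
potential_metrics <- function(X, X_hat, mode = c("temporal", "spatial")) {
  mode <- match.arg(mode)
  Xm <- if (inherits(X, "potential_field")) X$values else as.matrix(X)
  Xh <- if (inherits(X_hat, "potential_field")) X_hat$values else as.matrix(X_hat)
  if (!all(dim(Xm) == dim(Xh))) stop("X and X_hat must have equal shapes")
  if (mode == "spatial") { Xm <- t(Xm); Xh <- t(Xh) }
  cc <- vapply(seq_len(nrow(Xm)), function(i) correlation(Xm[i, ], Xh[i, ]),
               numeric(1))
  rd <- vapply(seq_len(nrow(Xm)), function(i) {
    if (all(Xm[i, ] == 0) || all(Xh[i, ] == 0)) NA_real_ else rdms(Xm[i, ], Xh[i, ])
  }, numeric(1))
  structure(
    list(per_unit = tibble::tibble(unit = seq_len(nrow(Xm)), cc = cc, rdms = rd),
         mode = mode),
    class = "potential_metrics"
  )
}

#' @export
print.potential_metrics <- function(x, ...) {
  g <- glance(x)
  cat("<potential_metrics> (", x$mode, ") CC ", round(g$cc_mean, 3), " +/- ",
      round(g$cc_sd, 3), ", RDMS ", round(g$rdms_mean, 3), " +/- ",
      round(g$rdms_sd, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname potential_metrics
#' @param x a `potential_metrics` object
#' @param ... unused
#' @method tidy potential_metrics
#' @export
tidy.potential_metrics <- function(x, ...) x$per_unit

#' @rdname potential_metrics
#' @method glance potential_metrics
#' @export
glance.potential_metrics <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    cc_mean = mean(x$per_unit$cc, na.rm = TRUE),
    cc_sd = stats::sd(x$per_unit$cc, na.rm = TRUE),
    rdms_mean = mean(x$per_unit$rdms, na.rm = TRUE),
    rdms_sd = stats::sd(x$per_unit$rdms, na.rm = TRUE)
  )
}

#' Relative absolute error of a dominant-frequency map
#'
#' `RAE(%) = (100/N) sum |F_n - Fhat_n| / F_n` over nodes with a positive
#' true DF; nodes with `NA` in either map, or a zero true DF, are excluded
#' with a warning.
#'
#' @param F,F_hat true and estimated DF (per-node vectors or `df_map`s)
#' @return percent error (>= 0)
#' @export
rae <- function(F, F_hat) {
  Fv <- if (inherits(F, "df_map")) F$df else F
  Fh <- if (inherits(F_hat, "df_map")) F_hat$df else F_hat
  if (length(Fv) != length(Fh)) stop("DF maps must have equal length")
  ok <- !is.na(Fv) & !is.na(Fh)
  zero <- ok & Fv == 0
  if (any(zero)) {
    warning(sum(zero), " node(s) with zero true DF excluded")
    ok <- ok & !zero
  }
  if (!any(ok)) stop("no nodes with valid DF in both maps")
  100 * mean(abs(Fv[ok] - Fh[ok]) / Fv[ok])
}

smf_p <- function(p) if (inherits(p, "smf")) p$p else p

#' Weighted under-estimation indicator (WUI)
#'
#' Percentage of the true SP region missed by the estimate, with each node
#' weighted by its true probability mass times its surface area:
#' `100 * sum_FN p A / (sum_FN p A + sum_TP p A)`, where FN are true-support
#' nodes outside the estimated support and TP the shared support.
#'
#' @param p,p_hat true and estimated SMFs (`smf` objects or probability
#'   vectors)
#' @param areas per-node areas from [node_areas()]
#' @param eps support threshold; mass `> eps` counts as support (default 0,
#'   exact non-zero support)
#' @return percent in \[0, 100\], or `NA_real_` when the true support is
#'   empty
#' @export
wui <- function(p, p_hat, areas, eps = 0) {
  p <- smf_p(p); ph <- smf_p(p_hat)
  sup <- p > eps; suph <- ph > eps
  if (!any(sup)) return(NA_real_)
  fn <- sup & !suph
  tp <- sup & suph
  denom <- sum(p[fn] * areas[fn]) + sum(p[tp] * areas[tp])
  if (denom == 0) return(NA_real_)
  100 * sum(p[fn] * areas[fn]) / denom
}

#' Weighted over-estimation indicator (WOI)
#'
#' Percentage of the estimated SP region that is spurious, weighted by the
#' estimated mass and node area:
#' `100 * sum_FP phat A / (sum_FP phat A + sum_TP phat A)`.
#'
#' @inheritParams wui
#' @return percent in \[0, 100\], or `NA_real_` when the estimated support
#'   is empty
#' @export
woi <- function(p, p_hat, areas, eps = 0) {
  p <- smf_p(p); ph <- smf_p(p_hat)
  sup <- p > eps; suph <- ph > eps
  if (!any(suph)) return(NA_real_)
  fp <- suph & !sup
  tp <- sup & suph
  denom <- sum(ph[fp] * areas[fp]) + sum(ph[tp] * areas[tp])
  if (denom == 0) return(NA_real_)
  100 * sum(ph[fp] * areas[fp]) / denom
}

#' Correlation between spatial mass functions
#' @inheritParams wui
#' @return Pearson CC of the two mass vectors, or `NA_real_` if either is
#'   constant
#' @export
cc_smf <- function(p, p_hat) {
  correlation(smf_p(p), smf_p(p_hat))
}

#' Geodesic mode distance between SMFs
#'
#' Dijkstra distance between the modes (argmax nodes, ties toward the
#' smallest index) of the true and estimated SMFs; complements the
#' support-overlap metrics when the two SMFs are near but disjoint.
#'
#' @inheritParams wui
#' @param mesh the `tri_mesh` both SMFs live on
#' @return distance in mm, or `NA_real_` when either SMF is all-zero
#' @export
mode_distance <- function(p, p_hat, mesh) {
  pv <- smf_p(p); ph <- smf_p(p_hat)
  if (all(pv == 0) || all(ph == 0)) return(NA_real_)
  m1 <- which.max(pv)   # which.max already takes the smallest index on ties
  m2 <- which.max(ph)
  geodesic_distance(mesh, m1, m2)
}

#' Two-sample Wilcoxon comparison
#'
#' Rank-sum test of equal medians (two-sided), as used to compare metric
#' distributions between solvers.
#'
#' @param sample_a,sample_b numeric samples
#' @param alpha significance level (default 0.05)
#' @return list with `p_value`, `significant`; degenerate all-tied input
#'   returns `p_value = NA` and `significant = FALSE`
#' @export
wilcoxon_compare <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("samples must be nonempty")
  }
  if (length(unique(c(sample_a, sample_b))) == 1L) {
    return(list(p_value = NA_real_, significant = FALSE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = FALSE)$p.value
  )
  list(p_value = p, significant = is.finite(p) && p < alpha)
}
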