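#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mesh_projection <- function(mesh) {
  v <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices), `-`)
  r <- sqrt(rowSums(v^2))
  tibble::tibble(
    node = seq_len(nrow(v)),
    lon = atan2(v[, 2], v[, 1]),
    lat = asin(pmin(1, pmax(-1, v[, 3] / r)))
  )
}

#' Plot a dominant-frequency map
#'
#' Flattens the mesh to a longitude/latitude projection about its centroid
#' and colors each node by its DF; a quick-look companion to the DF maps of
#' a benchmark run.
#'
#' @param object a `df_map`
#' @param mesh the `tri_mesh` the map lives on
#' @param ... unused
#' @return a ggplot
#' @method autoplot df_map
#' @export
autoplot.df_map <- function(object, mesh, ...) {
  d <- mesh_projection(mesh)
  d$df <- object$df
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, colour = .data$df)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "DF (Hz)") +
    ggplot2::labs(x = "longitude (rad)", y = "latitude (rad)",
                  title = "Dominant frequency map") +
    ggplot2::theme_minimal()
}

#' Plot a spatial mass function of singularity location
#'
#' @param object an `smf`
#' @param mesh the `tri_mesh`
#' @param ... unused
#' @return a ggplot
#' @method autoplot smf
#' @export
autoplot.smf <- function(object, mesh, ...) {
  d <- mesh_projection(mesh)
  d$p <- object$p
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, colour = .data$p)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "p(n)") +
    ggplot2::labs(x = "longitude (rad)", y = "latitude (rad)",
                  title = "SP spatial mass function") +
    ggplot2::theme_minimal()
}

#' Plot benchmark results
#'
#' One panel per metric, solvers on the x axis, one box per (solver, model)
#' over seeds and SNRs — the summary view used to compare regularization
#' methods.
#'
#' @param object an `ecgi_benchmark` tibble from [run_benchmark()]
#' @param metrics metrics to show (default: all except the sd companions)
#' @param ... unused
#' @return a ggplot
#' @method autoplot ecgi_benchmark
#' @export
autoplot.ecgi_benchmark <- function(object,
                                    metrics = setdiff(unique(object$metric),
                                                      c("cc_sd", "rdms_sd")),
                                    ...) {
  d <- dplyr::filter(object, .data$metric %in% metrics, .data$status == "ok")
  ggplot2::ggplot(d, ggplot2::aes(.data$solver, .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Summarize a benchmark over seeds
#'
#' @param x an `ecgi_benchmark`
#' @param ... unused
#' @return tibble with mean and sd of each metric per (solver, model, SNR)
#' @method tidy ecgi_benchmark
#' @export
tidy.ecgi_benchmark <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(dplyr::filter(x, .data$status == "ok"),
                    .data$solver, .data$model, .data$snr_db, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' @rdname tidy.ecgi_benchmark
#' @method glance ecgi_benchmark
#' @export
glance.ecgi_benchmark <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_solvers = length(unique(x$solver)),
    n_models = length(unique(x$model)),
    n_snr = length(unique(x$snr_db)),
    n_seeds = length(unique(x$seed)),
    n_failed = sum(x$status != "ok"),
    duration_s = if (is.null(cfg)) NA_real_ else cfg$duration_s
  )
}

#' @importFrom rlang .data
NULL
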