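#' The solver registry
#'
#' Names the fourteen reconstruction methods exactly as benchmark configs
#' refer to them: six Tikhonov variants `Tik-<m><o>` (`m` = `g`lobal or
#' `i`nstantaneous L-curve parameter, `o` = order 0/1/2), three truncated-SVD
#' orders `TSVD-0/1/2`, `DSVD`, `TV`, `Bayes`, `GS` (Greensite with
#' first-order Tikhonov) and `GMRES`.
#'
#' @return a tibble with columns `name`, `family`, `order`, `lambda_mode`
#' @export
solver_registry <- function() {
  tibble::tribble(
    ~name,     ~family,     ~order, ~lambda_mode,
    "Tik-g0",  "tikhonov",  0L,     "global",
    "Tik-g1",  "tikhonov",  1L,     "global",
    "Tik-g2",  "tikhonov",  2L,     "global",
    "Tik-i0",  "tikhonov",  0L,     "instantaneous",
    "Tik-i1",  "tikhonov",  1L,     "instantaneous",
    "Tik-i2",  "tikhonov",  2L,     "instantaneous",
    "TSVD-0",  "tsvd",      0L,     "lcurve_k",
    "TSVD-1",  "tsvd",      1L,     "lcurve_k",
    "TSVD-2",  "tsvd",      2L,     "lcurve_k",
    "DSVD",    "dsvd",      0L,     "global",
    "TV",      "tv",        1L,     "global",
    "Bayes",   "bayes",     NA_integer_, "none",
    "GS",      "greensite", 1L,     "per_component",
    "GMRES",   "gmres",     NA_integer_, "iterations"
  )
}

#' Precompute solver decompositions for a transfer matrix on a mesh
#'
#' Factorizations (SVD for order 0, GSVD for orders 1 and 2) are shared by
#' every solver that needs them; building them once per benchmark cell is
#' what keeps the grid affordable.
#'
#' @param A matrix or `transfer_matrix`
#' @param mesh atrial `tri_mesh` (needed for orders 1 and 2)
#' @param orders which operator orders to prepare
#' @return list with `A`, `operators`, `decs` keyed by order
#' @export
solver_context <- function(A, mesh = NULL, orders = 0:2) {
  Am <- if (inherits(A, "transfer_matrix")) A$entries else A
  ops <- list(); decs <- list()
  for (o in orders) {
    if (o > 0 && is.null(mesh)) next
    op <- if (o == 0) NULL else regularization_operator(mesh, o)
    ops[[as.character(o)]] <- op
    decs[[as.character(o)]] <- reg_decomposition(Am, op)
  }
  list(A = Am, operators = ops, decs = decs, mesh = mesh)
}

#' Reconstruct epicardial potentials with a named solver
#'
#' Single entry point over the method registry: picks the regularization
#' operator, selects the parameter (L-curve per instant or global, discrete
#' L-curve over the truncation level, fixed iteration budget, or the
#' supplied prior for Bayes) and returns the reconstruction with its
#' diagnostics.
#'
#' @param A matrix or `transfer_matrix` (M x N)
#' @param Y torso measurements: `potential_field` or M x T matrix
#' @param method a name from [solver_registry()]
#' @param mesh atrial `tri_mesh` (required for order-1/2 operators)
#' @param context optional [solver_context()] to reuse decompositions
#' @param lambda optional fixed regularization parameter (skips selection)
#' @param C_x,C_n prior and noise covariances (Bayes only); `C_n = NULL`
#'   defaults to `sigma_n^2 I` with `sigma_n2` (required then)
#' @param sigma_n2 noise variance used for the default `C_n`
#' @param k truncation level (TSVD) or temporal components (GS); `NULL`
#'   selects automatically
#' @param max_iter GMRES iteration budget (default 30) / TV IRLS cap
#' @param n_lambda L-curve grid size
#' @return an `ecgi_solution`: list with `estimate` (`potential_field` or
#'   matrix matching `Y`), `method`, `lambda`, `diagnostics`
#' @export
ecgi_solve <- function(A, Y, method, mesh = NULL, context = NULL,
                       lambda = NULL, C_x = NULL, C_n = NULL, sigma_n2 = NULL,
                       k = NULL, max_iter = 30, n_lambda = 60) {
  reg <- solver_registry()
  if (!method %in% reg$name) {
    stop("unknown solver \"", method, "\"; see solver_registry()")
  }
  row <- reg[reg$name == method, ]
  Am <- if (inherits(A, "transfer_matrix")) A$entries else A
  is_field <- inherits(Y, "potential_field")
  Ym <- if (is_field) Y$values else as.matrix(Y)

  get_dec <- function(order) {
    key <- as.character(order)
    if (!is.null(context) && !is.null(context$decs[[key]])) {
      return(list(dec = context$decs[[key]], op = context$operators[[key]]))
    }
    op <- if (order == 0) NULL else {
      if (is.null(mesh)) stop("`mesh` is required for order-", order, " operators")
      regularization_operator(mesh, order)
    }
    list(dec = reg_decomposition(Am, op), op = op)
  }

  lam <- lambda
  diag <- list()
  Xhat <- switch(row$family,
    tikhonov = {
      d <- get_dec(row$order)
      if (is.null(lam)) {
        lam <- if (row$lambda_mode == "global") {
          lcurve_lambda(Am, d$op, Ym, n_points = n_lambda, dec = d$dec)$lambda
        } else {
          lcurve_lambda_cols(d$dec, Ym, n_points = n_lambda)
        }
      }
      gfilter_apply(d$dec, Ym, lam)
    },
    tsvd = {
      d <- get_dec(row$order)
      if (is.null(k)) k <- lcurve_tsvd_k(d$dec, Ym)
      diag$k <- k
      tsvd_higher_order(Am, d$op, Ym, k, dec = d$dec)
    },
    dsvd = {
      d <- get_dec(0L)
      if (is.null(lam)) {
        lam <- lcurve_lambda(Am, NULL, Ym, n_points = n_lambda,
                             filter = "dsvd", dec = d$dec)$lambda
      }
      gfilter_apply(d$dec, Ym, lam, filter = "dsvd")
    },
    tv = {
      d <- get_dec(1L)
      if (is.null(lam)) {
        lam <- lcurve_lambda(Am, d$op, Ym, n_points = n_lambda, dec = d$dec)$lambda
      }
      out <- matrix(0, ncol(Am), ncol(Ym))
      conv <- logical(ncol(Ym))
      for (t in seq_len(ncol(Ym))) {
        r <- tv_solve(Am, d$op, Ym[, t], lam, max_iter = max_iter)
        out[, t] <- r$x
        conv[t] <- r$converged
      }
      diag$converged <- conv
      out
    },
    bayes = {
      if (is.null(C_x)) stop("Bayes requires `C_x` (see estimate_prior_covariance)")
      if (is.null(C_n)) {
        if (is.null(sigma_n2)) stop("Bayes requires `C_n` or `sigma_n2`")
        C_n <- diag(sigma_n2, nrow(Am))
      }
      bayes_map(Am, C_x, C_n, Ym)
    },
    greensite = {
      d <- get_dec(1L)
      r <- greensite_solve(Am, d$op, Ym, k_temporal = k, lambda = lambda,
                           dec = d$dec)
      lam <- r$lambdas
      diag$k <- r$k
      r$X
    },
    gmres = {
      r <- gmres_batch(Am, Ym, max_iter = max_iter)
      diag$k_selected <- r$k_selected
      r$X
    }
  )
  Xhat <- as.matrix(Xhat)
  est <- if (is_field) potential_field(Xhat, Y$fs, Y$t0) else Xhat
  structure(list(estimate = est, method = method, lambda = lam,
                 diagnostics = diag),
            class = "ecgi_solution")
}

#' @export
print.ecgi_solution <- function(x, ...) {
  est <- if (inherits(x$estimate, "potential_field")) x$estimate$values else x$estimate
  cat("<ecgi_solution> ", x$method, ": ", nrow(est), " nodes x ", ncol(est),
      " samples", sep = "")
  if (!is.null(x$lambda)) {
    if (length(x$lambda) == 1L) cat(", lambda = ", signif(x$lambda, 4), sep = "")
    else cat(", per-instant lambda in [", signif(min(x$lambda), 3), ", ",
             signif(max(x$lambda), 3), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ECGI solution
#'
#' One row per time sample with the regularization parameter used for it
#' (constant for global modes) — convenient for plotting parameter traces.
#'
#' @param x an `ecgi_solution`
#' @param ... unused
#' @method tidy ecgi_solution
#' @export
tidy.ecgi_solution <- function(x, ...) {
  est <- if (inherits(x$estimate, "potential_field")) x$estimate$values else x$estimate
  T <- ncol(est)
  lam <- if (is.null(x$lambda)) NA_real_ else x$lambda
  tibble::tibble(
    sample = seq_len(T),
    lambda = if (length(lam) == T) lam else rep(lam[1], T),
    estimate_norm = sqrt(colSums(est^2))
  )
}

#' @rdname tidy.ecgi_solution
#' @method glance ecgi_solution
#' @export
glance.ecgi_solution <- function(x, ...) {
  est <- if (inherits(x$estimate, "potential_field")) x$estimate$values else x$estimate
  lam <- if (is.null(x$lambda)) NA_real_ else x$lambda
  tibble::tibble(
    method = x$method,
    n_nodes = nrow(est),
    n_samples = ncol(est),
    lambda_median = stats::median(lam),
    lambda_min = min(lam),
    lambda_max = max(lam)
  )
}
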