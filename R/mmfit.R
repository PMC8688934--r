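#' Fit an equivalent Michaelis-Menten law to a simulated flux curve
#'
#' Least-squares fit of `V * S / (Km + S)` to a flux-versus-substrate curve,
#' used to summarise the mechanistic transporter models by their equivalent
#' Vmax and Km. The fit is deterministic: starting values are Vmax0 = max
#' flux and Km0 = substrate at half-maximal flux.
#'
#' @param substrate substrate concentrations (mM); at least 3 distinct values.
#' @param flux fluxes at those concentrations (any consistent unit; the
#'   fitted Vmax inherits it). Negative values (net efflux at low cis
#'   substrate) are permitted and simply enter the least-squares objective.
#' @return Object of class `mm_fit` with components `v_max`, `k_m`, `rss`,
#'   `fitted`, `data`, and `range` (fitted substrate range).
#' @examples
#' s <- seq(1, 100, by = 5)
#' f <- 1 * s / (5 + s)
#' fit <- fit_michaelis_menten(s, f)
#' coef(fit)   # c(v_max = 1, k_m = 5)
#' @export
fit_michaelis_menten <- function(substrate, flux) {
  if (length(substrate) < 3 || length(unique(substrate)) < 3)
    stop("fit_michaelis_menten: need >= 3 distinct substrate values", call. = FALSE)
  if (length(substrate) != length(flux))
    stop("fit_michaelis_menten: substrate and flux lengths differ", call. = FALSE)
  if (any(substrate < 0))
    stop("fit_michaelis_menten: substrate values must be >= 0", call. = FALSE)
  vmax0 <- max(flux)
  if (vmax0 <= 0)
    stop("fit_michaelis_menten: flux curve has no positive branch", call. = FALSE)
  half <- which(flux >= vmax0 / 2)[1]
  km0 <- max(substrate[half], 1e-3)
  df <- data.frame(s = substrate, j = flux)
  fit <- tryCatch(
    stats::nls(j ~ v * s / (km + s), data = df,
               start = list(v = vmax0, km = km0),
               algorithm = "port", lower = c(v = 1e-12, km = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
  } else {
    # Gauss-Newton can fail when much of the curve is negative (strong trans
    # inhibition); fall back to a deterministic direct search on log-params.
    sse <- function(th) {
      v <- exp(th[1]); km <- exp(th[2])
      sum((df$j - v * df$s / (km + df$s))^2)
    }
    op <- stats::optim(c(log(vmax0), log(km0)), sse, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    op <- stats::optim(op$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    cf <- c(v = exp(op$par[1]), km = exp(op$par[2]))
  }
  if (any(cf <= 0) || any(!is.finite(cf)))
    stop("fit_michaelis_menten: non-positive parameter estimate", call. = FALSE)
  fitted <- cf[["v"]] * df$s / (cf[["km"]] + df$s)
  structure(list(v_max = cf[["v"]], k_m = cf[["km"]],
                 rss = sum((df$j - fitted)^2),
                 fitted = fitted,
                 data = df,
                 range = range(substrate)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g, Km = %.4g (RSS %.3g, fitted over %g-%g)\n",
              x$v_max, x$k_m, x$rss, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(v_max = object$v_max, k_m = object$k_m)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$s else
    if (is.data.frame(newdata)) newdata$s else newdata
  object$v_max * s / (object$k_m + s)
}

#' @export
residuals.mm_fit <- function(object, ...) object$data$j - object$fitted
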