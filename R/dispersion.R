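# dispersion: R1rho relaxation-dispersion analysis. Monoexponential spin-lock
# decays give R1rho per field; R2,eff is extracted with a separately measured
# R1; an F test decides between a flat profile (no exchange) and a
# fast-exchange on-resonance Lorentzian.

#' Fit a monoexponential spin-lock decay
#'
#' Least-squares fit of I(T) = I0 exp(-R1rho T) to intensities measured at a
#' ladder of spin-lock durations. The returned uncertainty is the standard
#' error from the fit covariance. Non-decaying data (fitted rate <= 0) are
#' returned with a warning flag rather than an error.
#'
#' @param durations_ms spin-lock durations in ms (>= 3 values).
#' @param intensities positive peak intensities, same length.
#' @return list with `r1rho` (per s), `sigma` (per s), `i0`, `warning`
#'   (logical: rate not positive or fit degenerate).
#' @export
fit_r1rho <- function(durations_ms, intensities) {
  if (length(durations_ms) < 3L || length(intensities) != length(durations_ms))
    stop("need >= 3 matched duration/intensity points")
  if (any(intensities <= 0)) stop("intensities must be positive")
  T_s <- durations_ms / 1000
  lf <- stats::lm(log(intensities) ~ T_s)
  r0 <- -unname(stats::coef(lf)[2])
  i0 <- exp(unname(stats::coef(lf)[1]))
  d <- data.frame(T_s = T_s, I = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ i0 * exp(-r * T_s), data = d,
                      start = list(i0 = i0, r = max(r0, 1e-3)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    se <- sqrt(diag(stats::vcov(lf)))[2]
    return(list(r1rho = r0, sigma = unname(se), i0 = i0, warning = r0 <= 0))
  }
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["r"], error = function(e) NA_real_)
  list(r1rho = unname(co["r"]), sigma = unname(se), i0 = unname(co["i0"]),
       warning = !is.finite(co["r"]) || co["r"] <= 0)
}

#' Extract R2,eff from R1rho and R1
#'
#' With tilt angle theta = atan(nu1 / Omega) (theta = 90 deg on resonance),
#' R1rho = R1 cos^2(theta) + R2,eff sin^2(theta), hence
#' R2,eff = (R1rho - R1 cos^2 theta) / sin^2 theta.
#'
#' @param r1rho rotating-frame rate, per s.
#' @param r1 longitudinal rate, per s.
#' @param nu1_khz spin-lock field strength, kHz.
#' @param offset_khz resonance offset Omega, kHz (0 = on resonance).
#' @return R2,eff in per s.
#' @export
r2eff_from_r1rho <- function(r1rho, r1, nu1_khz, offset_khz = 0) {
  if (nu1_khz <= 0) stop("nu1 must be positive")
  theta <- if (offset_khz == 0) pi / 2 else atan(nu1_khz / offset_khz)
  s2 <- sin(theta)^2
  if (s2 < 1e-12) stop("tilt angle ~ 0: spin lock has no transverse component")
  (r1rho - r1 * cos(theta)^2) / s2
}

#' Fit a relaxation-dispersion profile and test for exchange
#'
#' Weighted least squares of two nested models of R2,eff(nu1): a flat model
#' R2,eff = R2_0 (one parameter, no exchange) and a fast-exchange on-resonance
#' Lorentzian R2,eff = R2_0 + phi k_ex / (k_ex^2 + (2 pi nu1)^2)
#' (three parameters). F = ((RSS_flat - RSS_ex) / 2) / (RSS_ex / (n - 3)) with
#' p from F(2, n - 3); the exchange model is selected when p < `alpha_level`.
#'
#' @param curve data.frame with columns `nu1_khz`, `r2eff`, `sigma`
#'   (>= 4 distinct fields).
#' @param alpha_level F-test significance level (default 0.05).
#' @return list of class `dispersion_fit`: `model` ("exchange" or "flat"),
#'   `F`, `p`, `rss_flat`, `rss_ex`, `params` (named vector `r20`, `phi`
#'   (s^-2), `kex` (s^-1) for the exchange branch, plus `r20_flat`),
#'   `boundary` flag for degenerate exchange fits, `n`.
#' @export
fit_dispersion <- function(curve, alpha_level = 0.05) {
  need <- c("nu1_khz", "r2eff", "sigma")
  if (!all(need %in% names(curve))) stop("curve needs columns nu1_khz, r2eff, sigma")
  curve <- curve[stats::complete.cases(curve[, need]), ]
  if (length(unique(curve$nu1_khz)) < 4L)
    stop("need >= 4 distinct spin-lock fields for model selection")
  w <- 1 / curve$sigma^2
  n <- nrow(curve)
  omega1 <- 2 * pi * curve$nu1_khz * 1000   # rad/s
  r20_flat <- sum(w * curve$r2eff) / sum(w)
  rss_flat <- sum(w * (curve$r2eff - r20_flat)^2)

  # Exchange model parametrized as R2_0 + rex / (1 + (omega1 / kex)^2) with
  # rex = phi / kex. For fixed kex the model is linear in (R2_0, rex), so the
  # profile over a logarithmic kex grid (refined by golden-section search)
  # gives the global weighted least-squares optimum.
  wls_rss <- function(kex) {
    X <- cbind(1, 1 / (1 + (omega1 / kex)^2))
    fit <- stats::lm.wfit(X, curve$r2eff, w)
    list(rss = sum(w * fit$residuals^2), coef = fit$coefficients)
  }
  kex_grid <- 10^seq(2, 7, length.out = 26)
  prof <- vapply(kex_grid, function(k) wls_rss(k)$rss, 0)
  i <- which.min(prof)
  lo <- kex_grid[max(i - 1, 1)]; hi <- kex_grid[min(i + 1, length(kex_grid))]
  opt <- stats::optimize(function(lk) wls_rss(exp(lk))$rss, c(log(lo), log(hi)))
  kex_hat <- exp(opt$minimum)
  best_fit <- wls_rss(kex_hat)
  best <- list(par = c(unname(best_fit$coef[1]), unname(best_fit$coef[2]), kex_hat),
               rss = best_fit$rss,
               boundary = i == 1L || i == length(kex_grid) ||
                 best_fit$coef[2] < 0)
  rss_ex <- min(best$rss, rss_flat)  # nested models: never worse than flat
  Fstat <- ((rss_flat - rss_ex) / 2) / (rss_ex / (n - 3))
  p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  structure(list(
    model = if (p < alpha_level) "exchange" else "flat",
    F = Fstat, p = p, rss_flat = rss_flat, rss_ex = rss_ex,
    params = c(r20 = best$par[1], phi = best$par[2] * best$par[3],
               kex = best$par[3], r20_flat = r20_flat),
    boundary = best$boundary, n = n), class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("<dispersion_fit> model: ", x$model,
      sprintf("  (F = %.3g, p = %.3g, n = %d)\n", x$F, x$p, x$n), sep = "")
  cat(sprintf("  flat R2_0 = %.3g /s; exchange R2_0 = %.3g /s, phi = %.3g /s^2, kex = %.3g /s%s\n",
              x$params["r20_flat"], x$params["r20"], x$params["phi"], x$params["kex"],
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Full dispersion analysis of a spin-lock series
#'
#' Fits each spin-lock field's decay with [fit_r1rho()], converts to R2,eff
#' with [r2eff_from_r1rho()] using the supplied R1, and runs
#' [fit_dispersion()].
#'
#' @param series a `spin_lock_series` from [make_dispersion_dataset()] or a
#'   list with `points` (each with `nu1_khz`, `offset_khz`, `durations_ms`,
#'   `intensities`) and `r1` (per s).
#' @param alpha_level F-test significance level.
#' @return list with `curve` (data.frame nu1_khz, r2eff, sigma) and `fit`
#'   (a `dispersion_fit`).
#' @export
analyze_dispersion <- function(series, alpha_level = 0.05) {
  rows <- lapply(series$points, function(pt) {
    r <- fit_r1rho(pt$durations_ms, pt$intensities)
    off <- if (is.null(pt$offset_khz)) 0 else pt$offset_khz
    data.frame(nu1_khz = pt$nu1_khz,
               r2eff = r2eff_from_r1rho(r$r1rho, series$r1, pt$nu1_khz, off),
               sigma = r$sigma)
  })
  curve <- do.call(rbind, rows)
  list(curve = curve, fit = fit_dispersion(curve, alpha_level = alpha_level))
}
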