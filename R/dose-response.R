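#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + 10^(h * (log10(ec50) - log10(x))))`
#' on log10 concentration, i.e. the standard 4PL
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^h)` with Hill slope
#' `h > 0`. Direction is handled by curve orientation, not slope sign: for
#' `"ANTAGONIST"` the response falls with concentration and the midpoint is
#' reported as an IC50. Initialization is deterministic from data
#' quantiles (response extremes for the asymptotes, the concentration
#' nearest half-maximum for the midpoint, Hill slope 1), so the fit is a
#' pure function of the data. Replicates are fit unweighted.
#'
#' @param data Data frame with concentration and response columns.
#' @param conc,response Column names (default `"conc_M"`, `"response"`).
#' @param direction `"AGONIST"` (rising) or `"ANTAGONIST"` (falling).
#' @return An object of class `fourpl_fit`: list with `bottom`, `top`,
#'   `ec50`, `hill`, `se_ec50`, `log10_ec50`, `se_log10_ec50`,
#'   `residual_ss`, `converged`, `direction`, `n`, `conc_range`,
#'   `extrapolated`, `data`.
#' @export
#' @examples
#' d <- simulate_dose_response(0, 100, 1e-7, 1, dilution_series(1e-4), cv = 0)
#' fit <- fit_4pl(d)
#' fit$ec50
fit_4pl <- function(data, conc = "conc_M", response = "response",
                    direction = c("AGONIST", "ANTAGONIST")) {
  direction <- match.arg(direction)
  x <- as.numeric(data[[conc]])
  y <- as.numeric(data[[response]])
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(x)) < 5) {
    stop("4PL fit requires at least 5 distinct concentrations", call. = FALSE)
  }
  lx <- log10(x)
  sign_h <- if (direction == "AGONIST") 1 else -1

  # deterministic initialization from data quantiles
  by_conc <- tapply(y, lx, mean)
  lv <- as.numeric(names(by_conc))
  bottom0 <- min(by_conc); top0 <- max(by_conc)
  half <- (bottom0 + top0) / 2
  lec50_0 <- lv[which.min(abs(by_conc - half))]

  failed <- function(msg) {
    structure(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                   hill = NA_real_, se_ec50 = NA_real_,
                   log10_ec50 = NA_real_, se_log10_ec50 = NA_real_,
                   residual_ss = NA_real_, converged = FALSE,
                   direction = direction, n = length(x),
                   conc_range = range(x), extrapolated = NA,
                   message = msg,
                   data = tibble::tibble(conc_M = x, response = y)),
              class = "fourpl_fit")
  }
  if (stats::sd(y) == 0 || top0 == bottom0) {
    return(failed("constant response: no sigmoid to fit"))
  }

  model <- function(p, lxv) {
    h <- exp(p[["lh"]])  # Hill slope kept positive by log parameterization
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(sign_h * h * (p[["lec50"]] - lxv)))
  }
  # Levenberg-Marquardt on the residual function directly; robust to the
  # zero-residual (noiseless) limit
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(bottom = bottom0, top = top0, lec50 = lec50_0, lh = 0),
      fn = function(p) y - model(p, lx),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4 || !is.finite(fit$deviance)) {
    return(failed("nonlinear least squares did not converge"))
  }
  cf <- unlist(fit$par)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  ec50 <- 10^cf[["lec50"]]
  se_l <- unname(se[["lec50"]])
  # canonicalize so top >= bottom; flipping the orientation sign with the
  # asymptote swap leaves the fitted curve unchanged
  b <- unname(cf[["bottom"]]); t <- unname(cf[["top"]])
  pred_sign <- sign_h
  if (b > t) { tmp <- b; b <- t; t <- tmp; pred_sign <- -pred_sign }
  structure(list(
    bottom = b, top = t, pred_sign = pred_sign,
    ec50 = unname(ec50), hill = unname(exp(cf[["lh"]])),
    se_ec50 = ec50 * log(10) * se_l,      # delta method on log10 scale
    log10_ec50 = unname(cf[["lec50"]]), se_log10_ec50 = se_l,
    residual_ss = fit$deviance, converged = TRUE,
    direction = direction, n = length(x), conc_range = range(x),
    extrapolated = ec50 < min(x) || ec50 > max(x),
    message = NULL,
    data = tibble::tibble(conc_M = x, response = y)
  ), class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  label <- if (x$direction == "ANTAGONIST") "IC50" else "EC50"
  cat("Four-parameter logistic fit (", tolower(x$direction), ")\n", sep = "")
  if (!x$converged) {
    cat("  NOT converged: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  %s: %.4g M (SE %.2g), Hill %.3g\n", label, x$ec50,
              x$se_ec50, x$hill))
  cat(sprintf("  bottom %.4g, top %.4g, residual SS %.4g, n = %d%s\n",
              x$bottom, x$top, x$residual_ss, x$n,
              if (isTRUE(x$extrapolated)) " [midpoint extrapolated]" else ""))
  invisible(x)
}

#' Tidy a 4PL fit into one row per parameter
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill),
    std.error = c(NA_real_, NA_real_, x$se_ec50, NA_real_)
  )
}

#' One-row summary of a 4PL fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble with `ec50`, `hill`, `bottom`, `top`, `residual_ss`,
#'   `n`, `converged`, `extrapolated`.
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hill = x$hill, bottom = x$bottom,
                 top = x$top, residual_ss = x$residual_ss, n = x$n,
                 converged = x$converged, extrapolated = x$extrapolated)
}

#' Predict from a 4PL fit
#'
#' @param object A converged `fourpl_fit`.
#' @param conc Concentrations (molar) at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric responses.
#' @export
predict.fourpl_fit <- function(object, conc, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit", call. = FALSE)
  sign_h <- object$pred_sign %||% (if (object$direction == "AGONIST") 1 else -1)
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(sign_h * object$hill * (object$log10_ec50 - log10(conc))))
}

#' Plot a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot: points at the data, fitted curve on log10
#'   concentration, dashed line at the midpoint.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_M, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Response",
                  title = sprintf("4PL fit (%s)", tolower(object$direction)))
  if (object$converged) {
    grid <- exp(seq(log(min(d$conc_M)), log(max(d$conc_M)), length.out = 200))
    curve_df <- tibble::tibble(conc_M = grid,
                               response = predict(object, grid))
    p <- p +
      ggplot2::geom_line(data = curve_df, color = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = "dashed",
                          color = "grey40")
  }
  p
}

#' EC90 from a fitted curve
#'
#' The concentration producing 90% of the fitted span:
#' `EC90 = EC50 * 9^(1/hill)`. Used to choose the agonist concentration
#' that anchors the antagonist screens.
#'
#' @param fit A converged `fourpl_fit` (or a list with `ec50` and `hill`).
#' @return EC90 in molar.
#' @export
#' @examples
#' ec90_from_fit(list(ec50 = 1e-8, hill = 1, converged = TRUE))  # 9e-8
ec90_from_fit <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("EC90 requires a converged fit", call. = FALSE)
  }
  stopifnot(fit$hill > 0, fit$ec50 > 0)
  fit$ec50 * 9^(1 / fit$hill)
}

#' Average IC50 across time-point fits
#'
#' When a compound's IC50 is stable across post-addition read times, the
#' per-time-point fits are averaged. Unconverged fits are dropped with a
#' warning.
#'
#' @param fits List of `fourpl_fit` objects (>= 2).
#' @return Tibble with `mean_ic50`, `sd_ic50`, `n_fits`, `n_excluded`.
#' @export
ic50_table <- function(fits) {
  stopifnot(length(fits) >= 2)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warning(sum(!conv), " unconverged fit(s) excluded from IC50 averaging",
            call. = FALSE)
  }
  vals <- vapply(fits[conv], function(f) f$ec50, numeric(1))
  if (length(vals) == 0) stop("no converged fits to average", call. = FALSE)
  tibble::tibble(mean_ic50 = mean(vals),
                 sd_ic50 = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_fits = length(vals), n_excluded = sum(!conv))
}
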