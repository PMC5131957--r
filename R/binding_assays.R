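#' Construct a binding curve
#'
#' Concentration-response data from a saturation binding assay (e.g. ELISA
#' absorbance against protein concentration). Replicates are pooled for
#' fitting.
#'
#' @param concentration_nM Protein concentrations in nM, strictly positive.
#' @param response Response values (absorbance, arbitrary units), one per
#'   concentration entry.
#' @param replicate Optional replicate labels.
#' @param probe Probe label (e.g. \code{"TAT"}, \code{"CON"},
#'   \code{"CTG"}).
#' @return Data frame of class \code{binding_curve}.
#' @export
binding_curve <- function(concentration_nM, response, replicate = 1L,
                          probe = "probe") {
  stopifnot(length(concentration_nM) == length(response),
            all(is.finite(concentration_nM)), all(concentration_nM > 0),
            all(is.finite(response)))
  df <- data.frame(concentration_nM = concentration_nM,
                   response = response,
                   replicate = rep_len(replicate, length(response)))
  grid <- sort(unique(df$concentration_nM))
  if (length(grid) < 5L) {
    stop("need at least 5 distinct concentrations for fitting, got ",
         length(grid))
  }
  attr(df, "probe") <- probe
  class(df) <- c("binding_curve", "data.frame")
  df
}

.as_binding_curve <- function(curve) {
  if (inherits(curve, "binding_curve")) return(curve)
  stopifnot(is.data.frame(curve),
            all(c("concentration_nM", "response") %in% names(curve)))
  binding_curve(curve$concentration_nM, curve$response,
                if ("replicate" %in% names(curve)) curve$replicate else 1L)
}

# multi-start nonlinear least squares; Kd starts at min / geometric mean /
# max of the concentration grid
.fit_curve <- function(curve, model = c("hyperbolic", "hill"),
                       offset = FALSE) {
  model <- match.arg(model)
  curve <- .as_binding_curve(curve)
  p <- curve$concentration_nM
  y <- curve$response
  if (stats::sd(y) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    stop("degenerate input: responses are constant, no saturation to fit")
  }
  grid <- sort(unique(p))
  kd_starts <- c(min(grid), exp(mean(log(grid))), max(grid))
  bmax0 <- max(y)
  dat <- data.frame(p = p, y = y)
  fits <- list()
  for (kd0 in kd_starts) {
    start <- list(Bmax = bmax0, Kd = kd0)
    lower <- c(Bmax = 1e-9, Kd = 1e-9)
    upper <- c(Bmax = Inf, Kd = Inf)
    if (model == "hill") {
      start$n <- 1
      lower <- c(lower, n = 1e-3)
      upper <- c(upper, n = 6)
    }
    if (offset) {
      start$c0 <- 0
      lower <- c(lower, c0 = -Inf)
      upper <- c(upper, c0 = Inf)
    }
    form <- if (model == "hyperbolic") {
      if (offset) y ~ c0 + Bmax * p / (Kd + p)
      else y ~ Bmax * p / (Kd + p)
    } else {
      if (offset) y ~ c0 + Bmax * p^n / (Kd^n + p^n)
      else y ~ Bmax * p^n / (Kd^n + p^n)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) {
    stop("binding-curve fit did not converge from any start (model: ",
         model, ")")
  }
  dev <- vapply(fits, stats::deviance, numeric(1L))
  fits[[which.min(dev)]]
}

.kd_fit <- function(fit, model, curve, offset) {
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    rep(NA_real_, length(co))
  })
  structure(list(model = model,
                 Kd = unname(co["Kd"]), Bmax = unname(co["Bmax"]),
                 hill_n = if (model == "hill") unname(co["n"]) else NULL,
                 offset = if ("c0" %in% names(co)) unname(co["c0"]) else NULL,
                 residual_sum = stats::deviance(fit),
                 stderr_Kd = unname(se["Kd"]),
                 converged = TRUE,
                 probe = attr(curve, "probe"),
                 fit = fit, data = curve),
            class = "kd_fit")
}

#' Fit a saturation binding curve
#'
#' Unweighted least squares on pooled replicates, with multi-start
#' initialisation of Kd (minimum, geometric mean and maximum of the
#' concentration grid); the best converged start wins. The hyperbolic model
#' is \deqn{B([P]) = B_{max} [P] / (K_d + [P])} and the Hill model
#' \deqn{B([P]) = B_{max} [P]^n / (K_d^n + [P]^n)} with \eqn{n} constrained
#' to (0, 6]. A constant background offset can optionally be co-estimated
#' (\code{offset = TRUE}); blank subtraction is otherwise the caller's
#' responsibility. Non-convergence from every start is an error, never a
#' silent fallback.
#'
#' @param curve A [binding_curve] or data frame with columns
#'   \code{concentration_nM}, \code{response} (and optionally
#'   \code{replicate}).
#' @param model \code{"hyperbolic"} or \code{"hill"}.
#' @param offset Estimate a constant background term (default off).
#' @return An object of class \code{kd_fit} with elements \code{model},
#'   \code{Kd} (nM), \code{Bmax}, \code{hill_n} (Hill only),
#'   \code{residual_sum}, \code{stderr_Kd} and \code{converged}.
#' @examples
#' cv <- generate_binding_curve(kd = 0.75, noise_sd = 0, seed = 1)
#' fit_binding_curve(cv)
#' @export
fit_binding_curve <- function(curve, model = c("hyperbolic", "hill"),
                              offset = FALSE) {
  model <- match.arg(model)
  curve <- .as_binding_curve(curve)
  fit <- .fit_curve(curve, model, offset)
  .kd_fit(fit, model, curve, offset)
}

#' @rdname fit_binding_curve
#' @export
fit_hyperbolic <- function(curve, offset = FALSE) {
  fit_binding_curve(curve, model = "hyperbolic", offset = offset)
}

#' @rdname fit_binding_curve
#' @export
fit_hill <- function(curve, offset = FALSE) {
  fit_binding_curve(curve, model = "hill", offset = offset)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> %s model%s\n", x$model,
              if (!is.null(x$probe)) paste0(" (probe ", x$probe, ")") else ""))
  cat(sprintf("  Kd   = %.4g nM (stderr %.3g)\n", x$Kd, x$stderr_Kd))
  cat(sprintf("  Bmax = %.4g\n", x$Bmax))
  if (!is.null(x$hill_n)) cat(sprintf("  n    = %.4g\n", x$hill_n))
  if (!is.null(x$offset)) cat(sprintf("  c0   = %.4g\n", x$offset))
  cat(sprintf("  residual sum of squares = %.4g\n", x$residual_sum))
  invisible(x)
}

#' @method coef kd_fit
#' @export
coef.kd_fit <- function(object, ...) {
  out <- c(Kd = object$Kd, Bmax = object$Bmax)
  if (!is.null(object$hill_n)) out <- c(out, n = object$hill_n)
  if (!is.null(object$offset)) out <- c(out, c0 = object$offset)
  out
}

#' @method summary kd_fit
#' @export
summary.kd_fit <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("Saturation binding fit (%s model), %d observations\n",
              object$model, nrow(object$data)))
  print(s$coefficients)
  invisible(s)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$concentration_nM
       else if (is.data.frame(newdata)) newdata$concentration_nM
       else newdata
  c0 <- if (is.null(object$offset)) 0 else object$offset
  if (object$model == "hyperbolic") {
    c0 + object$Bmax * p / (object$Kd + p)
  } else {
    c0 + object$Bmax * p^object$hill_n /
      (object$Kd^object$hill_n + p^object$hill_n)
  }
}

#' @method residuals kd_fit
#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @method plot kd_fit
#' @export
plot.kd_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration_nM, d$response, log = "x",
                 xlab = "[protein] (nM)", ylab = "response", ...)
  pg <- exp(seq(log(min(d$concentration_nM)),
                log(max(d$concentration_nM)), length.out = 200))
  graphics::lines(pg, predict(x, pg))
  graphics::abline(v = x$Kd, lty = 2)
  invisible(x)
}

#' @export
simulate.kd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  noise <- stats::sd(residuals(object))
  grid <- sort(unique(object$data$concentration_nM))
  reps <- max(table(object$data$concentration_nM))
  lapply(seq_len(nsim), function(i) {
    generate_binding_curve(
      kd = object$Kd, bmax = object$Bmax,
      hill_n = if (is.null(object$hill_n)) 1 else object$hill_n,
      grid = grid, noise_sd = noise, replicates = reps,
      seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
}

#' EMSA fraction bound from free-band depletion
#'
#' Percent of DNA bound computed from the depletion of the free-DNA band
#' relative to the no-protein lane:
#' \code{100 * (1 - free / reference)}, clamped to [0, 100].
#'
#' @param free_intensity Free-band intensity (>= 0), vectorised.
#' @param free_intensity_no_protein Reference free-band intensity from the
#'   no-protein lane (> 0).
#' @return Percent bound in [0, 100].
#' @examples
#' fraction_bound(c(100, 50, 0), 100)  # 0, 50, 100
#' @export
fraction_bound <- function(free_intensity, free_intensity_no_protein) {
  if (!is.finite(free_intensity_no_protein) ||
      free_intensity_no_protein <= 0) {
    stop("reference (no-protein) free-band intensity must be positive")
  }
  if (any(free_intensity < 0)) stop("free-band intensity must be >= 0")
  pmin(pmax(100 * (1 - free_intensity / free_intensity_no_protein), 0), 100)
}

#' Construct an EMSA competition series
#'
#' Band intensities of the protein-CON complex relative to the no-competitor
#' lane, across competitor amounts; by construction the relative band at
#' amount 0 equals 1.
#'
#' @param competitor Competitor label.
#' @param amounts Competitor amounts (ng), >= 0.
#' @param relative_band Relative band intensities in [0, 1].
#' @return Data frame of class \code{competition_series}.
#' @export
competition_series <- function(competitor, amounts, relative_band) {
  stopifnot(length(amounts) == length(relative_band),
            all(amounts >= 0), all(relative_band >= 0),
            all(relative_band <= 1))
  if (any(amounts == 0) && any(abs(relative_band[amounts == 0] - 1) > 1e-9)) {
    stop("relative band at competitor amount 0 must equal 1")
  }
  df <- data.frame(competitor = competitor, amounts = amounts,
                   relative_band = relative_band, stringsAsFactors = FALSE)
  class(df) <- c("competition_series", "data.frame")
  df
}

#' Relative-affinity index of a competitor
#'
#' Mean relative band intensity over the non-zero competitor amounts; a
#' stronger competitor depletes the complex band more, so a lower index
#' means higher relative affinity. Rankings of competitors follow the
#' ascending index.
#'
#' @param series A [competition_series] (or data frame with \code{amounts}
#'   and \code{relative_band}).
#' @return Numeric index in [0, 1].
#' @examples
#' s <- competition_series("pPA50", c(0, 50, 100), c(1, 0.5, 0.25))
#' relative_affinity(s)  # 0.375
#' @export
relative_affinity <- function(series) {
  nz <- series$amounts > 0
  if (!any(nz)) stop("need at least one non-zero competitor amount")
  mean(series$relative_band[nz])
}

#' Construct a salt-stability series
#'
#' Percent bound as a function of KCl concentration.
#'
#' @param kcl_mM KCl concentrations in mM.
#' @param percent_bound Percent bound in [0, 100].
#' @return Data frame of class \code{salt_series}.
#' @export
salt_series <- function(kcl_mM, percent_bound) {
  stopifnot(length(kcl_mM) == length(percent_bound),
            all(percent_bound >= 0), all(percent_bound <= 100))
  df <- data.frame(kcl_mM = kcl_mM, percent_bound = percent_bound)
  class(df) <- c("salt_series", "data.frame")
  df
}

#' Construct an EMSA titration series
#'
#' Percent bound as a function of protein tetramer / DNA molar ratio.
#'
#' @param molar_ratios Protein tetramer / DNA molar ratios.
#' @param percent_bound Percent bound in [0, 100].
#' @return Data frame of class \code{titration_series}.
#' @export
titration_series <- function(molar_ratios, percent_bound) {
  stopifnot(length(molar_ratios) == length(percent_bound),
            all(percent_bound >= 0), all(percent_bound <= 100))
  df <- data.frame(molar_ratio = molar_ratios,
                   percent_bound = percent_bound)
  class(df) <- c("titration_series", "data.frame")
  df
}
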