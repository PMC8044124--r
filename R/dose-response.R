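#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of the standard viability model
#' \deqn{f(d) = bottom + (top - bottom) / (1 + (d / m)^h)}
#' on the log-dose axis, where \code{m} is the concentration at half-maximal
#' effect and \code{h > 0} the Hill slope (the curve decreases from
#' \code{top} toward \code{bottom} as dose grows). The fit is a deterministic
#' multi-start optimization: starts iterate, in fixed order, over Hill slopes
#' \{0.5, 1, 2, 4\} and midpoints spanning the geometric range of the doses;
#' each start is refined with BFGS and the lowest residual sum of squares
#' wins. The span is parameterized as \code{top = bottom + exp(s)} so
#' \code{bottom <= top} holds by construction.
#'
#' @param dose positive concentrations, at least 4 distinct values.
#' @param response viability fractions (finite; replicates allowed).
#' @param constrain fix \code{top = 1}, \code{bottom = 0} (two-parameter
#'   variant).
#' @return An object of class \code{logistic4} with components
#'   \code{coefficients} (top, bottom, hill, midpoint), \code{fitted.values},
#'   \code{residuals}, \code{rss}, \code{convergence} (logical), \code{dose},
#'   \code{response}, \code{constrained}. Supports \code{coef}, \code{print},
#'   \code{summary}, \code{predict}, \code{residuals}, \code{fitted} and
#'   \code{plot}.
#' @examples
#' d <- 10^seq(-3, 2, length.out = 8)
#' y <- 1 / (1 + (d / 0.5)^1.5)
#' fit <- fit_logistic4(d, y)
#' coef(fit)
#' inhibitory_concentration(fit, 0.5)  # equals the midpoint
#' @export
fit_logistic4 <- function(dose, response, constrain = FALSE) {
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("doses must be positive and finite", call. = FALSE)
  if (any(!is.finite(response)))
    stop("responses must be finite", call. = FALSE)
  if (length(dose) != length(response))
    stop("dose and response lengths differ", call. = FALSE)
  if (length(unique(dose)) < 4)
    stop("need at least 4 distinct doses", call. = FALSE)
  if (stats::var(response) == 0)
    stop("fit failure: constant responses are unidentifiable", call. = FALSE)

  ld <- log(dose)
  f4 <- function(p) {
    # p = (bottom, log span, log m, log h)
    bottom <- p[1]
    top <- bottom + exp(p[2])
    bottom + (top - bottom) / (1 + exp(exp(p[4]) * (ld - p[3])))
  }
  f2 <- function(p) 1 / (1 + exp(exp(p[2]) * (ld - p[1])))  # p = (log m, log h)
  sse4 <- function(p) sum((response - f4(p))^2)
  sse2 <- function(p) sum((response - f2(p))^2)

  h_grid <- c(0.5, 1, 2, 4)
  m_grid <- exp(seq(min(ld), max(ld), length.out = 5))
  bottom0 <- min(response)
  span0 <- max(max(response) - min(response), 1e-6)

  best <- NULL
  for (h0 in h_grid) {
    for (m0 in m_grid) {
      p0 <- if (constrain) c(log(m0), log(h0))
            else c(bottom0, log(span0), log(m0), log(h0))
      res <- tryCatch(
        stats::optim(p0, if (constrain) sse2 else sse4, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-15)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  if (is.null(best))
    stop("fit failure: no start converged", call. = FALSE)
  # polish the winner with a derivative-free pass (robust near zero residual)
  polish <- tryCatch(
    stats::optim(best$par, if (constrain) sse2 else sse4,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-15)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  p <- best$par
  cf <- if (constrain) {
    c(top = 1, bottom = 0, hill = exp(p[2]), midpoint = exp(p[1]))
  } else {
    c(top = p[1] + exp(p[2]), bottom = p[1], hill = exp(p[4]),
      midpoint = exp(p[3]))
  }
  fitted <- cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (dose / cf[["midpoint"]])^cf[["hill"]])
  converged <- is.finite(best$value) && best$convergence == 0

  structure(
    list(coefficients = cf, dose = dose, response = response,
         fitted.values = fitted, residuals = response - fitted,
         rss = best$value, convergence = converged, constrained = constrain),
    class = "logistic4"
  )
}

logistic4_curve <- function(cf, dose) {
  cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (dose / cf[["midpoint"]])^cf[["hill"]])
}

#' @export
print.logistic4 <- function(x, ...) {
  cat("four-parameter logistic dose-response fit",
      if (x$constrained) " (top = 1, bottom = 0 constrained)", "\n", sep = "")
  print(signif(x$coefficients, 6))
  cat(sprintf("RSS %.3g over %d points; converged: %s\n",
              x$rss, length(x$dose), x$convergence))
  invisible(x)
}

#' @export
coef.logistic4 <- function(object, ...) object$coefficients

#' @export
predict.logistic4 <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dose
       else if (is.list(newdata)) newdata$dose
       else newdata
  logistic4_curve(object$coefficients, d)
}

#' @export
residuals.logistic4 <- function(object, ...) object$residuals

#' @export
fitted.logistic4 <- function(object, ...) object$fitted.values

#' @export
summary.logistic4 <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              rss = object$rss,
              sigma = sqrt(object$rss / max(length(object$dose) -
                                              (if (object$constrained) 2 else 4), 1)),
              n = length(object$dose),
              convergence = object$convergence,
              ic = tryCatch(
                inhibitory_concentration(object, c(0.10, 0.25, 0.50, 0.75)),
                error = function(e) NULL))
  class(out) <- "summary.logistic4"
  out
}

#' @export
print.summary.logistic4 <- function(x, ...) {
  cat("four-parameter logistic fit (n = ", x$n, ")\n", sep = "")
  print(signif(x$coefficients, 6))
  cat(sprintf("residual sd %.4g; converged: %s\n", x$sigma, x$convergence))
  if (!is.null(x$ic)) {
    cat("inhibitory concentrations:\n")
    print(signif(x$ic, 6))
  }
  invisible(x)
}

#' @export
plot.logistic4 <- function(x, n = 200, ...) {
  rng <- range(x$dose)
  grid <- exp(seq(log(rng[1]) - 0.5, log(rng[2]) + 0.5, length.out = n))
  plot(x$dose, x$response, log = "x", xlab = "dose", ylab = "response", ...)
  graphics::lines(grid, logistic4_curve(x$coefficients, grid))
  graphics::abline(v = x$coefficients[["midpoint"]], lty = 3)
  invisible(x)
}

#' Inhibitory concentration at a given effect level
#'
#' Inverts the fitted logistic in closed form: the ICx is the dose at which
#' the modeled inhibition — the fraction of the top-to-bottom span lost —
#' equals \code{x}, i.e. \code{m * (x / (1 - x))^(1 / h)}. IC50 equals the
#' fitted midpoint exactly.
#'
#' @param fit a converged \code{\link{fit_logistic4}} object.
#' @param x inhibition fraction(s) strictly in (0, 1); e.g.
#'   \code{c(0.10, 0.25, 0.50, 0.75)}.
#' @return Named numeric vector of doses.
#' @export
inhibitory_concentration <- function(fit, x) {
  stopifnot(inherits(fit, "logistic4"))
  if (!fit$convergence)
    stop("fit did not converge; ICx undefined", call. = FALSE)
  if (any(!is.finite(x) | x <= 0 | x >= 1))
    stop("effect level(s) must lie strictly in (0, 1)", call. = FALSE)
  cf <- fit$coefficients
  stats::setNames(cf[["midpoint"]] * (x / (1 - x))^(1 / cf[["hill"]]),
                  paste0("IC", round(100 * x)))
}

#' Fold-change resistance
#'
#' Ratio of a test IC50 to a reference (e.g. parental-line) IC50. Values above
#' 1 indicate resistance of the test relative to the reference.
#'
#' @param ic50_test,ic50_reference positive IC50 values in the same units.
#' @return numeric fold change(s).
#' @export
resistance_fold_change <- function(ic50_test, ic50_reference) {
  if (any(!is.finite(ic50_test) | ic50_test <= 0) ||
      any(!is.finite(ic50_reference) | ic50_reference <= 0))
    stop("IC50 values must be positive", call. = FALSE)
  ic50_test / ic50_reference
}

#' Combination index (Chou-Talalay, mutually exclusive form)
#'
#' For a drug combination achieving a chosen effect level at doses
#' (\code{dose_a}, \code{dose_b}), with single-agent doses \code{Dx_a} and
#' \code{Dx_b} producing the same effect,
#' \deqn{CI = dose_a / Dx_a + dose_b / Dx_b.}
#' CI below 1 is synergy, 1 additivity (within \code{tol}), above 1
#' antagonism.
#'
#' @param dose_a,dose_b combination doses (positive; vectors recycle).
#' @param Dx_a,Dx_b equi-effective single-agent doses (positive).
#' @param tol additivity tolerance around CI = 1.
#' @return data.frame of class \code{combination_record} with columns
#'   \code{dose_a}, \code{dose_b}, \code{Dx_a}, \code{Dx_b}, \code{CI},
#'   \code{verdict}.
#' @export
combination_index <- function(dose_a, dose_b, Dx_a, Dx_b, tol = 1e-6) {
  args <- cbind(dose_a = dose_a, dose_b = dose_b, Dx_a = Dx_a, Dx_b = Dx_b)
  if (any(!is.finite(args) | args <= 0))
    stop("all doses must be positive and finite", call. = FALSE)
  ci <- args[, "dose_a"] / args[, "Dx_a"] + args[, "dose_b"] / args[, "Dx_b"]
  verdict <- ifelse(abs(ci - 1) <= tol, "additive",
                    ifelse(ci < 1, "synergy", "antagonism"))
  out <- data.frame(args, CI = ci, verdict = verdict, stringsAsFactors = FALSE)
  class(out) <- c("combination_record", "data.frame")
  out
}
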