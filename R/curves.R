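#' Laying-rate curve models
#'
#' The three classical egg-production rate curves, evaluated at model
#' time \code{t} (weeks since onset of the recording window; the package
#' convention is t = week of age - 20, so t = 1 ... 23 covers weeks
#' 21-43):
#' \itemize{
#'   \item Wood: \eqn{y_t = a t^b e^{-ct}}
#'   \item compartmental: \eqn{y_t = a (1 - e^{-c(t-d)}) e^{-bt}}
#'   \item Yang-Ning: \eqn{y_t = a e^{-bt} / (1 + e^{-c(t-d)})}
#' }
#' In the Yang-Ning model \code{a} is the maximum potential laying rate,
#' \code{b} the rate of decline, \code{c} the rate of increase, and
#' \code{d} the model-time of first egg.
#'
#' @param t model time in weeks (week of age minus 20).
#' @param a,b,c,d model parameters.
#' @return laying rate at \code{t}.
#' @export
yangning <- function(t, a, b, c, d) a * exp(-b * t) / (1 + exp(-c * (t - d)))

#' @rdname yangning
#' @export
wood <- function(t, a, b, c) a * t^b * exp(-c * t)

#' @rdname yangning
#' @export
compartmental <- function(t, a, b, c, d) a * (1 - exp(-c * (t - d))) * exp(-b * t)

curve_fun <- function(model) {
  switch(model,
         yangning = function(t, p) yangning(t, p[1], p[2], p[3], p[4]),
         compartmental = function(t, p) compartmental(t, p[1], p[2], p[3], p[4]),
         wood = function(t, p) wood(t, p[1], p[2], p[3]))
}

curve_bounds <- function(model) {
  if (model == "wood")
    list(lower = c(a = 1e-8, b = 1e-8, c = 1e-8),
         upper = c(a = 5, b = 5, c = 2))
  else
    list(lower = c(a = 1e-8, b = 0, c = 1e-4, d = -5),
         upper = c(a = 1.5, b = 1, c = 10, d = 15))
}

curve_start_grid <- function(model) {
  g <- expand.grid(a = c(0.5, 0.8, 1.0), b = c(0.005, 0.02, 0.05),
                   c = c(0.5, 1, 2), d = c(1, 3, 5))
  if (model == "wood") unique(g[, c("a", "b", "c")]) else g
}

#' Fit a laying-rate curve to weekly mean rates
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt via
#' \code{minpack.lm}) from a fixed multi-start grid; the best start's fit
#' is returned. Model selection across the three curves uses
#' BIC = n log(RSS/n) + k log(n) with k parameters (Gaussian-residual
#' form).
#'
#' @param weekly_rates numeric vector of mean laying rates in [0, 1], one
#'   per week.
#' @param model one of \code{"yangning"}, \code{"compartmental"},
#'   \code{"wood"}.
#' @param weeks weeks of age the rates belong to (default 21-43); model
#'   time is \code{weeks - 20}.
#' @return an object of class \code{laying_curve}: fields \code{model},
#'   \code{params}, \code{rss}, \code{bic}, \code{fitted} (clamped to
#'   [0, 1]), \code{weeks}, \code{boundary} (TRUE when a parameter
#'   converged onto a bound — a degenerate fit).
#' @export
fit_laying_curve <- function(weekly_rates,
                             model = c("yangning", "compartmental", "wood"),
                             weeks = 21:43) {
  model <- match.arg(model)
  stopifnot(length(weekly_rates) == length(weeks))
  if (length(weekly_rates) < 6) stop("need at least 6 weekly points")
  if (any(weekly_rates < 0 | weekly_rates > 1))
    stop("weekly rates must be in [0, 1]")
  t <- weeks - 20
  f <- curve_fun(model)
  bounds <- curve_bounds(model)
  starts <- curve_start_grid(model)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         lower = as.numeric(bounds$lower),
                         upper = as.numeric(bounds$upper),
                         fn = function(p) weekly_rates - f(t, p),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("fit-failure: no start converged for model ", model)
  k <- length(best$par)
  n <- length(weekly_rates)
  names(best$par) <- names(bounds$lower)
  tol <- 1e-7
  boundary <- any(best$par <= as.numeric(bounds$lower) + tol |
                    best$par >= as.numeric(bounds$upper) - tol)
  out <- list(model = model, params = best$par, rss = best$rss,
              bic = n * log(best$rss / n) + k * log(n),
              fitted = clamp(f(t, best$par)), weeks = weeks,
              observed = weekly_rates, boundary = boundary)
  class(out) <- "laying_curve"
  out
}

#' Fit all three curve models and rank by BIC
#'
#' @inheritParams fit_laying_curve
#' @return list with \code{fits} (named list of \code{laying_curve}
#'   objects), \code{bic} (named, ascending) and \code{best} (name of the
#'   lowest-BIC model).
#' @export
select_curve_model <- function(weekly_rates, weeks = 21:43) {
  fits <- lapply(c("yangning", "compartmental", "wood"), function(m)
    fit_laying_curve(weekly_rates, m, weeks))
  names(fits) <- c("yangning", "compartmental", "wood")
  bic <- sort(vapply(fits, `[[`, numeric(1), "bic"))
  list(fits = fits, bic = bic, best = names(bic)[1])
}

#' @export
#' @method print laying_curve
print.laying_curve <- function(x, ...) {
  cat("Laying-rate curve fit (", x$model, " model)\n", sep = "")
  cat("  parameters:", paste(names(x$params),
                             signif(x$params, 4), sep = " = ",
                             collapse = ", "), "\n")
  cat("  RSS =", signif(x$rss, 4), " BIC =", round(x$bic, 3), "\n")
  if (x$boundary) cat("  note: fit converged on a parameter bound\n")
  if (x$model == "yangning") {
    sp <- stationary_point(x)
    if (!is.na(sp)) cat("  stationary point at", round(sp, 1), "weeks of age\n")
  }
  invisible(x)
}

#' @export
coef.laying_curve <- function(object, ...) object$params

#' @export
predict.laying_curve <- function(object, weeks = object$weeks, ...) {
  clamp(curve_fun(object$model)(weeks - 20, object$params))
}

#' @export
residuals.laying_curve <- function(object, ...) {
  object$observed - curve_fun(object$model)(object$weeks - 20, object$params)
}

#' @export
summary.laying_curve <- function(object, ...) {
  print(object)
  cat("  weekly residual SD:", signif(sqrt(object$rss / length(object$weeks)), 3), "\n")
  invisible(object)
}

#' @export
#' @method plot laying_curve
plot.laying_curve <- function(x, ...) {
  plot(x$weeks, x$observed, xlab = "week of age", ylab = "laying rate",
       ylim = c(0, 1), pch = 16, ...)
  ww <- seq(min(x$weeks), max(x$weeks), length.out = 200)
  graphics::lines(ww, predict(x, ww), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Stationary point of a fitted Yang-Ning curve
#'
#' Solves y'(t) = 0 in closed form: \eqn{t^* = d + \ln((c-b)/b)/c} when
#' 0 < b < c (otherwise the curve is monotone and \code{NA} is
#' returned), and converts model time to week of age by adding 20.
#'
#' @param fit a \code{laying_curve} with \code{model = "yangning"}, or a
#'   named numeric vector \code{c(a, b, c, d)}.
#' @return week of age of the curve's maximum, or \code{NA} when there
#'   is no interior optimum.
#' @export
stationary_point <- function(fit) {
  if (inherits(fit, "laying_curve")) {
    if (fit$model != "yangning")
      stop("unsupported model: stationary point is defined for the Yang-Ning fit")
    p <- fit$params
  } else p <- fit
  b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
  if (b <= 0 || b >= cc) return(NA_real_)
  unname(d + log((cc - b) / b) / cc + 20)
}

#' Split the laying cycle at the stationary point
#'
#' The up-stage runs from week 21 to the floor of the stationary week,
#' the sustained-stage from the next week to 43, and the all-stage is
#' the full 21-43 span.
#'
#' @param stationary_week week of age of the curve maximum, strictly
#'   inside (21, 43).
#' @return an object of class \code{stage_definition}: a named list of
#'   week ranges \code{up}, \code{sustained}, \code{all}.
#' @export
segment_stages <- function(stationary_week) {
  if (is.na(stationary_week) || stationary_week <= 21 || stationary_week >= 43)
    stop("stationary week out of range (21, 43): ", stationary_week)
  cut <- floor(stationary_week)
  out <- list(up = 21:cut, sustained = (cut + 1):43, all = 21:43)
  class(out) <- "stage_definition"
  out
}

#' @export
#' @method print stage_definition
print.stage_definition <- function(x, ...) {
  cat("Laying stages (weeks of age):\n")
  for (s in names(x))
    cat(sprintf("  %-9s %d-%d\n", s, min(x[[s]]), max(x[[s]])))
  invisible(x)
}
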