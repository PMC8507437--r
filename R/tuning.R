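#' Tuning settings
#'
#' Bundles the knobs of the coefficient-tuning engine. Defaults follow the
#' study conditions of the cross-calibration procedure: 150 observations
#' drawn with replacement per lake and replicate, lakes with fewer than 140
#' unique matches excluded, 10,000 bootstrap replicates, an unbounded robust
#' fit with a Cauchy loss.
#'
#' @param n_per_lake Observations drawn (with replacement) per included lake
#'   per replicate.
#' @param min_unique_per_lake Minimum number of unique surviving matches a
#'   lake must have to enter the bootstrap pool.
#' @param n_replicates Number of bootstrap replicates.
#' @param loss `"cauchy"` (robust, default) or `"linear"` (plain least
#'   squares).
#' @param loss_scale Scale `C` of the Cauchy loss
#'   `C^2 * log(1 + r^2 / C^2)`, in the residual's units (default 1).
#' @param seed Root seed for the bootstrap; per-replicate substream seeds are
#'   spawned from it and recorded in the result.
#' @param objective_space `"linear"` — residuals are formed in linear
#'   concentration units (mg m^-3 / FNU) — or `"log10"`.
#' @param rel_tol Relative convergence tolerance of the optimiser.
#' @param max_eval Maximum objective evaluations per fit.
#' @return A list of class `tuning_settings`.
#' @export
tuning_settings <- function(n_per_lake = 150, min_unique_per_lake = 140,
                            n_replicates = 10000,
                            loss = c("cauchy", "linear"), loss_scale = 1,
                            seed = 1L,
                            objective_space = c("linear", "log10"),
                            rel_tol = 1e-10, max_eval = 1000) {
  stopifnot(n_per_lake >= 1, n_replicates >= 1, loss_scale > 0)
  structure(
    list(n_per_lake = as.integer(n_per_lake),
         min_unique_per_lake = as.integer(min_unique_per_lake),
         n_replicates = as.integer(n_replicates),
         loss = match.arg(loss), loss_scale = loss_scale,
         seed = as.integer(seed),
         objective_space = match.arg(objective_space),
         rel_tol = rel_tol, max_eval = as.integer(max_eval)),
    class = "tuning_settings"
  )
}

# Forward model f(x; theta) per algorithm, on the predictor used for tuning.
# x is the MSI predictor: log10 blue:green ratio for OCx, red-edge:red ratio
# for gilerson, and a data.frame of (b665, b708, b778) reflectances for
# gons05. Invalid regions return NA; the objective maps them to a large
# penalty so the optimiser retreats.
model_predict <- function(theta, x, model, template) {
  switch(model,
    oc2 = ,
    oc3 = 10^(theta[1] + theta[2] * x + theta[3] * x^2 +
                theta[4] * x^3 + theta[5] * x^4),
    gilerson = {
      base <- theta[1] * x + theta[2]
      ifelse(base > 0, base^theta[3], NA_real_)
    },
    gons05 = {
      cf <- template
      den <- cf$k_gamma - cf$k_scatter * x$b778
      bb <- ifelse(den > 0 & x$b778 >= 0,
                   cf$k_scatter * cf$aw[["aw779"]] * x$b778 / den, NA_real_)
      ((x$b708 / x$b665) * (cf$aw[["aw709"]] + bb) - cf$aw[["aw665"]] -
          bb^theta[1]) / theta[2]
    },
    linear = theta[1] * x + theta[2],
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

model_theta <- function(init, model) {
  switch(model,
    oc2 = ,
    oc3 = ,
    gilerson = unname(coef_values(init)),
    gons05 = unname(coef_values(init)),      # (p, a_chl_star); aw frozen
    linear = unname(coef_values(init))
  )
}

model_result <- function(theta, init, model) {
  set_coef_values(init, theta)
}

#' One robust nonlinear least-squares fit
#'
#' Minimises `sum(rho(r_i^2))` over the algorithm's tunable coefficients,
#' where `r_i = f(x_i; theta) - y_i` and `rho` is either the identity
#' (`loss = "linear"`) or the Cauchy loss `C^2 log(1 + z / C^2)` that damps
#' the influence of large outliers. The solution is unbounded and
#' deterministic given inputs and the initial coefficients. Points where the
#' model is undefined at a trial `theta` incur a large finite penalty so the
#' optimiser moves back into the valid region.
#'
#' @param x Predictor: numeric vector, or for `"gons05"` a data frame with
#'   columns `b665`, `b708`, `b778`.
#' @param y Target values (reference-sensor product), same length.
#' @param model `"oc2"`, `"oc3"`, `"gilerson"`, `"gons05"` or `"linear"`.
#' @param init Initial [coefficient_set] (for `"linear"`, a
#'   [linear_calibration()]).
#' @param settings A [tuning_settings()] (bootstrap fields ignored here).
#' @return A list of class `fit_result`: `coefficients` (a coefficient set),
#'   `theta`, `objective`, `converged`, `status`.
#' @export
fit_once <- function(x, y, model, init, settings = tuning_settings()) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  stopifnot(length(y) == n)
  theta0 <- model_theta(init, model)
  if (n < length(theta0)) {
    stop("fewer observations (", n, ") than parameters (", length(theta0),
         ")", call. = FALSE)
  }
  log_space <- settings$objective_space == "log10"
  yy <- if (log_space) log10(y) else y
  C2 <- settings$loss_scale^2
  penalty <- 1e8
  objective <- function(theta) {
    f <- model_predict(theta, x, model, init)
    if (log_space) f <- log10(f)
    r2 <- (f - yy)^2
    r2[!is.finite(r2)] <- penalty
    if (settings$loss == "cauchy") sum(C2 * log1p(r2 / C2)) else sum(r2)
  }
  fit <- stats::nlminb(theta0, objective,
                       control = list(rel.tol = settings$rel_tol,
                                      x.tol = settings$rel_tol,
                                      eval.max = settings$max_eval,
                                      iter.max = settings$max_eval))
  # nlminb labels an exact-optimum start "false convergence"; only treat
  # iteration/evaluation-limit exits and non-finite objectives as failures
  ok <- is.finite(fit$objective) && !grepl("limit reached", fit$message)
  structure(
    list(coefficients = model_result(fit$par, init, model),
         theta = fit$par, objective = fit$objective,
         converged = ok, status = fit$message),
    class = "fit_result"
  )
}

#' Ordinary least-squares linear scaling
#'
#' Fits `y = gain * x + offset` by OLS; used for the band-ratio linear
#' scaling alternative and as the turbidity calibration model.
#'
#' @param x,y Numeric vectors, length >= 2, `x` non-degenerate.
#' @return A [linear_calibration()].
#' @export
#' @examples
#' fit_linear_scaling(c(0, 1), c(1, 3))   # gain 2, offset 1
fit_linear_scaling <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 finite points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: scaling undefined",
                              call. = FALSE)
  cf <- stats::coef(stats::lm(y ~ x))
  linear_calibration(gain = unname(cf[2]), offset = unname(cf[1]))
}

#' Coefficient deviation multipliers
#'
#' Element-wise ratio tuned/initial for matching parameter names — the
#' deviation of tuned coefficients from their pre-tuning values expressed as
#' a multiplier of the initial values. A zero initial coefficient yields an
#' `NA` entry with a warning.
#'
#' @param initial,tuned Two [coefficient_set]s of the same family.
#' @param digits Significant figures for the reported multipliers
#'   (`NULL` = full precision).
#' @return Named numeric vector of multipliers.
#' @export
#' @examples
#' reg <- read_registry()
#' coefficient_deviation(registry_coefficients(reg, "msi", "gons05"),
#'                       registry_coefficients(reg, "msi", "gons05", "tuned"))
coefficient_deviation <- function(initial, tuned, digits = NULL) {
  vi <- coef_values(initial)
  vt <- coef_values(tuned)
  stopifnot(identical(names(vi), names(vt)))
  if (any(vi == 0)) {
    warning("zero initial coefficient(s): ",
            paste(names(vi)[vi == 0], collapse = ", "),
            " have undefined multipliers", call. = FALSE)
  }
  out <- ifelse(vi == 0, NA_real_, vt / vi)
  names(out) <- names(vi)
  if (!is.null(digits)) out <- signif(out, digits)
  out
}
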