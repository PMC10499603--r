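# Steady-state one-site binding analysis for biosensor (BLI) data.
#
# At equilibrium the response follows R(C) = Rmax * C / (Kd + C). Kd and
# Rmax are fitted by least squares on a log parameterisation, which keeps
# both parameters positive without explicit constraints.

#' Fit a steady-state one-site binding isotherm
#'
#' Least-squares fit of `R(C) = Rmax * C / (Kd + C)` via
#' Levenberg-Marquardt on `log(Kd)`, `log(Rmax)`. Default starting values
#' are the geometric mid-range concentration for Kd and the maximum
#' response for Rmax.
#'
#' @param concentrations Analyte concentrations (nM), positive, >= 5
#'   points spanning at least one order of magnitude.
#' @param responses Equilibrium responses (sensor units), non-negative.
#' @param kd_init,rmax_init Optional starting values.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative parameter-change convergence tolerance
#'   (default 1e-8).
#' @return A `kd_fit`: `kd`, `rmax`, standard errors (delta method from
#'   the log scale), `rss`, `converged`, `n`.
#' @export
fit_steady_state <- function(concentrations, responses, kd_init = NULL,
                             rmax_init = NULL, max_iter = 500L,
                             tol = 1e-8) {
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length")
  }
  ok <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[ok]; responses <- responses[ok]
  if (length(concentrations) < 5L) {
    stop("at least 5 concentration points are required")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (diff(range(log10(concentrations))) < 1) {
    stop("concentrations must span at least one order of magnitude")
  }
  ord <- order(concentrations)
  mono <- responses[ord]
  if (any(diff(mono) < -0.1 * max(abs(responses)))) {
    warning("responses are non-monotone beyond the noise floor; fit may be unreliable")
  }
  if (is.null(kd_init)) kd_init <- exp(mean(range(log(concentrations))))
  if (is.null(rmax_init)) rmax_init <- max(responses)

  resid_fn <- function(par) {
    responses - exp(par[2]) * concentrations /
      (exp(par[1]) + concentrations)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(lkd = log(kd_init), lrmax = log(rmax_init)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = tol, ptol = tol)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(kd = NA_real_, rmax = NA_real_,
                          kd_se = NA_real_, rmax_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n = length(responses)),
                     class = "kd_fit"))
  }
  n <- length(responses)
  rss <- fit$deviance
  sigma2 <- rss / max(n - 2L, 1L)
  se_log <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))),
                     error = function(e) c(NA_real_, NA_real_))
  kd <- exp(fit$par[["lkd"]]); rmax <- exp(fit$par[["lrmax"]])
  structure(
    list(kd = kd, rmax = rmax,
         kd_se = kd * se_log[[1]],            # delta method
         rmax_se = rmax * se_log[[2]],
         rss = rss, converged = TRUE, n = n),
    class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.4g (se %.2g), Rmax = %.4g (se %.2g), RSS = %.3g, n = %d%s\n",
              x$kd, x$kd_se, x$rmax, x$rmax_se, x$rss, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Affinity fold change between two fitted Kd values
#'
#' Ratio `Kd_a / Kd_b` with a first-order (delta-method) propagated
#' standard error.
#'
#' @param fit_a,fit_b Converged [fit_steady_state()] results.
#' @return A list with `fold_change` and `se`.
#' @export
affinity_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "kd_fit"), inherits(fit_b, "kd_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both fits must have converged")
  }
  ratio <- fit_a$kd / fit_b$kd
  se <- ratio * sqrt((fit_a$kd_se / fit_a$kd)^2 +
                     (fit_b$kd_se / fit_b$kd)^2)
  list(fold_change = ratio, se = se)
}

#' Fit isotherms for each ligand in a response table
#'
#' @param data `data.frame` with columns `ligand`, `concentration_nM`,
#'   `response`.
#' @param ... Passed to [fit_steady_state()].
#' @return Named list of `kd_fit` objects, one per ligand.
#' @export
fit_bli_table <- function(data, ...) {
  req <- c("ligand", "concentration_nM", "response")
  if (!all(req %in% names(data))) {
    stop("data must have columns: ", paste(req, collapse = ", "))
  }
  lapply(split(data, data$ligand), function(df) {
    fit_steady_state(df$concentration_nM, df$response, ...)
  })
}
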