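#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Gauss-Newton standard errors from a numerical Jacobian at the optimum:
# cov = (J'J)^-1 * rss / dof. Parameters pinned at a bound get NA.
gn_standard_errors <- function(resid_fun, par, rss, dof) {
  n_par <- length(par)
  r0 <- resid_fun(par)
  J <- matrix(NA_real_, length(r0), n_par)
  h <- pmax(abs(par), 1e-8) * 1e-6
  for (j in seq_len(n_par)) {
    pp <- par; pp[j] <- pp[j] + h[j]
    pm <- par; pm[j] <- pm[j] - h[j]
    J[, j] <- (resid_fun(pp) - resid_fun(pm)) / (2 * h[j])
  }
  jtj <- crossprod(J)
  se <- rep(NA_real_, n_par)
  ok <- tryCatch({
    cv <- solve(jtj) * rss / dof
    se <- sqrt(pmax(diag(cv), 0))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) se <- rep(NA_real_, n_par)
  names(se) <- names(par)
  se
}

new_fit_result <- function(estimates, standard_errors, rss, dof, converged,
                           model_tag, n_points) {
  structure(
    list(estimates = estimates, standard_errors = standard_errors,
         rss = rss, dof = dof, converged = converged,
         model_tag = model_tag, n_points = n_points),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result [%s]%s\n", x$model_tag,
              if (x$converged) "" else "  (NOT converged)"))
  est <- x$estimates
  se <- x$standard_errors
  for (nm in names(est))
    cat(sprintf("  %-7s = %.6g  (SE %.3g)\n", nm, est[[nm]],
                if (is.null(se[[nm]]) || is.na(se[[nm]])) NA else se[[nm]]))
  cat(sprintf("  rss = %.6g, dof = %d, n = %d\n", x$rss, x$dof, x$n_points))
  invisible(x)
}

#' Michaelis-Menten fit of rates at a single activator concentration
#'
#' Least-squares fit of `v = k_cat_app * E * S / (K_M_app + S)` to replicate
#' initial rates measured across substrate levels at one fixed activator
#' concentration. Initialisation takes `k_cat_app` from the largest observed
#' rate and `K_M_app` from the substrate level whose rate is nearest half of
#' it; standard errors come from the Gauss-Newton curvature at the optimum.
#'
#' @param dataset an `assay_dataset` slice (all rows must share one
#'   activator level) with columns `substrate_uM`, `enzyme_uM`,
#'   `velocity_uM_per_s`.
#' @param weights optional per-row weights (e.g. 1/SEM^2); default
#'   unweighted.
#' @return A `fit_result` with estimates `k_cat_app` (1/s) and `K_M_app`
#'   (uM), `model_tag = "MM_apparent"`. Non-convergence or an unbounded
#'   K_M (degenerate, substrate-independent data) is reported through
#'   `converged = FALSE`, not as an error.
#' @export
fit_michaelis_menten <- function(dataset, weights = NULL) {
  stopifnot(all(c("substrate_uM", "enzyme_uM", "velocity_uM_per_s") %in%
                  names(dataset)))
  if (length(unique(dataset$activator_uM)) > 1L)
    stop("dataset slice spans several activator levels; fit one at a time",
         call. = FALSE)
  S <- dataset$substrate_uM
  v <- dataset$velocity_uM_per_s
  E <- dataset$enzyme_uM[1]
  if (length(unique(S)) < 3L)
    stop("need at least 3 distinct substrate levels", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(v)) else weights
  sw <- sqrt(w)

  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S[S > 0])
  resid_fun <- function(p) sw * (v - p[1] * E * S / (p[2] + S))
  start <- c(k_cat_app = vmax0 / E, K_M_app = km0)

  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = c(1e-12, 1e-12), upper = c(Inf, 1e9),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL
  )
  n <- length(v)
  dof <- n - 2L
  if (is.null(fit) || dof <= 0L) {
    return(new_fit_result(as.list(start), list(k_cat_app = NA, K_M_app = NA),
                          NA_real_, max(dof, 0L), FALSE, "MM_apparent", n))
  }
  par <- stats::coef(fit)
  rss <- sum(resid_fun(par)^2)
  # K_M driven to either bound flags substrate-independent (degenerate) data
  converged <- fit$info %in% 1:4 &&
    par[["K_M_app"]] < 1e8 && par[["K_M_app"]] > 1e-8
  se <- gn_standard_errors(resid_fun, par, rss, dof)
  new_fit_result(as.list(par),
                 list(k_cat_app = se[["k_cat_app"]], K_M_app = se[["K_M_app"]]),
                 rss, dof, converged, "MM_apparent", n)
}

global_param_names <- c("k_cat", "K_M", "K_act", "alpha", "beta")

#' Global fit of the non-essential-activator rate law
#'
#' Simultaneous least squares of the five-parameter rate law over every
#' (substrate, activator) condition of a dataset, optionally with the
#' coupling factor alpha pinned (`fix_alpha = 1` expresses "the activator
#' does not change substrate affinity", the restricted model of the nested
#' comparison in [extra_ss_f_test()]). Multi-start: the first start is
#' seeded from Michaelis-Menten fits at the extreme activator levels, the
#' remainder are log-uniform perturbations of it; the best residual sum of
#' squares wins. Bounds: `k_cat`, `K_M`, `K_act` positive; `alpha` in
#' (1e-3, 1e3); `beta` in (0, 1e3).
#'
#' @param dataset an `assay_dataset` covering at least two activator levels
#'   including zero.
#' @param fix_alpha optional fixed value for alpha (e.g. 1); `NULL` leaves
#'   it free.
#' @param weights optional per-row weights (e.g. 1/SEM^2); default
#'   unweighted, matching common practice when replicate scatter is roughly
#'   proportional to the mean.
#' @param n_starts number of multi-start attempts (>= 1).
#' @param start_seed seed for the start perturbations (fit is deterministic
#'   given data and this seed; the caller's RNG state is untouched).
#' @return A `fit_result` with the five estimates (alpha echoed at its fixed
#'   value with SE `NA` when pinned), `model_tag` `"global_alpha_free"` or
#'   `"global_alpha_fixed"`.
#' @export
fit_global <- function(dataset, fix_alpha = NULL, weights = NULL,
                       n_starts = 8, start_seed = 1L) {
  stopifnot(all(c("substrate_uM", "activator_uM", "enzyme_uM",
                  "velocity_uM_per_s") %in% names(dataset)))
  acts <- sort(unique(dataset$activator_uM))
  if (length(acts) < 2L || acts[1] != 0)
    stop("need >= 2 activator levels including 0 (beta is unidentifiable otherwise)",
         call. = FALSE)
  S <- dataset$substrate_uM
  A <- dataset$activator_uM
  E <- dataset$enzyme_uM
  v <- dataset$velocity_uM_per_s
  w <- if (is.null(weights)) rep(1, length(v)) else weights
  sw <- sqrt(w)

  free <- if (is.null(fix_alpha)) global_param_names else
    setdiff(global_param_names, "alpha")
  model_tag <- if (is.null(fix_alpha)) "global_alpha_free" else
    "global_alpha_fixed"

  full_par <- function(p) {
    q <- c(p)
    if (!is.null(fix_alpha)) q <- c(q, alpha = fix_alpha)
    q[global_param_names]
  }
  resid_fun <- function(p) {
    q <- full_par(p)
    s <- S / q[["K_M"]]
    a <- A / q[["K_act"]]
    pred <- E * q[["k_cat"]] * s * (1 + q[["beta"]] * a / q[["alpha"]]) /
      (1 + s + a + s * a / q[["alpha"]])
    sw * (v - pred)
  }

  # MM fits at the two extreme activator levels seed the start point
  base <- local({
    d0 <- dataset[dataset$activator_uM == acts[1], , drop = FALSE]
    dmax <- dataset[dataset$activator_uM == acts[length(acts)], , drop = FALSE]
    f0 <- tryCatch(fit_michaelis_menten(d0), error = function(e) NULL)
    fmax <- tryCatch(fit_michaelis_menten(dmax), error = function(e) NULL)
    kc <- if (!is.null(f0)) f0$estimates$k_cat_app else max(v) / E[1]
    km <- if (!is.null(f0)) f0$estimates$K_M_app else stats::median(S[S > 0])
    bt <- if (!is.null(fmax)) max(fmax$estimates$k_cat_app / kc, 1.1) else 5
    al <- if (!is.null(fmax) && !is.null(f0))
      min(max(fmax$estimates$K_M_app / km, 1e-2), 1e2) else 1
    c(k_cat = max(kc, 1e-6), K_M = max(km, 1e-3),
      K_act = stats::median(acts[acts > 0]), alpha = al, beta = bt)
  })

  lower <- c(k_cat = 1e-9, K_M = 1e-9, K_act = 1e-9, alpha = 1e-3, beta = 0)
  upper <- c(k_cat = 1e6, K_M = 1e9, K_act = 1e9, alpha = 1e3, beta = 1e3)

  starts <- with_local_seed(start_seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1L) return(base[free])
      p <- base * 10^stats::runif(length(base), -0.5, 0.5)
      pmin(pmax(p[free], lower[free] * 1.01), upper[free] * 0.99)
    })
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = lower[free], upper = upper[free],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid_fun(stats::coef(fit))^2)
    if (is.null(best) || rss < best$rss - 0)
      best <- list(fit = fit, rss = rss)
  }

  n <- length(v)
  dof <- n - length(free)
  if (is.null(best)) {
    est <- as.list(full_par(base[free]))
    return(new_fit_result(est, stats::setNames(as.list(rep(NA_real_, 5)),
                                               global_param_names),
                          NA_real_, dof, FALSE, model_tag, n))
  }
  if (dof <= 0L)
    stop("not enough data points for the number of free parameters",
         call. = FALSE)
  par <- stats::coef(best$fit)
  rss <- best$rss
  se_free <- gn_standard_errors(resid_fun, par, rss, dof)
  est <- as.list(full_par(par))
  se <- stats::setNames(as.list(rep(NA_real_, 5)), global_param_names)
  for (nm in free) se[[nm]] <- se_free[[nm]]
  converged <- best$fit$info %in% 1:4
  new_fit_result(est, se, rss, dof, converged, model_tag, n)
}

#' Extra-sum-of-squares F-test between nested fits
#'
#' Compares a restricted model (fewer free parameters, e.g. the coupling
#' factor pinned at 1) with the full model fitted to the same data:
#' \deqn{F = \frac{(RSS_r - RSS_f)/(df_r - df_f)}{RSS_f/df_f}}
#' with the p-value from the upper tail of the F(df_r - df_f, df_f)
#' distribution. A small negative RSS difference (within numerical fit
#' tolerance) is clamped to zero; a larger one means the fits are not nested
#' or one failed, and is an error.
#'
#' @param restricted,full `fit_result` objects from fits of the same
#'   dataset, with `restricted$dof > full$dof`.
#' @param tolerance allowed relative RSS inversion before erroring.
#' @return An object of class `f_test_result`: `f_statistic`, `df_num`,
#'   `df_den`, `p_value`.
#' @export
extra_ss_f_test <- function(restricted, full, tolerance = 1e-8) {
  stopifnot(inherits(restricted, "fit_result"), inherits(full, "fit_result"))
  if (restricted$n_points != full$n_points)
    stop("fits are not of the same dataset (different n)", call. = FALSE)
  if (restricted$dof <= full$dof)
    stop("restricted model must have more residual degrees of freedom",
         call. = FALSE)
  drss <- restricted$rss - full$rss
  if (drss < 0) {
    if (-drss <= tolerance * max(full$rss, .Machine$double.eps)) drss <- 0
    else stop("restricted RSS below full RSS: models not nested or fit failed",
              call. = FALSE)
  }
  df_num <- restricted$dof - full$dof
  df_den <- full$dof
  f <- (drss / df_num) / (full$rss / df_den)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  structure(
    list(f_statistic = f, df_num = df_num, df_den = df_den, p_value = p),
    class = "f_test_result"
  )
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("Extra-sum-of-squares F-test: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value))
  invisible(x)
}

#' Apparent-constant table across activator levels
#'
#' Fits [fit_michaelis_menten()] at every activator level of a dataset and
#' tabulates apparent k_cat, apparent K_M and catalytic power, the layout of
#' a per-activator kinetic summary table.
#'
#' @param dataset an `assay_dataset`.
#' @param digits decimal places for the rounded catalytic-power column
#'   (half-away-from-zero); raw values are retained alongside.
#' @return A data.frame with one row per activator level: estimates, their
#'   SEs, raw and rounded catalytic power, and a convergence flag.
#' @export
apparent_constant_table <- function(dataset, digits = 1) {
  acts <- sort(unique(dataset$activator_uM))
  rows <- lapply(acts, function(a) {
    fit <- fit_michaelis_menten(dataset[dataset$activator_uM == a, ,
                                        drop = FALSE])
    cp <- if (fit$converged)
      catalytic_power(fit$estimates$k_cat_app, fit$estimates$K_M_app)
    else NA_real_
    data.frame(activator_uM = a,
               k_cat_app = fit$estimates$k_cat_app,
               k_cat_app_se = fit$standard_errors$k_cat_app,
               K_M_app = fit$estimates$K_M_app,
               K_M_app_se = fit$standard_errors$K_M_app,
               catalytic_power = cp,
               catalytic_power_rounded = round_half_up(cp, digits),
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
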