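#' Initial velocity under the non-essential-activator rate law
#'
#' Evaluates the rapid-equilibrium steady-state velocity for an enzyme whose
#' activity is modulated by a non-essential activator A acting on substrate S:
#'
#' \deqn{v = \frac{E\,k_{cat}\,(S/K_M)\,\bigl(1 + \beta A/(\alpha K_{act})\bigr)}
#'          {1 + S/K_M + A/K_{act} + S A/(\alpha K_M K_{act})}}
#'
#' The four enzyme species E, ES, EA and ESA are assumed to equilibrate fast
#' relative to turnover; ES turns over at `k_cat` and ESA at `beta * k_cat`.
#' With `alpha = beta = 1` this is exactly single-substrate
#' Michaelis-Menten, independent of A.
#'
#' @param params a [kinetic_params] object.
#' @param cond an [assay_condition] object; `substrate_conc` and
#'   `activator_conc` may be equal-length vectors for vectorised evaluation.
#' @return Velocity in uM/s (vector recycled over the condition grid).
#' @examples
#' p <- mical_params("MO")
#' velocity(p, assay_condition(100, 7.5, 0.6))  # ~0.84 uM/s
#' @seealso [apparent_kcat()], [apparent_km()] for the fixed-activator
#'   Michaelis-Menten decomposition.
#' @export
velocity <- function(params, cond) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "assay_condition"))
  S <- cond$substrate_conc
  A <- cond$activator_conc
  E <- cond$enzyme_conc
  s <- S / params$K_M
  a <- A / params$K_act
  num <- E * params$k_cat * s * (1 + params$beta * a / params$alpha)
  den <- 1 + s + a + s * a / params$alpha
  num / den
}

#' Apparent turnover number at a fixed activator concentration
#'
#' At a fixed activator concentration A the full rate law collapses to a
#' Michaelis-Menten form in substrate; its apparent turnover number is
#' \deqn{k_{cat}^{app}(A) = k_{cat}\,
#'   \frac{1 + \beta A/(\alpha K_{act})}{1 + A/(\alpha K_{act})}}
#' which runs from `k_cat` at A = 0 to `beta * k_cat` at saturating A.
#'
#' @param params a [kinetic_params] object.
#' @param activator_conc activator concentration(s), uM, >= 0.
#' @return Apparent k_cat in 1/s.
#' @export
apparent_kcat <- function(params, activator_conc) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(activator_conc))
  if (any(activator_conc < 0))
    stop("activator_conc must be >= 0", call. = FALSE)
  a <- activator_conc / (params$alpha * params$K_act)
  params$k_cat * (1 + params$beta * a) / (1 + a)
}

#' Apparent Michaelis constant at a fixed activator concentration
#'
#' \deqn{K_M^{app}(A) = K_M\,
#'   \frac{1 + A/K_{act}}{1 + A/(\alpha K_{act})}}
#' runs from `K_M` at A = 0 to `alpha * K_M` at saturating activator, and is
#' constant in A exactly when `alpha = 1` (no coupling between substrate and
#' activator binding).
#'
#' @inheritParams apparent_kcat
#' @return Apparent K_M in uM.
#' @export
apparent_km <- function(params, activator_conc) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(activator_conc))
  if (any(activator_conc < 0))
    stop("activator_conc must be >= 0", call. = FALSE)
  params$K_M * (1 + activator_conc / params$K_act) /
    (1 + activator_conc / (params$alpha * params$K_act))
}

#' Catalytic power (specificity constant) in 1/(s mM)
#'
#' The ratio of the apparent turnover number to the apparent Michaelis
#' constant, unit-converted from uM to mM so values land on the customary
#' s^-1 mM^-1 scale of kinetic summary tables.
#'
#' @param k_cat_app apparent turnover number, 1/s (>= 0).
#' @param K_M_app apparent Michaelis constant, uM (> 0).
#' @return Catalytic power `1000 * k_cat_app / K_M_app`, s^-1 mM^-1.
#' @examples
#' catalytic_power(1.7, 37.7)    # 45.09...
#' catalytic_power(10.3, 9.9)    # 1040.40...
#' @export
catalytic_power <- function(k_cat_app, K_M_app) {
  stopifnot(is.numeric(k_cat_app), is.numeric(K_M_app))
  if (any(k_cat_app < 0)) stop("k_cat_app must be >= 0", call. = FALSE)
  if (any(K_M_app <= 0)) stop("K_M_app must be > 0", call. = FALSE)
  1000 * k_cat_app / K_M_app
}

#' Fold change relative to a reference value
#'
#' @param value_at value in the perturbed state.
#' @param value_ref reference value (> 0).
#' @return `value_at / value_ref`.
#' @examples
#' fold_change(1.18, 0.68)  # ~1.7-fold turnover increase
#' @export
fold_change <- function(value_at, value_ref) {
  stopifnot(is.numeric(value_at), is.numeric(value_ref))
  if (any(value_ref <= 0)) stop("value_ref must be > 0", call. = FALSE)
  value_at / value_ref
}

#' Round half away from zero
#'
#' Report-table rounding: 45.05 -> 45.1 at one decimal, unlike banker's
#' rounding. Used when regenerating printed kinetic summary tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
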