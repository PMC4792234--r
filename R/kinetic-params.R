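#' Global kinetic parameters for the non-essential-activator model
#'
#' Bundle the five parameters of the rapid-equilibrium non-essential
#' activation scheme: the enzyme turns over substrate (NADPH) with turnover
#' number `k_cat` and Michaelis constant `K_M`; the activator (F-actin) binds
#' with dissociation constant `K_act`; bound activator rescales the substrate
#' dissociation constant by `alpha` (coupling; `alpha < 1` means mutually
#' enhancing binding) and the turnover number of the ternary complex by
#' `beta` (acceleration). `alpha = 1, beta = 1` collapses the model to
#' single-substrate Michaelis-Menten.
#'
#' @param k_cat turnover number of the enzyme-substrate complex, 1/s.
#' @param K_M substrate (NADPH) half-saturation constant, uM.
#' @param K_act activator (F-actin) dissociation constant, uM.
#' @param alpha dimensionless coupling factor, > 0.
#' @param beta dimensionless acceleration factor, >= 0.
#'
#' @return An object of class `kinetic_params` (named list of the five
#'   parameters).
#' @examples
#' # published global parameters for the MO-CH construct
#' kinetic_params(k_cat = 1.7, K_M = 37.7, K_act = 10.5,
#'                alpha = 0.16, beta = 7.43)
#' @export
kinetic_params <- function(k_cat, K_M, K_act, alpha = 1, beta = 1) {
  stopifnot(
    is.numeric(k_cat), length(k_cat) == 1L, is.finite(k_cat),
    is.numeric(K_M), length(K_M) == 1L, is.finite(K_M),
    is.numeric(K_act), length(K_act) == 1L, is.finite(K_act),
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
    is.numeric(beta), length(beta) == 1L, is.finite(beta)
  )
  if (k_cat <= 0) stop("k_cat must be strictly positive", call. = FALSE)
  if (K_M <= 0) stop("K_M must be strictly positive", call. = FALSE)
  if (K_act <= 0) stop("K_act must be strictly positive", call. = FALSE)
  if (alpha <= 0) stop("alpha must be strictly positive", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  structure(
    list(k_cat = k_cat, K_M = K_M, K_act = K_act, alpha = alpha, beta = beta),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Non-essential-activator kinetic parameters:\n")
  cat(sprintf("  k_cat = %g 1/s,  K_M = %g uM,  K_act = %g uM\n",
              x$k_cat, x$K_M, x$K_act))
  cat(sprintf("  alpha = %g (coupling),  beta = %g (acceleration)\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Published global parameter sets for the two MICAL constructs
#'
#' Convenience constructors for the globally fitted parameters of the
#' isolated monooxygenase domain (`MO`: alpha restrained to 1) and the
#' monooxygenase plus calponin-homology construct (`MO-CH`: alpha free).
#'
#' @param construct `"MO"` or `"MO-CH"`.
#' @return A [kinetic_params] object.
#' @examples
#' mical_params("MO")
#' mical_params("MO-CH")
#' @export
mical_params <- function(construct = c("MO", "MO-CH")) {
  construct <- match.arg(construct)
  if (construct == "MO") {
    kinetic_params(k_cat = 0.68, K_M = 28.8, K_act = 9.3,
                   alpha = 1, beta = 4.7)
  } else {
    kinetic_params(k_cat = 1.7, K_M = 37.7, K_act = 10.5,
                   alpha = 0.16, beta = 7.43)
  }
}

#' Assay condition
#'
#' One cuvette's composition: substrate, activator and total enzyme
#' concentrations, all in uM.
#'
#' @param substrate_conc NADPH concentration, uM (>= 0).
#' @param activator_conc F-actin concentration, uM (>= 0).
#' @param enzyme_conc total enzyme concentration, uM (> 0).
#' @return An object of class `assay_condition`.
#' @examples
#' assay_condition(substrate_conc = 100, activator_conc = 7.5,
#'                 enzyme_conc = 0.6)
#' @export
assay_condition <- function(substrate_conc, activator_conc = 0,
                            enzyme_conc = 0.6) {
  stopifnot(is.numeric(substrate_conc), is.numeric(activator_conc),
            is.numeric(enzyme_conc), length(enzyme_conc) == 1L)
  if (any(substrate_conc < 0)) stop("substrate_conc must be >= 0", call. = FALSE)
  if (any(activator_conc < 0)) stop("activator_conc must be >= 0", call. = FALSE)
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0", call. = FALSE)
  structure(
    list(substrate_conc = substrate_conc, activator_conc = activator_conc,
         enzyme_conc = enzyme_conc),
    class = "assay_condition"
  )
}
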