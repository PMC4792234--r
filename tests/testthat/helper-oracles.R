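# Independent oracles used across the suite.

# Rapid-equilibrium species enumeration: relative abundances of the four
# enzyme species (E, ES, EA, ESA) from the binding constants, summing the
# turnover of the two productive species. Written as the species ledger,
# independent of the packed rate-law expression in the package.
oracle_velocity <- function(k_cat, K_M, K_act, alpha, beta, S, A, E) {
  w_E <- 1
  w_ES <- S / K_M
  w_EA <- A / K_act
  w_ESA <- (S / K_M) * (A / (alpha * K_act))
  total <- w_E + w_ES + w_EA + w_ESA
  E * (k_cat * w_ES + beta * k_cat * w_ESA) / total
}

# Apparent Michaelis-Menten constants obtained from the enumeration oracle
# by probing it: k_cat_app from the saturating-substrate limit, K_M_app as
# the substrate level at which the oracle velocity is half of that.
oracle_apparent <- function(k_cat, K_M, K_act, alpha, beta, A, E = 1) {
  v_at <- function(S) oracle_velocity(k_cat, K_M, K_act, alpha, beta, S, A, E)
  vmax <- v_at(1e12)
  k_cat_app <- vmax / E
  K_M_app <- stats::uniroot(function(S) v_at(S) - vmax / 2,
                            c(1e-9, 1e9), tol = 1e-12)$root
  list(k_cat_app = k_cat_app, K_M_app = K_M_app)
}

# Upper-tail F probability by numerical integration of the density, the
# independent route against the distribution-function call in the package.
oracle_f_pvalue <- function(f, df1, df2) {
  stats::integrate(function(x) stats::df(x, df1, df2), f, Inf,
                   rel.tol = 1e-10)$value
}

# Orientation-averaged form factor of a uniform sphere of radius R.
sphere_intensity <- function(q, R, I0 = 1) {
  x <- q * R
  I0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}
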