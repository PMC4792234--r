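test_that("Michaelis-Menten fits recover noise-free apparent constants exactly", {
  p <- mical_params("MO-CH")
  des <- mical_design("MO-CH", replicates = 1, noise_cv = 0)
  d <- generate_dataset(p, des)
  for (a in c(0, 8)) {
    fit <- fit_michaelis_menten(d[d$activator_uM == a, ])
    expect_true(fit$converged)
    expect_equal(fit$estimates$k_cat_app, apparent_kcat(p, a),
                 tolerance = 1e-6)
    expect_equal(fit$estimates$K_M_app, apparent_km(p, a), tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
  # zero-activator slice of MO recovers the unactivated constants
  dm <- generate_dataset(mical_params("MO"),
                        mical_design("MO", replicates = 1, noise_cv = 0))
  f0 <- fit_michaelis_menten(dm[dm$activator_uM == 0, ])
  expect_equal(f0$estimates$k_cat_app, 0.68, tolerance = 1e-6)
  expect_equal(f0$estimates$K_M_app, 28.8, tolerance = 1e-6)
})

test_that("substrate-independent data are flagged, not silently fitted", {
  d <- data.frame(substrate_uM = rep(c(10, 50, 150), each = 2),
                  activator_uM = 0, enzyme_uM = 0.6, replicate = 1:2,
                  velocity_uM_per_s = 1.0)
  fit <- fit_michaelis_menten(d)
  expect_false(fit$converged)
  expect_error(fit_michaelis_menten(d[d$substrate_uM < 50, ]), "3 distinct")
})

test_that("noisy apparent constants land within 2 SE of the species-fraction oracle", {
  p <- mical_params("MO-CH")
  d <- generate_dataset(p, mical_design("MO-CH", seed = 21))
  fit <- fit_michaelis_menten(d[d$activator_uM == 8, ])
  o <- oracle_apparent(1.7, 37.7, 10.5, 0.16, 7.43, A = 8)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$k_cat_app - o$k_cat_app),
            2 * fit$standard_errors$k_cat_app)
  expect_lt(abs(fit$estimates$K_M_app - o$K_M_app),
            2 * fit$standard_errors$K_M_app)
})

test_that("the global fit recovers noise-free parameters and honours fixed alpha", {
  p <- mical_params("MO-CH")
  d <- generate_dataset(p, mical_design("MO-CH", replicates = 1,
                                        noise_cv = 0))
  fit <- fit_global(d)
  expect_true(fit$converged)
  truth <- c(k_cat = 1.7, K_M = 37.7, K_act = 10.5, alpha = 0.16,
             beta = 7.43)
  for (nm in names(truth))
    expect_equal(fit$estimates[[nm]], unname(truth[nm]), tolerance = 1e-4)

  # alpha = 1 truth: pinning alpha must not cost residual sum of squares
  p1 <- mical_params("MO")
  d1 <- generate_dataset(p1, mical_design("MO", replicates = 1,
                                          noise_cv = 0))
  f_free <- fit_global(d1)
  f_fix <- fit_global(d1, fix_alpha = 1)
  expect_lt(abs(f_fix$rss - f_free$rss), 1e-8)
  expect_equal(f_fix$estimates$alpha, 1)
  expect_true(is.na(f_fix$standard_errors$alpha))
  expect_equal(f_fix$dof, f_free$dof + 1L)

  expect_error(fit_global(d1[d1$activator_uM == 0, ]), "activator levels")
})

test_that("the global fit is consistent: noisy alpha within 2 SE, exact as noise vanishes", {
  p <- mical_params("MO-CH")
  d <- generate_dataset(p, mical_design("MO-CH", seed = 33))
  fit <- fit_global(d)
  expect_lt(abs(fit$estimates$alpha - 0.16), 2 * fit$standard_errors$alpha)
  # estimator consistency: shrinking the noise collapses the error
  d_small <- generate_dataset(p, mical_design("MO-CH", noise_cv = 1e-4,
                                              seed = 33))
  fit_small <- fit_global(d_small)
  expect_equal(fit_small$estimates$alpha, 0.16, tolerance = 1e-2)
})

test_that("the extra-sum-of-squares F statistic and p-value match the density-integration oracle", {
  mk <- function(rss, dof, n, tag) {
    structure(list(estimates = list(), standard_errors = list(), rss = rss,
                   dof = dof, converged = TRUE, model_tag = tag,
                   n_points = n),
              class = "fit_result")
  }
  r <- mk(12, 18, 20, "global_alpha_fixed")
  f <- mk(10, 17, 20, "global_alpha_free")
  ft <- extra_ss_f_test(r, f)
  expect_equal(ft$f_statistic, 3.4)
  expect_equal(ft$df_num, 1L)
  expect_equal(ft$df_den, 17L)
  expect_equal(ft$p_value, oracle_f_pvalue(3.4, 1, 17), tolerance = 1e-8)

  # equal RSS: no evidence at all
  ft0 <- extra_ss_f_test(mk(10, 18, 20, "a"), mk(10, 17, 20, "b"))
  expect_equal(ft0$f_statistic, 0)
  expect_equal(ft0$p_value, 1)

  expect_error(extra_ss_f_test(mk(10, 17, 20, "a"), mk(9, 18, 20, "b")),
               "degrees of freedom")
  expect_error(extra_ss_f_test(mk(8, 18, 20, "a"), mk(10, 17, 20, "b")),
               "nested")
  expect_error(extra_ss_f_test(mk(10, 18, 21, "a"), mk(9, 17, 20, "b")),
               "same dataset")
})

test_that("parameter recovery over repeated campaigns is unbiased with honest intervals", {
  p <- mical_params("MO-CH")
  truth <- c(k_cat = 1.7, K_M = 37.7, K_act = 10.5, alpha = 0.16,
             beta = 7.43)
  n_sim <- 200
  est <- matrix(NA_real_, n_sim, 5, dimnames = list(NULL, names(truth)))
  cover <- matrix(NA, n_sim, 5, dimnames = list(NULL, names(truth)))
  for (s in seq_len(n_sim)) {
    d <- generate_dataset(p, mical_design("MO-CH", seed = 5000 + s))
    fit <- fit_global(d, n_starts = 2)
    for (nm in names(truth)) {
      est[s, nm] <- fit$estimates[[nm]]
      cover[s, nm] <- abs(fit$estimates[[nm]] - truth[nm]) <=
        2 * fit$standard_errors[[nm]]
    }
  }
  rel_bias <- abs(apply(est, 2, median) - truth) / truth
  expect_true(all(rel_bias < 0.05))
  expect_true(all(colMeans(cover) >= 0.85))
})

test_that("positive coupling shows up as monotonically decreasing fitted apparent K_M", {
  p <- mical_params("MO-CH")  # alpha = 0.16 < 1
  hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    d <- generate_dataset(p, mical_design("MO-CH", seed = 9000 + s))
    tab <- apparent_constant_table(d)
    if (all(diff(tab$K_M_app) < 0)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
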