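test_that("SEC calibration is exact on log-linear standards and robust to jitter", {
  # perfectly log-linear set: predictions at the standards are exact
  vo <- 8
  ratio <- c(1.0, 1.3, 1.6, 1.9, 2.2)
  masses <- 10^(8 - 2.2 * ratio)
  std <- data.frame(Ve_mL = ratio * vo, mass_Da = masses)
  cal <- sec_calibration(std, void_volume = vo)
  expect_equal(cal$slope, -2.2, tolerance = 1e-10)
  for (i in seq_len(5))
    expect_equal(sec_predict_mass(cal, std$Ve_mL[i])$mass, masses[i],
                 tolerance = 1e-9)

  # zero slope: constant prediction
  flat <- data.frame(Ve_mL = c(8, 10, 12), mass_Da = rep(5e4, 3))
  cal_flat <- sec_calibration(flat, void_volume = vo)
  expect_equal(sec_predict_mass(cal_flat, 11)$mass, 5e4, tolerance = 1e-9)

  # 1% elution-volume jitter: predictions agree exactly with a closed-form
  # least-squares oracle (normal equations) and track the truth to a few
  # percent in the typical draw
  set.seed(7)
  err <- replicate(20, {
    jit <- std
    jit$Ve_mL <- jit$Ve_mL * (1 + rnorm(5, 0, 0.01))
    calj <- sec_calibration(jit, void_volume = vo)
    x <- jit$Ve_mL / vo
    y <- log10(jit$mass_Da)
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    oracle <- 10^(a + b * 1.45)
    expect_equal(sec_predict_mass(calj, 1.45 * vo)$mass, oracle,
                 tolerance = 1e-9)
    truth <- 10^(8 - 2.2 * 1.45)
    abs(sec_predict_mass(calj, 1.45 * vo)$mass - truth) / truth
  })
  expect_lt(median(err), 0.05)

  expect_error(sec_calibration(std[1, ], vo), "2 standards")
  expect_warning(sec_predict_mass(cal, 30), "extrapolating")
})

test_that("the packaged synthetic standards give a usable calibration", {
  path <- system.file("extdata", "sec_standards_synthetic.tsv",
                      package = "micalkin")
  std <- read_sec_standards(path)
  expect_equal(nrow(std), 5)
  cal <- sec_calibration(std, void_volume = 8)
  expect_gt(cal$r_squared, 0.99)
  est <- sec_predict_mass(cal, 11.678, reference_mass = 68425)
  expect_equal(est$mass, 61455, tolerance = 0.05)
})

test_that("Guinier fitting recovers exact and near-Gaussian profiles", {
  q <- seq(0.005, 0.2, by = 0.002)
  # exact Guinier/Gaussian profile: recovery to machine-level accuracy
  prof <- scattering_profile(q, 7 * exp(-q^2 * 30^2 / 3))
  g <- guinier_fit(prof)
  expect_equal(g$I0, 7, tolerance = 1e-6)
  expect_equal(g$Rg, 30, tolerance = 1e-6)

  # uniform-sphere form factor: Rg within 2% of sqrt(3/5) * R
  profs <- scattering_profile(q, sphere_intensity(q, R = 30))
  gs <- guinier_fit(profs)
  expect_equal(gs$Rg, sqrt(3 / 5) * 30, tolerance = 0.02)

  # flat profile has no Guinier region
  expect_error(guinier_fit(scattering_profile(q, rep(2, length(q)))),
               "no Guinier region")
})

test_that("the correlation volume matches its closed form and is scale-invariant", {
  Rg <- 30; I0 <- 5
  q <- seq(0.002, 0.32, by = 0.001)
  prof <- scattering_profile(q, I0 * exp(-q^2 * Rg^2 / 3))
  vc <- correlation_volume(prof, I0 = I0, q_upper = 0.3)
  # analytic q-weighted Gaussian integral
  int <- 3 * I0 / (2 * Rg^2) * (1 - exp(-0.3^2 * Rg^2 / 3))
  expect_equal(vc, I0 / int, tolerance = 0.005)

  # intensity scale cancels
  prof10 <- scattering_profile(q, 10 * prof$intensity)
  expect_equal(correlation_volume(prof10, I0 = 10 * I0, q_upper = 0.3), vc,
               tolerance = 1e-9)

  # grid convergence: halving the step moves Vc by < 0.1%
  q2 <- seq(0.002, 0.32, by = 0.0005)
  prof2 <- scattering_profile(q2, I0 * exp(-q2^2 * Rg^2 / 3))
  vc2 <- correlation_volume(prof2, I0 = I0, q_upper = 0.3)
  expect_lt(abs(vc2 - vc) / vc, 0.001)

  expect_error(correlation_volume(prof, I0 = I0, q_upper = 1), "q range")
})

test_that("mass estimators implement their defining relations", {
  # volume-of-correlation relation and its scaling laws
  est <- mass_from_vc(250, 31)
  expect_equal(est$mass, (250^2 / 31) / 1.231)
  expect_equal(mass_from_vc(500, 31)$mass, 4 * est$mass)
  expect_equal(mass_from_vc(250, 31e6)$mass, est$mass / 1e6)
  expect_error(mass_from_vc(-1, 31), "positive")

  # forward-scattering ratio: identity and linearity
  expect_equal(mass_from_i0_ratio(10, 2, 10, 2, 132000)$mass, 132000)
  expect_equal(mass_from_i0_ratio(5, 2, 10, 2, 132000)$mass, 66000)
  # ideal forward simulation I0 = k * mass * conc recovers the sample mass
  k <- 0.037
  est2 <- mass_from_i0_ratio(I0_sample = k * 68425 * 4.0, conc_sample = 4.0,
                             I0_standard = k * 132000 * 2.0,
                             conc_standard = 2.0, mass_standard = 132000)
  expect_equal(est2$mass, 68425)
  expect_error(mass_from_i0_ratio(1, 0, 1, 1, 1), "positive")

  # percent deviation reproduces the reported solution-mass deviations
  expect_equal(round_half_up(percent_mass_deviation(61455, 68425)), -10.2)
  expect_equal(round_half_up(percent_mass_deviation(55000, 68425)), -19.6)
  expect_equal(percent_mass_deviation(5, 5), 0)
})

test_that("Debye toy profiles obey closed forms for degenerate point sets", {
  q <- seq(0.01, 0.5, by = 0.01)
  # single point scatters flat
  p1 <- toy_profile(matrix(0, 1, 3), q)
  expect_equal(p1$intensity, rep(1, length(q)))
  expect_equal(coordinate_rg(matrix(0, 1, 3)), 0)

  # two points at distance d: I(q) = 2 (1 + sin(qd)/(qd)), Rg = d/2
  d <- 12
  pts <- rbind(c(0, 0, 0), c(d, 0, 0))
  p2 <- toy_profile(pts, q)
  expect_equal(p2$intensity, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  expect_equal(coordinate_rg(pts), d / 2)

  expect_error(toy_profile(matrix(numeric(0), 0, 3), q), "at least one")
})

test_that("sphere point clouds round-trip: coordinate Rg vs Guinier Rg", {
  rg_ball <- sqrt(3 / 5) * 30
  pts <- ball_points(10000, radius = 30, seed = 5)
  rg_c <- coordinate_rg(pts)
  expect_equal(rg_c, rg_ball, tolerance = 0.01)

  q <- seq(0.005, 0.12, by = 0.0025)
  prof <- toy_profile(pts, q)  # histogram path at this size
  g <- guinier_fit(prof)
  expect_equal(g$Rg, rg_c, tolerance = 0.02)

  # histogram evaluation agrees with the exact pair sum
  pts_s <- ball_points(800, radius = 30, seed = 6)
  exact <- toy_profile(pts_s, q, exact_limit = 2000)
  binned <- toy_profile(pts_s, q, exact_limit = 1)
  expect_equal(binned$intensity, exact$intensity, tolerance = 1e-3)
})

test_that("random toy clouds keep Guinier and coordinate Rg within 3%", {
  q <- seq(0.004, 0.1, by = 0.002)
  set.seed(31)
  for (i in 1:5) {
    pts <- matrix(rnorm(3 * 600, sd = runif(1, 8, 20)), ncol = 3)
    rg_c <- coordinate_rg(pts)
    g <- guinier_fit(toy_profile(pts, q), qmax_rg = 1.3)
    expect_equal(g$Rg, rg_c, tolerance = 0.03)
  }
})
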