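#' Assay design: condition grid, replication and noise for synthetic data
#'
#' Describes a cuvette-assay campaign: the substrate and activator
#' concentration grids, the shared enzyme concentration, the number of
#' replicate measurements per condition, and the relative noise on replicate
#' velocities (multiplicative Gaussian, coefficient of variation
#' `noise_cv`). Defaults for the two construct designs are available through
#' [mical_design()].
#'
#' @param substrate_levels strictly increasing NADPH levels, uM, >= 0.
#' @param activator_levels strictly increasing F-actin levels, uM, >= 0.
#' @param enzyme_conc total enzyme, uM (> 0).
#' @param replicates replicate velocities per condition (>= 1).
#' @param noise_cv coefficient of variation of replicate velocities (>= 0).
#' @param seed integer seed controlling replicate noise.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(substrate_levels, activator_levels,
                         enzyme_conc = 0.6, replicates = 3,
                         noise_cv = 0.03, seed = 1L) {
  stopifnot(is.numeric(substrate_levels), is.numeric(activator_levels),
            length(substrate_levels) >= 1L, length(activator_levels) >= 1L)
  if (any(substrate_levels < 0) || any(activator_levels < 0))
    stop("concentration levels must be non-negative", call. = FALSE)
  if (is.unsorted(substrate_levels, strictly = TRUE) ||
      is.unsorted(activator_levels, strictly = TRUE))
    stop("levels must be strictly increasing", call. = FALSE)
  if (enzyme_conc <= 0) stop("enzyme_conc must be > 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(
    list(substrate_levels = as.numeric(substrate_levels),
         activator_levels = as.numeric(activator_levels),
         enzyme_conc = enzyme_conc,
         replicates = as.integer(replicates),
         noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "assay_design"
  )
}

#' Published assay designs for the two MICAL constructs
#'
#' The MO campaign used six NADPH levels (3-100 uM) against five F-actin
#' levels (0-7.5 uM); the MO-CH campaign five NADPH levels (10-150 uM)
#' against four F-actin levels (0-8 uM); both at 600 nM enzyme with 3-4
#' replicates per condition. The MO activator grid stores 0.45 uM for its
#' second level, matching the summary-table column header.
#'
#' @param construct `"MO"` or `"MO-CH"`.
#' @param replicates replicates per condition (default 3).
#' @param noise_cv velocity coefficient of variation (default 0.03).
#' @param seed integer seed.
#' @return An [assay_design] object.
#' @export
mical_design <- function(construct = c("MO", "MO-CH"), replicates = 3,
                         noise_cv = 0.03, seed = 1L) {
  construct <- match.arg(construct)
  if (construct == "MO") {
    assay_design(substrate_levels = c(3, 6, 12.5, 25, 50, 100),
                 activator_levels = c(0, 0.45, 0.9, 2.2, 7.5),
                 enzyme_conc = 0.6, replicates = replicates,
                 noise_cv = noise_cv, seed = seed)
  } else {
    assay_design(substrate_levels = c(10, 25, 50, 100, 150),
                 activator_levels = c(0, 2, 4, 8),
                 enzyme_conc = 0.6, replicates = replicates,
                 noise_cv = noise_cv, seed = seed)
  }
}

# Deterministic per-condition substream seed from a campaign seed.
# Keeps generated replicates independent of grid iteration order and of the
# caller's RNG state; constants are arbitrary coprime multipliers.
condition_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

# Evaluate a function with the global RNG state saved and restored, so
# package internals that need reproducible draws do not disturb the caller.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an absorbance-vs-time progress trace
#'
#' Integrates substrate depletion `dS/dt = -v(S, A)` under the
#' non-essential-activator rate law with a fixed-step classical Runge-Kutta
#' scheme and converts to absorbance at 340 nm through the NADPH extinction
#' coefficient (default 6220 M^-1 cm^-1, 1 cm path). The activator is held
#' constant unless `deplete_activator` is set, in which case it is consumed
#' stoichiometrically with the substrate (`nadph_per_site` NADPH per
#' activator site, default 1:1), reproducing the early downward curvature
#' seen in traces where the activator is exhausted within the read window.
#'
#' @param params a [kinetic_params] object.
#' @param cond an [assay_condition] (scalar concentrations).
#' @param duration total simulated time, s (> 0).
#' @param dt integration/sampling step, s (> 0, < duration).
#' @param noise_sd_abs Gaussian absorbance noise SD, AU (>= 0).
#' @param deplete_activator consume activator with turnover?
#' @param nadph_per_site NADPH oxidised per activator site consumed.
#' @param epsilon340 extinction coefficient, M^-1 cm^-1.
#' @param path_cm optical path length, cm.
#' @param offset_abs constant absorbance offset, AU.
#' @param seed integer seed for the absorbance noise.
#' @return An object of class `progress_trace`: a list with `times` (s),
#'   `absorbance` (AU), the noise-free `absorbance_true`, and the generating
#'   parameters/condition for provenance.
#' @export
simulate_trace <- function(params, cond, duration = 30, dt = 0.05,
                           noise_sd_abs = 0, deplete_activator = FALSE,
                           nadph_per_site = 1, epsilon340 = 6220,
                           path_cm = 1, offset_abs = 0, seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "assay_condition"),
            length(cond$substrate_conc) == 1L,
            length(cond$activator_conc) == 1L)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt >= duration) stop("dt must be smaller than duration", call. = FALSE)
  if (noise_sd_abs < 0) stop("noise_sd_abs must be >= 0", call. = FALSE)

  times <- seq(0, duration, by = dt)
  # one validated condition object, mutated cheaply inside the integrator
  cond_t <- assay_condition(cond$substrate_conc, cond$activator_conc,
                            cond$enzyme_conc)
  rhs <- function(t, y, parms) {
    cond_t$substrate_conc <- max(y[["S"]], 0)
    cond_t$activator_conc <- max(y[["A"]], 0)
    v <- velocity(params, cond_t)
    dA <- if (deplete_activator) -v / nadph_per_site else 0
    list(c(S = -v, A = dA))
  }
  y0 <- c(S = cond$substrate_conc, A = cond$activator_conc)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "rk4")
  S_t <- pmax(out[, "S"], 0)
  # uM -> M, times M^-1 cm^-1 and cm path
  abs_true <- epsilon340 * path_cm * S_t * 1e-6 + offset_abs
  absorbance <- abs_true
  if (noise_sd_abs > 0) {
    noise <- with_local_seed(seed, stats::rnorm(length(times), 0, noise_sd_abs))
    absorbance <- abs_true + noise
  }
  structure(
    list(times = times, absorbance = absorbance, absorbance_true = abs_true,
         substrate = S_t, activator = pmax(out[, "A"], 0),
         params = params, condition = cond,
         epsilon340 = epsilon340, path_cm = path_cm),
    class = "progress_trace"
  )
}

#' Initial rate from a progress trace
#'
#' Ordinary least-squares slope of absorbance against time inside the read
#' window (default 5-10 s, the interval used once mixing has settled but
#' before substrate or activator depletion bends the trace), converted to a
#' velocity through the extinction coefficient and path length. Small
#' negative estimates within 3 SE of zero are clipped to zero with a
#' warning; larger negative slopes are returned as-is (they indicate a
#' genuinely rising trace, not noise).
#'
#' @param trace a `progress_trace` from [simulate_trace()] (or a list with
#'   `times`, `absorbance`, `epsilon340`, `path_cm`).
#' @param window numeric `c(t_start, t_end)` in seconds.
#' @param epsilon340,path_cm conversion constants; default taken from the
#'   trace itself.
#' @return Initial velocity, uM/s.
#' @export
extract_initial_rate <- function(trace, window = c(5, 10),
                                 epsilon340 = trace$epsilon340,
                                 path_cm = trace$path_cm) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  keep <- trace$times >= window[1] & trace$times <= window[2]
  if (!any(keep)) stop("no samples fall inside the read window", call. = FALSE)
  if (sum(keep) < 3L)
    stop("need at least 3 samples in the read window", call. = FALSE)
  t <- trace$times[keep]
  a <- trace$absorbance[keep]
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (a - mean(a))) / sxx
  rss <- sum((a - mean(a) - slope * (t - mean(t)))^2)
  se <- sqrt(rss / (length(t) - 2) / sxx)
  rate <- -slope / (epsilon340 * path_cm * 1e-6)  # AU/s -> uM/s
  if (rate < 0) {
    rate_se <- se / (epsilon340 * path_cm * 1e-6)
    if (rate > -3 * rate_se) {
      warning("negative initial-rate estimate within noise; clipped to 0",
              call. = FALSE)
      rate <- 0
    }
  }
  rate
}

#' Generate a replicate initial-rate dataset over an assay design
#'
#' For each (substrate, activator) pair of the design, draws `replicates`
#' velocities around the closed-form rate-law velocity with multiplicative
#' Gaussian noise of the design's coefficient of variation, emulating the
#' roughly constant relative scatter of replicate initial rates in cuvette
#' assays. Each condition uses its own deterministic substream of the design
#' seed, so datasets are reproducible and independent of grid order. Draws
#' are truncated at zero (velocities are non-negative by construction).
#'
#' @param params a [kinetic_params] object (ground truth).
#' @param design an [assay_design].
#' @return A data.frame of class `assay_dataset` with columns
#'   `substrate_uM`, `activator_uM`, `enzyme_uM`, `replicate`,
#'   `velocity_uM_per_s`; summarise with [summarise_dataset()].
#' @export
generate_dataset <- function(params, design) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "assay_design"))
  grid <- expand.grid(substrate_uM = design$substrate_levels,
                      activator_uM = design$activator_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    S <- grid$substrate_uM[i]
    A <- grid$activator_uM[i]
    v0 <- velocity(params, assay_condition(S, A, design$enzyme_conc))
    if (design$noise_cv > 0) {
      eps <- with_local_seed(condition_seed(design$seed, i),
                             stats::rnorm(design$replicates, 0,
                                          design$noise_cv))
      v <- pmax(v0 * (1 + eps), 0)
    } else {
      v <- rep(v0, design$replicates)
    }
    rows[[i]] <- data.frame(substrate_uM = S, activator_uM = A,
                            enzyme_uM = design$enzyme_conc,
                            replicate = seq_len(design$replicates),
                            velocity_uM_per_s = v)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assay_dataset", "data.frame")
  attr(out, "seed") <- design$seed
  out
}

#' Per-condition mean and SEM of an assay dataset
#'
#' @param dataset an `assay_dataset` (or any data.frame with the same
#'   columns).
#' @return A data.frame with one row per condition: replicate count, mean
#'   velocity, and SEM (NA when a condition has a single replicate).
#' @export
summarise_dataset <- function(dataset) {
  stopifnot(all(c("substrate_uM", "activator_uM", "velocity_uM_per_s") %in%
                  names(dataset)))
  key <- interaction(dataset$substrate_uM, dataset$activator_uM, drop = TRUE)
  agg <- lapply(split(dataset, key), function(d) {
    n <- nrow(d)
    data.frame(substrate_uM = d$substrate_uM[1],
               activator_uM = d$activator_uM[1],
               enzyme_uM = d$enzyme_uM[1],
               n = n,
               mean_velocity = mean(d$velocity_uM_per_s),
               sem_velocity = if (n >= 2)
                 stats::sd(d$velocity_uM_per_s) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$activator_uM, out$substrate_uM), ]
  rownames(out) <- NULL
  out
}

#' Generate a dataset by simulating and reading full progress traces
#'
#' Slower, trace-level counterpart of [generate_dataset()]: each condition
#' is simulated as an absorbance trace and its velocity read back with
#' [extract_initial_rate()], exercising the whole measurement pipeline
#' rather than perturbing closed-form velocities.
#'
#' @inheritParams generate_dataset
#' @param duration,dt,noise_sd_abs,window passed to [simulate_trace()] and
#'   [extract_initial_rate()]. `window` may also be a function
#'   `f(substrate_uM, activator_uM)` returning `c(t_start, t_end)`, so that
#'   fast-turnover conditions can be read over a window short enough that
#'   substrate depletion does not bend the trace.
#' @return An `assay_dataset` data.frame (see [generate_dataset()]).
#' @export
generate_dataset_from_traces <- function(params, design, duration = 12,
                                         dt = 0.05, noise_sd_abs = 0,
                                         window = c(5, 10)) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(design, "assay_design"))
  grid <- expand.grid(substrate_uM = design$substrate_levels,
                      activator_uM = design$activator_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * design$replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    win_i <- if (is.function(window))
      window(grid$substrate_uM[i], grid$activator_uM[i]) else window
    dur_i <- max(duration, win_i[2] * 1.2)
    dt_i <- min(dt, diff(win_i) / 20)
    for (r in seq_len(design$replicates)) {
      k <- k + 1L
      tr <- simulate_trace(params,
                           assay_condition(grid$substrate_uM[i],
                                           grid$activator_uM[i],
                                           design$enzyme_conc),
                           duration = dur_i, dt = dt_i,
                           noise_sd_abs = noise_sd_abs,
                           seed = condition_seed(design$seed,
                                                 i * 1000L + r))
      rows[[k]] <- data.frame(substrate_uM = grid$substrate_uM[i],
                              activator_uM = grid$activator_uM[i],
                              enzyme_uM = design$enzyme_conc,
                              replicate = r,
                              velocity_uM_per_s =
                                extract_initial_rate(tr, window = win_i))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assay_dataset", "data.frame")
  attr(out, "seed") <- design$seed
  out
}
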