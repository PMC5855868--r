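# Seeded generators of synthetic chemosensor-array data.  Two designs are
# emulated: a single-batch "wound headspace" style dataset (4 classes x 20
# observations x 15 sensors, scalar feature = response maximum) and a
# multi-batch "inflammable gas" style dataset (4 gases x 10 concentrations
# over 5 drifting batches x 8 sensors, scalar feature = response minimum).
# Sensor response curves follow a rise-plateau-decay envelope with a
# saturating concentration nonlinearity, the usual abstraction of
# metal-oxide sensor dynamics.

#' Labeled chemosensor dataset container
#'
#' @param X Numeric feature matrix, rows = observations.
#' @param labels Class labels, one per row.
#' @param batch Optional batch ids, one per row.
#' @param meta Optional list of generator parameters / provenance.
#' @return Object of class `enose_dataset` with fields `X`, `labels`
#'   (factor), `batch`, `meta`.
#' @export
enose_dataset <- function(X, labels, batch = NULL, meta = list()) {
  X <- .as_sample_matrix(X)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(X)) stop2("one label per row required")
  if (any(table(labels) == 0)) stop2("every class must be nonempty")
  if (!is.null(batch)) {
    if (length(batch) != nrow(X)) stop2("one batch id per row required")
    batch <- as.factor(batch)
  }
  structure(list(X = X, labels = labels, batch = batch, meta = meta),
            class = "enose_dataset")
}

#' @export
print.enose_dataset <- function(x, ...) {
  cat(sprintf("<enose_dataset: %d observations x %d sensors, %d class(es)%s>\n",
              nrow(x$X), ncol(x$X), nlevels(x$labels),
              if (is.null(x$batch)) ""
              else sprintf(", %d batch(es)", nlevels(x$batch))))
  print(table(class = x$labels))
  invisible(x)
}

#' @export
as.data.frame.enose_dataset <- function(x, ...) {
  df <- as.data.frame(x$X)
  df$label <- as.character(x$labels)
  if (!is.null(x$batch)) df$batch <- as.character(x$batch)
  df
}

# saturating concentration nonlinearities g(c)
.concentration_response <- function(concentration, nonlinearity) {
  if (any(concentration < 0)) stop2("negative concentration")
  switch(nonlinearity,
    log = log1p(concentration),
    power = concentration^0.6,
    `sigmoid-saturation` = 2 / (1 + exp(-concentration)) - 1,
    stop2("unknown nonlinearity '", nonlinearity, "'"))
}

# rise-plateau-decay envelope; peaks at exactly 1 on the plateau
.response_envelope <- function(n_time, t_rise, t_fall, decay_rate) {
  t <- seq_len(n_time)
  env <- pmin(t / t_rise, 1)
  decay <- exp(-pmax(t - t_fall, 0) * decay_rate)
  env * decay
}

#' Simulate sensor response curves for one exposure
#'
#' Each sensor follows `baseline + s * gain * g(concentration) * env(t) +
#' noise`, where `env` rises linearly to a plateau at 1 and decays
#' exponentially after washout, `g` is the configured saturating
#' nonlinearity, and `s` is +1 for conductance-increase (`mode = "rise"`)
#' or -1 for conductance-decrease (`mode = "dip"`) sensors.  With zero
#' noise the above-baseline plateau equals `gain * g(concentration)`
#' exactly, and a zero concentration gives a flat baseline.
#'
#' @param gains Positive per-sensor gain vector.
#' @param concentration Analyte concentration (>= 0).
#' @param baseline Baseline response level; default 0.2.
#' @param nonlinearity `"log"` (default), `"power"` or
#'   `"sigmoid-saturation"`.
#' @param noise_sd Per-timepoint gaussian noise SD; default 0.
#' @param n_time Number of timepoints; default 50.
#' @param t_rise,t_fall Rise end / washout start timepoints.
#' @param decay_rate Post-washout exponential decay rate.
#' @param mode `"rise"` or `"dip"`.
#' @param seed Optional seed.
#' @return `n_time` x `length(gains)` matrix of responses.
#' @export
simulate_response_curve <- function(gains, concentration, baseline = 0.2,
                                    nonlinearity = "log", noise_sd = 0,
                                    n_time = 50, t_rise = 10, t_fall = 35,
                                    decay_rate = 0.05,
                                    mode = c("rise", "dip"), seed = NULL) {
  mode <- match.arg(mode)
  if (any(gains < 0)) stop2("gains must be nonnegative")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  g <- .concentration_response(concentration, nonlinearity)
  env <- .response_envelope(n_time, t_rise, t_fall, decay_rate)
  sgn <- if (mode == "rise") 1 else -1
  with_seed(seed, {
    curves <- baseline + sgn * outer(env, gains * g)
    if (noise_sd > 0)
      curves <- curves + matrix(stats::rnorm(length(curves), 0, noise_sd),
                                nrow = n_time)
    curves
  })
}

#' Extract the scalar per-sensor feature from a response curve
#'
#' The standard steady-state summaries: the maximum of each sensor's
#' series for conductance-increase responses, or the minimum for
#' conductance-decrease responses.
#'
#' @param curve Matrix (timepoints x sensors) or a single series.
#' @param mode `"max"` or `"min"`.
#' @return Numeric vector, one feature per sensor.
#' @export
extract_scalar_feature <- function(curve, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (is.vector(curve)) curve <- matrix(curve, ncol = 1)
  if (nrow(curve) == 0 || length(curve) == 0) stop2("empty response curve")
  apply(curve, 2, if (mode == "max") max else min)
}

#' Configuration of the wound-headspace-style generator
#'
#' Study conditions for the single-batch design: `n_classes` odor classes
#' (four wound states in the motivating application) with
#' `samples_per_class` observations over `n_sensors` sensors.  The last
#' two classes share a mean response profile and differ only in the
#' radius of a spherical shell around it (`radius`), so the dataset is
#' not linearly separable by construction: that pair can only be told
#' apart through a nonlinear decision surface.  Remaining classes get
#' distinct sinusoidal gain profiles with isotropic within-class spread
#' (`within_sd`).  A per-observation log-normal intensity factor
#' (`intensity_sd`) emulates uncontrolled headspace concentration
#' variation.
#'
#' @param n_sensors,n_classes,samples_per_class Design shape; defaults
#'   15 / 4 / 20 (an 80 x 15 feature matrix).
#' @param noise_sd Per-timepoint response noise SD; default 0.05.
#' @param within_sd Within-class gain spread for the mean-separated
#'   classes; default 0.25.
#' @param radius Shell radii of the two concentric classes; default
#'   `c(0.35, 1.4)`.
#' @param radius_jitter Log-normal SD of the per-sample radius; default 0.1.
#' @param intensity_sd Log-normal SD of the global intensity factor;
#'   default 0.05.
#' @param n_nuisance Number of additive class-independent interference
#'   factors (correlated baseline/environmental variation with fixed
#'   random sensor loadings); default 3.
#' @param nuisance_sd SD of each interference factor; default 0.6.
#' @param nonlinearity Concentration nonlinearity of the response model.
#' @param concentration Common analyte concentration fed through the
#'   nonlinearity; default `exp(1) - 1` so the log response equals 1.
#' @return Object of class `sensor_model_config`.
#' @export
wound_sensor_config <- function(n_sensors = 15, n_classes = 4,
                                samples_per_class = 20, noise_sd = 0.05,
                                within_sd = 0.25, radius = c(0.35, 1.4),
                                radius_jitter = 0.1, intensity_sd = 0.05,
                                n_nuisance = 3, nuisance_sd = 0.6,
                                nonlinearity = "log",
                                concentration = exp(1) - 1) {
  if (n_classes < 2) stop2("need at least two classes")
  if (noise_sd < 0 || within_sd < 0 || intensity_sd < 0)
    stop2("spread parameters must be >= 0")
  if (length(radius) != 2 || any(radius <= 0))
    stop2("`radius` must be two positive shell radii")
  structure(list(n_sensors = as.integer(n_sensors),
                 n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 noise_sd = noise_sd, within_sd = within_sd,
                 radius = radius, radius_jitter = radius_jitter,
                 intensity_sd = intensity_sd,
                 n_nuisance = as.integer(n_nuisance),
                 nuisance_sd = nuisance_sd,
                 nonlinearity = nonlinearity,
                 concentration = concentration),
            class = "sensor_model_config")
}

# Class mean gain profiles: distinct sinusoids for classes 1..C-2, one
# shared profile for the concentric pair (classes C-1 and C).
.wound_profiles <- function(C, p) {
  s <- seq_len(p) / p
  prof <- matrix(0, C, p)
  for (cl in seq_len(max(C - 2, 0)))
    prof[cl, ] <- 1.8 + 0.7 * sin(2 * pi * (s + (cl - 1) / C))
  shared <- 1.8 + 0.5 * cos(2 * pi * s)
  if (C >= 2) {
    prof[C - 1, ] <- shared
    prof[C, ] <- shared
  }
  prof
}

#' Simulate a wound-headspace-style dataset
#'
#' Generates the single-batch design described in
#' [wound_sensor_config()]: per observation, a per-sensor gain vector is
#' drawn from the class geometry (mean-separated profiles, or a
#' spherical shell for the final, deliberately non-linearly-separable
#' class pair), response curves are simulated, and the per-sensor
#' response maximum is extracted as the scalar feature.  Default shape:
#' 80 observations x 15 sensors, 4 balanced classes.
#'
#' @param config A [wound_sensor_config()].
#' @param seed Optional seed; the same seed reproduces the dataset
#'   exactly.
#' @return An [enose_dataset()]; `meta` records the generator parameters
#'   and the class geometry.
#' @export
simulate_wound_dataset <- function(config = wound_sensor_config(),
                                   seed = NULL) {
  if (!inherits(config, "sensor_model_config"))
    stop2("`config` must come from wound_sensor_config()")
  C <- config$n_classes
  p <- config$n_sensors
  npc <- config$samples_per_class
  prof <- .wound_profiles(C, p)
  with_seed(seed, {
    # fixed loadings of the class-independent interference factors
    L <- if (config$n_nuisance > 0) {
      Lm <- matrix(stats::rnorm(p * config$n_nuisance), p)
      apply(Lm, 2, function(v) v / sqrt(sum(v^2)))
    }
    N <- C * npc
    X <- matrix(0, N, p)
    labels <- factor(rep(paste0("class_", seq_len(C)), each = npc))
    row <- 0L
    for (cl in seq_len(C)) {
      for (j in seq_len(npc)) {
        row <- row + 1L
        if (cl >= C - 1) {            # concentric shell pair
          u <- stats::rnorm(p)
          u <- u / sqrt(sum(u^2))
          r <- config$radius[cl - (C - 2)] *
            exp(stats::rnorm(1, 0, config$radius_jitter))
          gains <- prof[cl, ] + r * u
        } else {
          gains <- prof[cl, ] + stats::rnorm(p, 0, config$within_sd)
        }
        gains <- gains * exp(stats::rnorm(1, 0, config$intensity_sd))
        gains <- pmax(gains, 0.05)
        curves <- simulate_response_curve(
          gains, config$concentration, nonlinearity = config$nonlinearity,
          noise_sd = config$noise_sd, mode = "rise")
        feat <- extract_scalar_feature(curves, "max")
        if (config$n_nuisance > 0)
          feat <- feat + drop(L %*% stats::rnorm(config$n_nuisance, 0,
                                                 config$nuisance_sd))
        X[row, ] <- feat
      }
    }
    colnames(X) <- paste0("sensor_", seq_len(p))
    enose_dataset(X, labels,
                  meta = list(generator = "wound", config = unclass(config),
                              seed = seed,
                              note = paste("classes", C - 1, "and", C,
                                           "are concentric shells (not",
                                           "linearly separable)")))
  })
}

#' Configuration of the drifting multi-batch gas generator
#'
#' Study conditions for the multi-batch design: `n_gases` analytes at
#' `concentration_levels` concentrations measured by `n_sensors` sensors
#' across `n_batches` nominally identical device batches.  Each batch
#' applies a per-sensor multiplicative gain perturbation
#' (`1 + N(0, drift_gain_sd)`) and additive baseline offset
#' (`N(0, drift_offset_sd)`) relative to the reference batch (batch 1,
#' which is unperturbed); the `high_drift_batch` receives
#' `high_drift_mult` times both SDs, emulating one severely drifted
#' device.
#'
#' @param n_sensors,n_gases,n_batches,samples_per_batch Design shape;
#'   defaults 8 / 4 / 5 / 128 (a 640 x 8 feature matrix).
#' @param concentration_levels Concentrations cycled within each gas;
#'   default 10 evenly spaced levels from 10 to 100.
#' @param noise_sd Per-timepoint response noise SD; default 0.02.
#' @param within_sd Multiplicative per-sample gain jitter SD; default 0.12.
#' @param drift_gain_sd,drift_offset_sd Per-batch drift SDs; defaults 0.04.
#' @param high_drift_batch Index of the severely drifted batch; default
#'   the last batch.
#' @param high_drift_mult Drift-SD multiplier for that batch; default 5.
#' @param nonlinearity Concentration nonlinearity; default `"log"`.
#' @return Object of class `sensor_model_config`.
#' @export
drift_sensor_config <- function(n_sensors = 8, n_gases = 4, n_batches = 5,
                                samples_per_batch = 128,
                                concentration_levels = seq(10, 100,
                                                           length.out = 10),
                                noise_sd = 0.02, within_sd = 0.12,
                                drift_gain_sd = 0.04,
                                drift_offset_sd = 0.04,
                                high_drift_batch = NULL,
                                high_drift_mult = 5,
                                nonlinearity = "log") {
  if (n_batches < 2) stop2("need at least two batches")
  if (any(concentration_levels < 0)) stop2("negative concentration")
  structure(list(n_sensors = as.integer(n_sensors),
                 n_gases = as.integer(n_gases),
                 n_batches = as.integer(n_batches),
                 samples_per_batch = as.integer(samples_per_batch),
                 concentration_levels = concentration_levels,
                 noise_sd = noise_sd, within_sd = within_sd,
                 drift_gain_sd = drift_gain_sd,
                 drift_offset_sd = drift_offset_sd,
                 high_drift_batch = as.integer(high_drift_batch %||%
                                                 n_batches),
                 high_drift_mult = high_drift_mult,
                 nonlinearity = nonlinearity),
            class = "sensor_model_config")
}

# distinct positive gas gain profiles over the sensor array
.gas_profiles <- function(G, p) {
  s <- seq_len(p) / p
  prof <- matrix(0, G, p)
  for (g in seq_len(G))
    prof[g, ] <- 1.2 + 0.3 * sin(2 * pi * (s + (g - 1) / G)) +
      0.1 * (g - 1) / G
  prof
}

#' Simulate a drifting multi-batch gas dataset
#'
#' Generates the multi-batch design of [drift_sensor_config()]: each
#' batch measures every gas at the configured concentration levels with
#' conductance-decrease sensors, the per-sensor response minimum is
#' extracted as the scalar feature, and batch-specific gain/offset
#' perturbations inject calibration drift (strongest in the designated
#' high-drift batch).  Default shape: 640 observations x 8 sensors over
#' 5 batches of 128.
#'
#' @param config A [drift_sensor_config()].
#' @param seed Optional seed.
#' @return An [enose_dataset()] with `batch` labels `1..n_batches`;
#'   `meta` records the drawn per-batch drift parameters.
#' @export
simulate_drift_dataset <- function(config = drift_sensor_config(),
                                   seed = NULL) {
  if (!inherits(config, "sensor_model_config"))
    stop2("`config` must come from drift_sensor_config()")
  G <- config$n_gases
  p <- config$n_sensors
  B <- config$n_batches
  npb <- config$samples_per_batch
  per_gas <- npb %/% G
  if (per_gas < 1) stop2("samples_per_batch too small for the gas count")
  prof <- .gas_profiles(G, p)
  with_seed(seed, {
    # per-batch drift draws (batch 1 is the unperturbed reference)
    gain_mult <- matrix(1, B, p)
    offset <- matrix(0, B, p)
    for (b in seq_len(B)[-1]) {
      mult <- if (b == config$high_drift_batch) config$high_drift_mult else 1
      gain_mult[b, ] <- 1 + stats::rnorm(p, 0, mult * config$drift_gain_sd)
      offset[b, ] <- stats::rnorm(p, 0, mult * config$drift_offset_sd)
    }
    gain_mult <- pmax(gain_mult, 0.05)
    N <- B * npb
    X <- matrix(0, N, p)
    labels <- character(N)
    batch <- integer(N)
    row <- 0L
    for (b in seq_len(B)) {
      for (g in seq_len(G)) {
        conc <- rep_len(config$concentration_levels, per_gas)
        extra <- if (g == G) npb - G * per_gas else 0L
        if (extra > 0)
          conc <- c(conc, rep_len(config$concentration_levels, extra))
        for (cc in conc) {
          row <- row + 1L
          gains <- prof[g, ] *
            (1 + stats::rnorm(p, 0, config$within_sd))
          gains <- pmax(gains * gain_mult[b, ], 0.01)
          curves <- simulate_response_curve(
            gains, cc, baseline = 5, nonlinearity = config$nonlinearity,
            noise_sd = config$noise_sd, mode = "dip")
          X[row, ] <- extract_scalar_feature(curves, "min") + offset[b, ]
          labels[row] <- paste0("gas_", g)
          batch[row] <- b
        }
      }
    }
    colnames(X) <- paste0("sensor_", seq_len(p))
    enose_dataset(X, factor(labels), batch = batch,
                  meta = list(generator = "drift", config = unclass(config),
                              seed = seed, gain_mult = gain_mult,
                              offset = offset))
  })
}
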