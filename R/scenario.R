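#' Define a synthetic calcium-imaging scenario
#'
#' A scenario is the full generative parameterization of a synthetic
#' recording: the spatial substrate (cells scattered on a square field), a
#' planted directed coupling graph, spontaneous event rates, propagation
#' kinetics, the calcium transient kernel, imaging noise, and a condition
#' scaling used to emulate experimental groups (sham vs. hypoxic
#' degradation). Identical scenario + seed yields bit-identical output at
#' every stage.
#'
#' Defaults mirror a confocal recording of a primary neuron-glial culture:
#' 2 Hz frame rate on a 420 x 420 um field, calcium oscillations lasting
#' several seconds at well under one event per minute per cell, and signal
#' propagation at a few tens of um/s so that delays between nearby cells
#' span roughly 2-10 s.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_size side of the square field of view, um.
#' @param sampling_rate frame rate, Hz.
#' @param duration recording length, s.
#' @param base_event_rate spontaneous event rate per cell, events/min.
#' @param silenced_fraction fraction of cells that never fire, in [0, 1].
#' @param coupling_probability probability that an ordered pair of cells
#'   within \code{connectivity_radius} is coupled.
#' @param connectivity_radius maximum distance (um) for candidate edges.
#' @param transmit_probability probability an event propagates along an edge.
#' @param propagation_speed calcium wave speed, um/s; an edge's delay is
#'   distance / speed plus jitter.
#' @param delay_jitter_sd standard deviation of Gaussian delay jitter, s
#'   (delays are truncated at 0).
#' @param refractory_period per-cell dead time after an accepted event, s;
#'   bounds transitive propagation cascades.
#' @param amplitude peak transient amplitude in dF/F units.
#' @param rise_tau,decay_tau transient kernel time constants, s
#'   (\code{decay_tau > rise_tau}).
#' @param baseline_f0 resting fluorescence, arbitrary units.
#' @param noise_sd imaging noise standard deviation as a fraction of
#'   \code{baseline_f0}.
#' @param bleach_rate optional linear photobleaching, fraction of baseline
#'   lost per second (0 disables).
#' @param condition_scaling named numeric vector with elements \code{rate}
#'   (multiplies \code{base_event_rate}), \code{transmit} (multiplies
#'   \code{transmit_probability}), \code{silenced_offset} (added to
#'   \code{silenced_fraction}) and optionally \code{speed} (multiplies
#'   \code{propagation_speed}); this is how condition presets act.
#' @param seed master integer seed; per-stage sub-seeds are derived from it
#'   deterministically so stages can be re-run independently.
#'
#' @return An object of class \code{"ca_scenario"}: a validated named list.
#' @seealso [sham_scenario()], [hypoxia_scenario()], [simulate_recording()]
#' @export
#' @examples
#' scn <- scenario(n_cells = 10, duration = 120, seed = 1)
#' scn$effective$event_rate
scenario <- function(n_cells = 30,
                     field_size = 420,
                     sampling_rate = 2,
                     duration = 600,
                     base_event_rate = 0.9,
                     silenced_fraction = 0,
                     coupling_probability = 0.02,
                     connectivity_radius = 200,
                     transmit_probability = 0.9,
                     propagation_speed = 20,
                     delay_jitter_sd = 0.1,
                     refractory_period = 2,
                     amplitude = 1.0,
                     rise_tau = 0.5,
                     decay_tau = 3,
                     baseline_f0 = 100,
                     noise_sd = 0.05,
                     bleach_rate = 0,
                     condition_scaling = c(rate = 1, transmit = 1,
                                           silenced_offset = 0, speed = 1),
                     seed = 1L) {
  scn <- list(
    n_cells = n_cells, field_size = field_size,
    sampling_rate = sampling_rate, duration = duration,
    base_event_rate = base_event_rate,
    silenced_fraction = silenced_fraction,
    coupling_probability = coupling_probability,
    connectivity_radius = connectivity_radius,
    transmit_probability = transmit_probability,
    propagation_speed = propagation_speed,
    delay_jitter_sd = delay_jitter_sd,
    refractory_period = refractory_period,
    amplitude = amplitude, rise_tau = rise_tau, decay_tau = decay_tau,
    baseline_f0 = baseline_f0, noise_sd = noise_sd,
    bleach_rate = bleach_rate,
    condition_scaling = condition_scaling,
    seed = as.integer(seed)
  )
  class(scn) <- "ca_scenario"
  validate_scenario(scn)
}

validate_scenario <- function(scn) {
  stop_scn <- function(msg) stop("invalid scenario: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  if (!num1(scn$n_cells) || scn$n_cells < 1 ||
      scn$n_cells != round(scn$n_cells))
    stop_scn("n_cells must be a positive integer")
  for (f in c("field_size", "sampling_rate", "duration", "propagation_speed",
              "rise_tau", "decay_tau", "baseline_f0", "amplitude",
              "refractory_period")) {
    if (!num1(scn[[f]]) || scn[[f]] <= 0)
      stop_scn(sprintf("%s must be strictly positive", f))
  }
  for (f in c("base_event_rate", "delay_jitter_sd", "noise_sd",
              "bleach_rate")) {
    if (!num1(scn[[f]]) || scn[[f]] < 0)
      stop_scn(sprintf("%s must be non-negative", f))
  }
  for (f in c("silenced_fraction", "coupling_probability",
              "transmit_probability")) {
    if (!num1(scn[[f]]) || scn[[f]] < 0 || scn[[f]] > 1)
      stop_scn(sprintf("%s must lie in [0, 1]", f))
  }
  if (scn$decay_tau <= scn$rise_tau)
    stop_scn("decay_tau must exceed rise_tau (well-formed transient)")
  cs <- scn$condition_scaling
  if (!is.numeric(cs) || !all(c("rate", "transmit", "silenced_offset")
                              %in% names(cs)))
    stop_scn(paste("condition_scaling needs named elements",
                   "rate, transmit, silenced_offset"))
  if (scn$duration * scn$sampling_rate < 2)
    stop_scn("recording must span at least 2 frames")

  speed_factor <- if ("speed" %in% names(cs)) cs[["speed"]] else 1
  if (speed_factor <= 0)
    stop_scn("condition_scaling['speed'] must be strictly positive")

  # effective (condition-scaled) parameters, clamped to valid ranges
  scn$effective <- list(
    event_rate = scn$base_event_rate * cs[["rate"]],
    transmit_probability = min(1, max(0, scn$transmit_probability *
                                        cs[["transmit"]])),
    silenced_fraction = min(1, max(0, scn$silenced_fraction +
                                     cs[["silenced_offset"]])),
    propagation_speed = scn$propagation_speed * speed_factor
  )
  scn
}

#' Condition presets
#'
#' `sham_scenario()` leaves all condition factors at 1 (healthy culture).
#' `hypoxia_scenario()` degrades the network the way delayed post-hypoxic
#' damage does: spontaneous event rate halved, propagation reliability
#' halved, an extra 30% of cells silenced, and calcium wave propagation
#' slowed to two thirds of its healthy speed (post-hypoxic cultures show a
#' markedly reduced signal delay rate). Both accept any [scenario()]
#' argument.
#'
#' @param ... arguments forwarded to [scenario()].
#' @return A \code{"ca_scenario"} object.
#' @export
sham_scenario <- function(...) {
  scenario(..., condition_scaling = c(rate = 1, transmit = 1,
                                      silenced_offset = 0, speed = 1))
}

#' @rdname sham_scenario
#' @export
hypoxia_scenario <- function(...) {
  scenario(..., condition_scaling = c(rate = 0.5, transmit = 0.5,
                                      silenced_offset = 0.3, speed = 0.67))
}

# Deterministic per-stage sub-seed from the master seed.  Stages: positions,
# graph, events, noise, movie.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(positions = 1L, graph = 2L, events = 3L, noise = 4L,
              movie = 5L)
  k <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' @export
print.ca_scenario <- function(x, ...) {
  cat(sprintf("ca_scenario: %d cells on %g x %g um, %g s at %g Hz (seed %d)\n",
              x$n_cells, x$field_size, x$field_size, x$duration,
              x$sampling_rate, x$seed))
  cat(sprintf("  events %.3g/min (eff), transmit %.2f (eff), silenced %.2f (eff)\n",
              x$effective$event_rate, x$effective$transmit_probability,
              x$effective$silenced_fraction))
  invisible(x)
}

#' Read a scenario from a JSON or YAML configuration file
#'
#' Flat keys matching [scenario()] arguments; unknown keys are rejected.
#'
#' @param path file ending in .json, .yaml or .yml.
#' @return A \code{"ca_scenario"} object.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported scenario config format: .", ext, call. = FALSE)
  )
  if (!is.null(cfg$condition_scaling))
    cfg$condition_scaling <- unlist(cfg$condition_scaling)
  known <- names(formals(scenario))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown scenario keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(scenario, cfg)
}
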