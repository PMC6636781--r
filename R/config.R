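# Configuration plumbing: every tunable of the engine and of the scenario
# generators lives in one flat registry of scalar keys with declared ranges,
# so that config files fail fast on unknown keys or out-of-range values and
# a fully resolved configuration can be echoed next to every run.

# defaults double as the calibration record: sizes and rates the in-silico
# experiments run at (see the methods vignette for the rationale)
sim_defaults <- function() {
  list(
    width = 50L, height = 50L,       # lattice (toroidal)
    occupancy = 0.1,                 # initial bacterial density
    moi = 1,                         # phage:bacteria ratio of the inoculum
    iterations = 100L,               # single-phase run length
    phase1_iterations = 10L,         # two-phase protocol: propagation phase
    phase2_antibiotic_iteration = 7L,
    total_iterations = 100L,
    n_sample = 500L,                 # virions sampled between the phases
    p_ads = 0.5,                     # adsorption prob. per co-located virion
    p_decay = 0.2,                   # free-virion decay per iteration: a
                                     # hostless pool dies out within the run
    p_death = 0.01,                  # intrinsic bacterial death
    max_age = Inf,
    cost = 0.05,                     # fitness cost per active resistance gene
    p_kill = 1.0,                    # kill prob. per exposed iteration ...
    drug_delay = 2L,                 # ... after this many tolerated exposures
    stress_on_exposure = 20,
    p_recomb = 1.0,                  # recombination prob. of injected cargo
    drug_duration = 10L,             # iterations an antibiotic dose persists
    L = 100L,                        # genome size in gene slots
    n_essential = 20L,
    n_accessory = 10L,
    marker_drug = "CAM",
    p_GT = 0.4,                      # transducing-particle probability
    p_lys = 0.8,                     # max lysogenization probability
    K_lys = 2,                       # half-saturation (local free virions)
    burst_size = 50L,
    headful = 10L,                   # capsid capacity in gene slots
    alpha = 1e5,                     # induction offset (spontaneous ~ 1e-5)
    kappa = 0.4,                     # induction stress sensitivity
    prophage_span = 10L,
    record = TRUE,
    record_classes = TRUE
  )
}

# key -> c(min, max) for numeric checks; NULL = no numeric range
config_ranges <- function() {
  list(
    width = c(1, Inf), height = c(1, Inf), occupancy = c(0, 1), moi = c(0, Inf),
    iterations = c(1, Inf), phase1_iterations = c(1, Inf),
    phase2_antibiotic_iteration = c(1, Inf), total_iterations = c(2, Inf),
    n_sample = c(0, Inf), p_ads = c(0, 1), p_decay = c(0, 1), p_death = c(0, 1),
    max_age = c(1, Inf), cost = c(0, 1 - 1e-12), p_kill = c(0, 1),
    drug_delay = c(0, Inf), stress_on_exposure = c(0, Inf), p_recomb = c(0, 1),
    drug_duration = c(1, Inf), L = c(1, Inf), n_essential = c(0, Inf),
    n_accessory = c(0, Inf), p_GT = c(0, 1), p_lys = c(0, 1), K_lys = c(0, Inf),
    burst_size = c(0, Inf), headful = c(0, Inf), alpha = c(1e-12, Inf),
    kappa = c(1e-12, Inf), prophage_span = c(1, Inf)
  )
}

check_scalars <- function(values) {
  ranges <- config_ranges()
  for (key in names(values)) {
    rng <- ranges[[key]]
    if (is.null(rng)) next
    v <- values[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < rng[1] || v > rng[2]) {
      stop(sprintf("configuration value out of range: %s = %s (allowed [%g, %g])",
                   key, format(values[[key]]), rng[1], rng[2]), call. = FALSE)
    }
  }
  invisible(values)
}

int_keys <- c("width", "height", "iterations", "phase1_iterations",
              "phase2_antibiotic_iteration", "total_iterations", "n_sample",
              "drug_delay", "drug_duration", "L", "n_essential", "n_accessory",
              "burst_size", "headful", "prophage_span")

resolve_scalars <- function(overrides) {
  defaults <- sim_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- modifyList(defaults, overrides)
  check_scalars(vals)
  for (k in int_keys) {
    if (is.finite(vals[[k]])) vals[[k]] <- as.integer(vals[[k]])
  }
  vals
}

#' Build a custom simulation configuration
#'
#' Assembles a single-phase run from strains, phage genotypes, founder
#' populations, a free-phage inoculum and an antibiotic schedule, on top of
#' the engine defaults. All scalar defaults can be overridden by name (see
#' `sim_defaults()` in the sources for the full list); unknown keys are
#' rejected.
#'
#' @param strains list of [strain_spec()] objects.
#' @param genotypes list of [phage_genotype()] objects (ids must be `1..n`).
#' @param populations list of `list(strain =, n =)` founder blocks.
#' @param inoculum `list(genotype =, n =)` free functional virions placed at
#'   random sites, or `NULL`.
#' @param drugs character vector of antibiotics in the schedule.
#' @param drug_start first iteration of antibiotic application (`NA` = never).
#' @param ... scalar overrides of the engine defaults.
#' @return A configuration list of class `pt_config`.
#' @export
sim_config <- function(strains, genotypes, populations, inoculum = NULL,
                       drugs = character(0), drug_start = NA_integer_, ...) {
  vals <- resolve_scalars(list(...))
  if (inherits(strains, "strain_spec")) strains <- list(strains)
  if (inherits(genotypes, "phage_genotype")) genotypes <- list(genotypes)
  cfg <- c(vals,
           list(scenario_id = "custom",
                strains = strains, genotypes = genotypes,
                populations = populations, inoculum = inoculum,
                drugs = drugs,
                drug_start = if (is.na(drug_start)) NA_integer_
                             else as.integer(drug_start)))
  class(cfg) <- "pt_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  if (!inherits(config, "pt_config")) {
    stop("`config` must be created by sim_config(), scenario_config() or load_config()")
  }
  check_scalars(config[intersect(names(config), names(config_ranges()))])
  if (length(config$strains) == 0L) stop("configuration has no strains")
  for (g in config$genotypes) {
    if (g$headful > min(vapply(config$strains, `[[`, integer(1), "L"))) {
      stop("headful capacity exceeds the genome size of a configured strain")
    }
  }
  invisible(config)
}

#' Load a run configuration from a plain-text file
#'
#' The file is YAML with an optional `scenario` key naming one of the built
#' in experiment designs (see [scenario_config()]) and any number of scalar
#' overrides. Unknown keys and out-of-range values raise errors naming the
#' offending key. Loading is deterministic; an empty file yields the default
#' scenario at default parameters.
#'
#' @param path path of the configuration file.
#' @return A configuration of class `pt_config` with all defaults merged.
#' @seealso [write_config()] for the round-trip companion.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  scen <- y$scenario
  if (is.null(scen)) scen <- "S1_temperate_GT"
  y$scenario <- NULL
  unknown <- setdiff(names(y), names(sim_defaults()))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, c(list(scenario_id = scen), y))
}

#' Write a configuration to a plain-text file
#'
#' Persists the scenario name and all scalar parameters; reloading with
#' [load_config()] reconstructs an identical configuration.
#'
#' @param config a configuration from [scenario_config()] or [load_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(sim_defaults())
  out <- c(list(scenario = config$scenario_id), config[keys])
  names(out) <- c("scenario", keys)
  yaml::write_yaml(out, path)
  invisible(path)
}
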