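# Sensitivity machinery: random parameter designs with a dummy noise
# parameter, mass replicate execution of the two-phase scenario, the
# phage-survival response, random-forest permutation importance (%IncMSE)
# and the p_GT x {genome size, burst size, sample size} heatmap sweeps.

#' Default parameter ranges of the sensitivity design
#'
#' Broad ranges chosen to allow a diversity of outcomes, over the
#' biological transfer and decision parameters of the system: the
#' transduction and lysogenization probabilities, the burst size, the
#' between-phase sample size, the donor genome size and the antibiotic
#' timing. The infection-machinery constants (adsorption and decay
#' probabilities) stay at their calibrated defaults: varied over wide
#' ranges they act through raw predation pressure and pool persistence and
#' mask every biological effect. Continuous parameters are sampled
#' uniformly; integer parameters uniformly over the integer range.
#'
#' @return named list of ranges (`c(min, max)`, with an `"int"` attribute
#'   for integer parameters).
#' @export
default_rfa_ranges <- function() {
  int_range <- function(lo, hi) structure(c(lo, hi), int = TRUE)
  log_range <- function(lo, hi) structure(c(lo, hi), log = TRUE)
  list(p_GT = log_range(1e-3, 1),
       p_lys = log_range(1e-4, 1),
       burst_size = int_range(5, 100),
       n_sample = int_range(10, 1000),
       phase2_antibiotic_iteration = int_range(3, 15))
}

#' Sample a random parameter design
#'
#' Draws `n_combos` parameter combinations independently and uniformly
#' within the declared ranges and appends the dummy parameter: a random
#' choice among {1, 2, 3} with no effect on any simulation, which serves as
#' the noise floor of the importance analysis.
#'
#' @param ranges named list of ranges as in [default_rfa_ranges()].
#' @param n_combos number of parameter combinations (rows).
#' @param n_reps replicate simulations per combination (recorded as an
#'   attribute; used by [run_design()]).
#' @param seed integer seed.
#' @return A `data.frame` of class `pt_design` with one column per
#'   parameter plus `dummy`.
#' @export
sample_parameter_designs <- function(ranges = default_rfa_ranges(),
                                     n_combos = 300L, n_reps = 10L, seed = 1L) {
  if (!length(ranges)) stop("empty parameter ranges")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[2] < r[1] ||
        (isTRUE(attr(r, "log")) && r[1] <= 0)) {
      stop("invalid range for parameter ", nm)
    }
  }
  set.seed(seed)
  cols <- lapply(ranges, function(r) {
    if (isTRUE(attr(r, "int"))) {
      sample.int(r[2] - r[1] + 1L, n_combos, replace = TRUE) + r[1] - 1L
    } else if (isTRUE(attr(r, "log"))) {
      # probabilities are explored across orders of magnitude
      10^runif(n_combos, log10(r[1]), log10(r[2]))
    } else {
      runif(n_combos, r[1], r[2])
    }
  })
  cols$dummy <- sample(1:3, n_combos, replace = TRUE)
  out <- as.data.frame(cols)
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pt_design", "data.frame")
  out
}

#' Fraction of replicates with surviving phage
#'
#' Phage are alive when free functional particles remain or prophages
#' persist in living cells.
#'
#' @param outcomes list of outcome summaries (as in `pt_sim$outcome`) or a
#'   data.frame with a `phage_survived` column.
#' @return fraction in `[0, 1]`.
#' @export
response_phage_survival <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    v <- outcomes$phage_survived
  } else {
    if (!length(outcomes)) stop("empty outcome list")
    v <- vapply(outcomes, `[[`, logical(1), "phage_survived")
  }
  if (!length(v)) stop("empty outcome list")
  mean(v)
}

#' Execute a parameter design
#'
#' Runs the two-phase temperate/transducing scenario once per design row
#' and replicate (replicate seeds derived deterministically from
#' `master_seed`) and summarises each row as the fraction of replicates
#' where phage survive. The dummy column is deliberately not forwarded to
#' the simulator.
#'
#' @param design a design from [sample_parameter_designs()].
#' @param master_seed integer master seed.
#' @param base overrides applied to every row (e.g. lattice size).
#' @param verbose print progress every 50 rows.
#' @return numeric vector of responses, one per design row.
#' @export
run_design <- function(design, master_seed = 1L,
                       base = list(width = 30L, height = 30L),
                       verbose = FALSE) {
  n_reps <- attr(design, "n_reps")
  if (is.null(n_reps)) n_reps <- 10L
  params <- setdiff(names(design), "dummy")
  set.seed(master_seed)
  row_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(design) * n_reps),
                      nrow = nrow(design))
  responses <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    ov <- c(as.list(design[i, params, drop = FALSE]), base,
            list(record = FALSE, record_classes = FALSE))
    cfg <- do.call(scenario_config, c(list("S1_temperate_GT"), ov))
    outs <- vector("list", n_reps)
    for (k in seq_len(n_reps)) {
      outs[[k]] <- suppressWarnings(run_two_phase(cfg, row_seeds[i, k]))$outcome
    }
    responses[i] <- response_phage_survival(outs)
    if (verbose && i %% 50L == 0L) {
      message("design row ", i, "/", nrow(design))
    }
  }
  responses
}

#' Random-forest permutation importance of the design parameters
#'
#' Fits a random-forest regression of the response on the design parameters
#' (including the dummy) and reports, per parameter, the percentage increase
#' in out-of-bag mean squared error when that parameter's values are
#' randomly permuted (%IncMSE): influential parameters produce large
#' increases, while irrelevant ones stay near the dummy's noise floor.
#'
#' @param design a design from [sample_parameter_designs()].
#' @param responses one response per design row.
#' @param n_trees number of trees.
#' @param seed integer seed for the forest.
#' @return A `data.frame` with columns `parameter`, `importance` (%IncMSE)
#'   and `rank`, sorted by decreasing importance.
#' @export
rfa_importance <- function(design, responses, n_trees = 10000L, seed = 1L) {
  if (length(responses) != nrow(design)) {
    stop("one response per design row is required")
  }
  x <- as.data.frame(design)
  if (stats::var(responses) == 0) {
    warning("constant response; importances are all zero")
    out <- data.frame(parameter = names(x), importance = 0,
                      rank = seq_along(x))
    return(out)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = responses, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)
  out <- data.frame(parameter = rownames(imp), importance = as.numeric(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Survival heatmap over p_GT and a second experimental axis
#'
#' Runs the two-phase temperate/transducing scenario for every combination
#' of the transduction probability and one of: the genome size of the
#' resistant donor strain, the phage burst size, or the number of virions
#' sampled between the phases. Each cell is summarised as the fraction of
#' replicates where bacteria and phage jointly survive (the heatmaps are
#' typically binned by the replicate median, i.e. majority survival).
#'
#' @param p_GT_grid values of the transduction probability (rows).
#' @param axis one of `"genome_size"`, `"burst_size"`, `"n_sample"`.
#' @param axis_levels values of the second axis (columns).
#' @param n_reps replicates per cell.
#' @param master_seed integer master seed.
#' @param base overrides applied to every cell (lattice size etc.).
#' @return numeric matrix of joint-survival fractions with `p_GT` rows and
#'   axis-level columns; the axis name is stored in `attr(, "axis")`.
#' @export
sweep_heatmap <- function(p_GT_grid, axis = c("genome_size", "burst_size",
                                              "n_sample"),
                          axis_levels, n_reps = 20L, master_seed = 1L,
                          base = list(width = 30L, height = 30L)) {
  axis <- match.arg(axis)
  if (!length(p_GT_grid) || !length(axis_levels)) stop("empty sweep grid")
  key <- switch(axis, genome_size = "L", burst_size = "burst_size",
                n_sample = "n_sample")
  set.seed(master_seed)
  seeds <- array(sample.int(.Machine$integer.max - 1L,
                            length(p_GT_grid) * length(axis_levels) * n_reps),
                 dim = c(length(p_GT_grid), length(axis_levels), n_reps))
  m <- matrix(NA_real_, length(p_GT_grid), length(axis_levels),
              dimnames = list(p_GT = p_GT_grid, axis_levels))
  for (i in seq_along(p_GT_grid)) {
    for (j in seq_along(axis_levels)) {
      ov <- c(base, list(p_GT = p_GT_grid[i], record = FALSE,
                         record_classes = FALSE))
      ov[[key]] <- axis_levels[j]
      cfg <- do.call(scenario_config, c(list("S1_temperate_GT"), ov))
      joint <- logical(n_reps)
      for (k in seq_len(n_reps)) {
        o <- suppressWarnings(run_two_phase(cfg, seeds[i, j, k]))$outcome
        joint[k] <- o$bacteria_survived && o$phage_survived
      }
      m[i, j] <- mean(joint)
    }
  }
  attr(m, "axis") <- axis
  attr(m, "n_reps") <- n_reps
  m
}
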