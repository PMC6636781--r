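# Structured outputs: genome snapshots (gene-level serialization of sampled
# cells, with provenance and prophage annotations), time-series CSV,
# outcome JSON, and self-contained run directories.

#' Sample and serialize genomes from a running population
#'
#' Uniformly samples living bacteria (all of them, if fewer than `n_cells`)
#' and serializes their genomes gene by gene: category, drug, activity,
#' provenance (the strain the DNA originated from, preserved through
#' transduction) and the integrated prophage runs. The snapshot is a
#' faithful serialization: [snapshot_from_json()] of
#' [snapshot_to_json()] reproduces it exactly.
#'
#' @param sim a `pt_sim` run with `keep_state = TRUE`, or an engine state.
#' @param n_cells number of cells to sample.
#' @return A list of class `pt_snapshot` with `iteration`, `sample_size` and
#'   `cells`; each cell records `strain`, `length`, a `genes` table with
#'   columns `slot`, `category`, `drug`, `active`, `provenance`, and a
#'   `prophages` table with `genotype_id`, `immunity_group`, `start`,
#'   `span`.
#' @export
export_snapshot <- function(sim, n_cells = 5L) {
  st <- if (inherits(sim, "pt_state")) sim else sim$state
  if (is.null(st)) stop("run the simulation with keep_state = TRUE to snapshot it")
  ctx <- st$ctx
  r <- ctx$reg
  alive <- which(st$occ)
  if (!length(alive)) {
    warning("no living bacteria to snapshot")
    return(structure(list(iteration = st$t, sample_size = 0L, cells = list()),
                     class = "pt_snapshot"))
  }
  take <- alive[sample.int(length(alive), min(n_cells, length(alive)))]
  cells <- lapply(take, function(s) {
    gid <- st$gid[s]
    loci <- reg_loci(r, gid)
    present <- which(loci > 0L)
    rows <- loci[present]
    genes <- data.frame(slot = present,
                        category = ctx$genes$category[rows],
                        drug = ctx$genes$drug[rows],
                        active = ctx$genes$active[rows],
                        provenance = ctx$genes$provenance[rows],
                        stringsAsFactors = FALSE)
    pro <- reg_pro(r, gid)
    prophages <- data.frame(
      genotype_id = pro$pro_gt,
      immunity_group = vapply(pro$pro_gt, function(g) {
        ctx$genotypes[[g]]$immunity_group
      }, character(1)),
      start = pro$pro_start,
      span = pro$pro_span,
      stringsAsFactors = FALSE)
    list(strain = ctx$strain_names[st$strain[s]],
         length = r$len[gid],
         genes = genes,
         prophages = prophages)
  })
  structure(list(iteration = st$t, sample_size = length(take), cells = cells),
            class = "pt_snapshot")
}

#' @rdname export_snapshot
#' @param snapshot a `pt_snapshot`.
#' @param path file to write to (or read from); `NULL` returns/accepts a
#'   JSON string.
#' @export
snapshot_to_json <- function(snapshot, path = NULL) {
  x <- unclass(snapshot)
  js <- jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname export_snapshot
#' @param json a JSON string or file path produced by [snapshot_to_json()].
#' @export
snapshot_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$iteration <- as.integer(x$iteration)
  x$sample_size <- as.integer(x$sample_size)
  x$cells <- lapply(x$cells, function(cell) {
    g <- cell$genes
    genes <- data.frame(slot = as.integer(unlist0(g$slot)),
                        category = as.character(unlist0(g$category)),
                        drug = as.character(unlist0(g$drug)),
                        active = as.logical(unlist0(g$active)),
                        provenance = as.character(unlist0(g$provenance)),
                        stringsAsFactors = FALSE)
    p <- cell$prophages
    prophages <- data.frame(genotype_id = as.integer(unlist0(p$genotype_id)),
                            immunity_group = as.character(unlist0(p$immunity_group)),
                            start = as.integer(unlist0(p$start)),
                            span = as.integer(unlist0(p$span)),
                            stringsAsFactors = FALSE)
    list(strain = cell$strain, length = as.integer(cell$length),
         genes = genes, prophages = prophages)
  })
  structure(x, class = "pt_snapshot")
}

# NULL-safe unlist that maps JSON null back to NA
unlist0 <- function(x) {
  if (is.null(x)) return(logical(0))
  x[vapply(x, is.null, logical(1))] <- NA
  unlist(x)
}

#' Write the recorded time series as CSV
#'
#' One row per iteration with the stable, versioned header
#' `iteration, n_bacteria, n_lysogens, n_resistant, n_double_resistant,
#' free_functional, free_transducing, cum_transductions, cum_inductions`;
#' the per-class long table (strain x resistance profile x lysogen status)
#' is written alongside when recorded.
#'
#' @param sim a `pt_sim`.
#' @param path CSV destination for the summary series.
#' @param class_path optional CSV destination for the per-class counts.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(sim, path, class_path = NULL) {
  write.csv(sim$series, path, row.names = FALSE)
  if (!is.null(class_path) && !is.null(sim$class_counts)) {
    write.csv(sim$class_counts, class_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write an outcome summary as JSON
#'
#' @param outcome an outcome summary (`pt_sim$outcome`) or a
#'   `pt_replicates` object (whose per-replicate outcomes and survival
#'   fractions are written).
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
write_outcome_json <- function(outcome, path) {
  if (inherits(outcome, "pt_replicates")) {
    outcome <- list(survival = outcome$survival, outcomes = outcome$outcomes)
  }
  jsonlite::write_json(outcome, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Save a complete, re-executable run directory
#'
#' Writes the resolved configuration, the seed, the time series, the
#' per-class counts and the outcome into `dir` -- everything needed to
#' re-execute the run bit-identically.
#'
#' @param sim a `pt_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(sim$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(list(seed = sim$outcome$seed,
                            scenario = sim$config$scenario_id),
                       file.path(dir, "seed.json"), auto_unbox = TRUE)
  write_timeseries_csv(sim, file.path(dir, "timeseries.csv"),
                       file.path(dir, "class_counts.csv"))
  if (!is.null(sim$phase1)) {
    write.csv(sim$phase1, file.path(dir, "timeseries_phase1.csv"),
              row.names = FALSE)
  }
  write_outcome_json(sim$outcome, file.path(dir, "outcome.json"))
  invisible(dir)
}
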