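# Declarative definitions of the in-silico experiments: the two-phase
# four-scenario design (one phage type per scenario), the two-lysogen
# gene-shuffling design with its controls, and the lysate-capacity worked
# example.

#' @rdname scenario_config
#' @export
scenario_ids <- c("S1_temperate_GT", "S2_temperate_nonGT", "S3_virulent_GT",
                  "S4_virulent_nonGT", "FIG6_two_lysogens", "S4A_no_prophage",
                  "S4B_no_drug_low_induction", "S4C_no_drug_high_induction")

#' Configure a named in-silico experiment
#'
#' The four single-phage scenarios share every parameter except the phage
#' lifestyle and transduction ability: `S1_temperate_GT` (temperate,
#' transducing), `S2_temperate_nonGT` (temperate, `p_GT = 0`),
#' `S3_virulent_GT` (virulent, transducing), `S4_virulent_nonGT` (virulent,
#' `p_GT = 0`). They run the two-phase protocol (see [run_two_phase()]):
#' phage first propagate on an antibiotic-resistant strain, a sample of the
#' lysate then infects a sensitive population, and the antibiotic is applied
#' during the second phase.
#'
#' `FIG6_two_lysogens` is the gene-shuffling experiment: two strains, both
#' lysogens of the same temperate transducing phage, one carrying an active
#' erythromycin (ERM) and an inactive chloramphenicol (CAM) resistance gene,
#' the other the complement; both drugs are applied at iteration 10. Its
#' controls: `S4A_no_prophage` (same strains without prophages),
#' `S4B_no_drug_low_induction` (no antibiotics, `alpha = 1e5`, spontaneous
#' induction ~ 1e-5) and `S4C_no_drug_high_induction` (no antibiotics,
#' `alpha = 1e3`, spontaneous induction ~ 1e-3). The chromosomal markers sit
#' maximally distant from the prophage integration site.
#'
#' @param scenario_id one of `scenario_ids`.
#' @param ... scalar parameter overrides (see [sim_config()]).
#' @return A configuration of class `c("scenario_config", "pt_config")`.
#' @examples
#' cfg <- scenario_config("S1_temperate_GT", width = 20, height = 20)
#' @export
scenario_config <- function(scenario_id = scenario_ids, ...) {
  scenario_id <- match.arg(scenario_id)
  overrides <- list(...)
  if (scenario_id %in% c("S2_temperate_nonGT", "S4_virulent_nonGT") &&
      is.null(overrides$p_GT)) {
    overrides$p_GT <- 0
  }
  if (scenario_id == "S4C_no_drug_high_induction" && is.null(overrides$alpha)) {
    overrides$alpha <- 1e3
  }
  vals <- resolve_scalars(overrides)
  lifestyle <- if (scenario_id %in% c("S3_virulent_GT", "S4_virulent_nonGT")) {
    "virulent"
  } else "temperate"
  phage <- phage_genotype(lifestyle, p_GT = vals$p_GT,
                          burst_size = vals$burst_size, headful = vals$headful,
                          immunity_group = "A", p_lys = vals$p_lys,
                          K_lys = vals$K_lys, alpha = vals$alpha,
                          kappa = vals$kappa,
                          prophage_span = vals$prophage_span, id = 1L)
  two_lysogen <- scenario_id %in% c("FIG6_two_lysogens", "S4A_no_prophage",
                                    "S4B_no_drug_low_induction",
                                    "S4C_no_drug_high_induction")
  if (two_lysogen) {
    pro <- if (scenario_id == "S4A_no_prophage") NULL else phage
    mk <- function(name, active_drug) {
      strain_spec(name, L = vals$L, n_essential = vals$n_essential,
                  n_accessory = vals$n_accessory,
                  markers = data.frame(drug = c("ERM", "CAM"),
                                       active = c(active_drug == "ERM",
                                                  active_drug == "CAM")),
                  lysogen_of = pro)
    }
    strains <- list(mk("lysogenA", "ERM"), mk("lysogenB", "CAM"))
    n_half <- round(vals$occupancy * vals$width * vals$height / 2)
    populations <- list(list(strain = "lysogenA", n = n_half),
                        list(strain = "lysogenB", n = n_half))
    with_drug <- scenario_id %in% c("FIG6_two_lysogens", "S4A_no_prophage")
    cfg <- c(vals, list(
      scenario_id = scenario_id,
      strains = strains, genotypes = list(phage),
      populations = populations, inoculum = NULL,
      drugs = if (with_drug) c("ERM", "CAM") else character(0),
      drug_start = if (with_drug) 10L else NA_integer_))
  } else {
    mk <- function(name, active) {
      strain_spec(name, L = vals$L, n_essential = vals$n_essential,
                  n_accessory = vals$n_accessory,
                  markers = data.frame(drug = vals$marker_drug, active = active))
    }
    strains <- list(mk("res", TRUE), mk("sens", FALSE))
    cfg <- c(vals, list(
      scenario_id = scenario_id,
      strains = strains, genotypes = list(phage),
      populations = NULL, inoculum = NULL,
      drugs = vals$marker_drug,
      drug_start = vals$phase2_antibiotic_iteration))
  }
  class(cfg) <- c("scenario_config", "pt_config")
  validate_config(cfg)
  cfg
}

# the runner appropriate for a configuration (used by run_replicates)
scenario_runner <- function(config) {
  id <- config$scenario_id
  if (id %in% c("S1_temperate_GT", "S2_temperate_nonGT", "S3_virulent_GT",
                "S4_virulent_nonGT")) {
    return(run_two_phase)
  }
  if (id %in% c("FIG6_two_lysogens", "S4A_no_prophage",
                "S4B_no_drug_low_induction", "S4C_no_drug_high_induction")) {
    return(run_gene_shuffling)
  }
  run_simulation
}

#' Create an empty lattice and seed founder populations
#'
#' `new_lattice()` builds an empty engine state for a configuration;
#' `init_population()` places `n_cells` founder bacteria of a configured
#' strain on free sites, with genomes built from the strain specification
#' (essential and accessory genes, active or inactive resistance markers,
#' optional integrated prophage; all provenance tags set to the strain
#' name).
#'
#' @param config a `pt_config`.
#' @param lattice a state from `new_lattice()`.
#' @param strain a strain name configured in the lattice.
#' @param n_cells number of founder cells; must not exceed free sites.
#' @return the lattice state (an environment), invisibly for
#'   `init_population()`.
#' @export
new_lattice <- function(config) {
  validate_config(config)
  ctx <- new_context(config$strains, config$genotypes,
                     extra_drugs = config$drugs)
  new_state(ctx, config)
}

#' @rdname new_lattice
#' @export
init_population <- function(lattice, strain, n_cells) {
  ctx <- lattice$ctx
  sid <- match(strain, ctx$strain_names)
  if (is.na(sid)) stop("unknown strain: ", strain)
  place_bacteria(lattice, n_cells, ctx$founders[sid], sid)
}

#' Run the two-phase infection protocol
#'
#' Phase 1: phage propagate for `phase1_iterations` on the resistant strain
#' (initial density `occupancy`, inoculum at `moi`). All free virions are
#' then collected and `n_sample` of them drawn uniformly without replacement
#' (all of them, if fewer are available; an empty lysate yields an empty
#' sample with a warning). Phase 2: the sample is introduced to a fresh
#' lattice of sensitive bacteria, the antibiotic is applied from
#' `phase2_antibiotic_iteration` for `drug_duration` iterations, and the
#' simulation runs to `total_iterations` overall.
#'
#' @param config a two-phase [scenario_config()].
#' @param seed integer seed.
#' @param keep_state keep the final phase-2 engine state.
#' @return An object of class `c("pt_two_phase", "pt_sim")` with elements
#'   `phase1` (phase-1 series), `series` (phase-2 series), `sample`
#'   (lysate size and sampled functional/transducing counts), `outcome`,
#'   and optionally `state`.
#' @export
run_two_phase <- function(config, seed, keep_state = FALSE) {
  validate_config(config)
  set.seed(seed)
  ctx <- new_context(config$strains, config$genotypes,
                     extra_drugs = config$drugs)
  sid_res <- match("res", ctx$strain_names)
  sid_sens <- match("sens", ctx$strain_names)
  if (is.na(sid_res) || is.na(sid_sens)) {
    stop("two-phase configs need strains 'res' and 'sens'")
  }

  cfg1 <- config
  cfg1$drug_start <- NA_integer_
  st1 <- new_state(ctx, cfg1)
  n1 <- round(config$occupancy * st1$n_sites)
  place_bacteria(st1, n1, ctx$founders[sid_res], sid_res)
  add_virions(st1, round(config$moi * n1), 1L)
  run_state(st1, config$phase1_iterations)

  nv <- length(st1$vsite)
  ns <- min(config$n_sample, nv)
  if (nv == 0L) warning("no free virions available at sampling; phase 2 starts phage-free")
  pick <- if (nv > 0L) sample.int(nv, ns) else integer(0)
  sample_info <- list(available = nv, sampled = ns,
                      functional = sum(st1$vkind[pick] == 0L),
                      transducing = sum(st1$vkind[pick] == 1L))

  st2 <- new_state(ctx, config)
  n2 <- round(config$occupancy * st2$n_sites)
  place_bacteria(st2, n2, ctx$founders[sid_sens], sid_sens)
  if (ns > 0L) {
    vir_append(st2, list(site = sample.int(st2$n_sites, ns, replace = TRUE),
                         gt = st1$vgt[pick], kind = st1$vkind[pick],
                         cg = st1$vcg[pick], cs = st1$vcs[pick]))
  }
  run_state(st2, config$total_iterations - config$phase1_iterations)

  structure(list(phase1 = series_df(st1),
                 series = series_df(st2),
                 class_counts = class_counts_df(st2),
                 sample = sample_info,
                 outcome = outcome_state(st2, seed),
                 config = config,
                 state = if (keep_state) st2 else NULL),
            class = c("pt_two_phase", "pt_sim"))
}

#' Run the two-lysogen gene-shuffling experiment
#'
#' A mixed culture of two lysogenic strains with complementary antibiotic
#' resistance genes. Resistance can only move between the strains inside
#' transducing particles released by prophage induction; double-resistant
#' cells are counted over time. Supports the controls without prophages
#' (`S4A_no_prophage`) and without antibiotics at low or high spontaneous
#' induction (`S4B`/`S4C`).
#'
#' @param config a gene-shuffling [scenario_config()].
#' @param seed integer seed.
#' @param keep_state keep the final engine state.
#' @return An object of class `c("pt_shuffle", "pt_sim")`; on top of the
#'   usual `series`/`outcome` it carries `double_resistant`, a list with
#'   `final` (living double-resistant cells at the last iteration) and
#'   `created` (cumulative transduction events that made a cell
#'   double resistant).
#' @export
run_gene_shuffling <- function(config, seed, keep_state = FALSE) {
  validate_config(config)
  set.seed(seed)
  ctx <- new_context(config$strains, config$genotypes,
                     extra_drugs = config$drugs)
  st <- new_state(ctx, config)
  for (p in config$populations) {
    sid <- match(p$strain, ctx$strain_names)
    place_bacteria(st, p$n, ctx$founders[sid], sid)
  }
  run_state(st, config$iterations)
  alive <- which(st$occ)
  n_double <- sum(ctx$nbits[ctx$reg$res_mask[st$gid[alive]] + 1L] >= 2L)
  structure(list(series = series_df(st),
                 class_counts = class_counts_df(st),
                 outcome = outcome_state(st, seed),
                 double_resistant = list(final = n_double,
                                         final_bacteria = length(alive),
                                         created = st$cum_double_created),
                 config = config,
                 state = if (keep_state) st else NULL),
            class = c("pt_shuffle", "pt_sim"))
}

#' Bacterial-DNA capacity of a phage lysate
#'
#' Pure arithmetic on measured lysate properties: with `pfu_per_ml`
#' infective particles per millilitre, a transducing:infective ratio of
#' `transducing_ratio` and `headful_bp` base pairs per transducing capsid,
#' one millilitre of lysate carries
#' `pfu_per_ml * transducing_ratio * headful_bp` base pairs of bacterial
#' DNA, i.e. that amount divided by `genome_bp` full genome equivalents.
#'
#' @param pfu_per_ml plaque-forming units per ml (> 0).
#' @param transducing_ratio transducing particles per infective particle
#'   (>= 0).
#' @param headful_bp base pairs per transducing particle (> 0).
#' @param genome_bp reference genome length in bp (> 0).
#' @return list with `transducing_per_ml`, `transduced_bp_per_ml`,
#'   `genome_equivalents_per_ml`.
#' @examples
#' # 1e9 PFU/ml, 1 transducing particle per 700 infective, 43 kbp headful:
#' lysate_capacity(1e9, 1 / 700, 43e3, genome_bp = 2.8e6)
#' @export
lysate_capacity <- function(pfu_per_ml, transducing_ratio, headful_bp,
                            genome_bp = 2.8e6) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok(pfu_per_ml) || pfu_per_ml <= 0) stop("pfu_per_ml must be positive")
  if (!ok(transducing_ratio) || transducing_ratio < 0) {
    stop("transducing_ratio must be nonnegative")
  }
  if (!ok(headful_bp) || headful_bp <= 0) stop("headful_bp must be positive")
  if (!ok(genome_bp) || genome_bp <= 0) stop("genome_bp must be positive")
  tp <- pfu_per_ml * transducing_ratio
  bp <- tp * headful_bp
  list(transducing_per_ml = tp,
       transduced_bp_per_ml = bp,
       genome_equivalents_per_ml = bp / genome_bp)
}
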