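#' Stress-dependent prophage induction probability
#'
#' The probability that a prophage is induced in one iteration follows a
#' sigmoid in the host's stress level:
#' `P(s) = 1 / (1 + alpha * exp(-kappa * s))`. At zero stress this equals
#' `1 / (1 + alpha)`, so `alpha = 1e5` corresponds to a spontaneous induction
#' rate of about `1e-5` per lysogen per iteration and `alpha = 1e3` to about
#' `1e-3`; the probability rises monotonically towards 1 as stress grows.
#'
#' @param stress nonnegative stress level(s).
#' @param alpha positive offset parameter setting the spontaneous rate.
#' @param kappa positive stress sensitivity (per stress unit).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' induction_probability(0, alpha = 1e5, kappa = 0.4)  # 1 / 100001
#' induction_probability(0, alpha = 1e3, kappa = 0.4)  # 1 / 1001
#' @export
induction_probability <- function(stress, alpha, kappa) {
  if (!is.numeric(stress) || any(!is.finite(stress)) || any(stress < 0)) {
    stop("`stress` must be finite and nonnegative")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a finite positive scalar")
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    stop("`kappa` must be a finite positive scalar")
  }
  1 / (1 + alpha * exp(-kappa * stress))
}

#' Lysogenization probability of an infecting phage
#'
#' Virulent phage never lysogenize. For temperate phage the probability
#' saturates with the number of free virions in the Moore neighbourhood of
#' the infected cell: `p_lys * n / (n + K_lys)`.
#'
#' @param genotype a [phage_genotype()].
#' @param n_local_free free virions at Moore distance one (vectorized).
#' @return numeric vector of probabilities.
#' @export
lysogeny_probability <- function(genotype, n_local_free) {
  if (any(n_local_free < 0)) stop("`n_local_free` must be nonnegative")
  if (genotype$lifestyle == "virulent") {
    return(rep(0, length(n_local_free)))
  }
  n <- n_local_free
  p <- genotype$p_lys * n / (n + genotype$K_lys)
  p[n == 0 & genotype$K_lys == 0] <- 0
  p
}

#' Decide between the lytic and lysogenic cycle
#'
#' @inheritParams lysogeny_probability
#' @return `"lysogenize"` or `"lyse"`.
#' @export
decide_lifecycle <- function(genotype, n_local_free) {
  if (length(n_local_free) != 1L || n_local_free < 0) {
    stop("`n_local_free` must be a single nonnegative count")
  }
  p <- lysogeny_probability(genotype, n_local_free)
  if (runif(1) < p) "lysogenize" else "lyse"
}

#' Package a burst of virions from a lysing host
#'
#' Each of the `burst_size` progeny is independently a generalized
#' transducing particle with probability `p_GT`. A transducing particle
#' carries a headful of host DNA: the `headful` consecutive non-prophage
#' slots starting at a uniformly random position of the circular host genome
#' (prophage-occupied slots are skipped; empty slots take up capacity but
#' contribute no gene). Cargo genes keep the host's provenance tags.
#'
#' @param host_genome the [bacterial_genome()] of the lysing host.
#' @param genotype the [phage_genotype()] replicating in the host.
#' @return list of [virion()] objects of length `burst_size`.
#' @examples
#' g <- bacterial_genome(20, genes("resistance", drug = "CAM", active = TRUE,
#'                                 provenance = "A"), at = 11)
#' burst <- package_burst(g, phage_genotype("temperate", p_GT = 1,
#'                                          burst_size = 5, headful = 2))
#' @export
package_burst <- function(host_genome, genotype) {
  np <- non_prophage_loci(host_genome)
  n_np <- length(np)
  if (genotype$headful > n_np) {
    stop("headful capacity exceeds the host's non-prophage genome size")
  }
  is_tr <- runif(genotype$burst_size) < genotype$p_GT
  lapply(seq_len(genotype$burst_size), function(i) {
    if (!is_tr[i]) return(virion(genotype, "phage_dna"))
    start <- sample.int(n_np, 1L)
    w <- np[headful_window(n_np, start, genotype$headful)]
    cargo <- host_genome$genes[w[w > 0L], , drop = FALSE]
    rownames(cargo) <- NULL
    virion(genotype, "bacterial_dna", cargo = cargo)
  })
}

#' Recombine transduced DNA into a recipient
#'
#' With probability `p_recomb` the cargo genes are integrated into the
#' recipient genome (appended at the designated integration region, donor
#' provenance preserved); an active resistance gene then immediately confers
#' phenotypic resistance to its drug, even alongside an inactive native
#' copy. With probability `1 - p_recomb` the genome is unchanged (the DNA is
#' degraded).
#'
#' @param recipient a [bacterium()].
#' @param cargo gene table carried by a transducing particle.
#' @param p_recomb recombination probability.
#' @return the updated [bacterium()].
#' @export
inject_transduced <- function(recipient, cargo, p_recomb = 1) {
  stopifnot(p_recomb >= 0, p_recomb <= 1)
  if (runif(1) < p_recomb) {
    recipient$genome <- genome_append_genes(recipient$genome, cargo)
  }
  recipient
}

#' Roulette-wheel fitness of a bacterium
#'
#' Growth is identical across strains except that every *active* resistance
#' gene carries a multiplicative cost: `w = (1 - cost)^k` with `k` the number
#' of active resistance genes. The weight is used as the roulette-wheel mass
#' in the competition of neighbouring bacteria for a free lattice site.
#'
#' @param bact a [bacterium()].
#' @param cost cost per active resistance gene, in `[0, 1)`.
#' @return positive scalar weight.
#' @export
fitness <- function(bact, cost = 0.05) {
  if (!is.numeric(cost) || cost < 0 || cost >= 1) {
    stop("`cost` must lie in [0, 1)")
  }
  (1 - cost)^n_active_resistance(bact)
}

#' Antibiotic exposure of one bacterium
#'
#' All bacteria exposed to at least one applied drug acquire the exposure
#' stress level (driving antibiotic-associated prophage induction); stress
#' resets to zero on iterations without exposure. A cell lacking an active
#' resistance gene for one of the applied drugs accumulates unprotected
#' exposures and, once it has tolerated `drug_delay` of them, is killed with
#' probability `p_kill` on each further exposed iteration. The tolerance
#' window models the lag between drug action and death, during which the
#' stress response can still trigger prophage induction.
#'
#' @param bact a [bacterium()].
#' @param applied_drugs character vector of antibiotics present this
#'   iteration (empty for none).
#' @param p_kill per-iteration kill probability once the delay is exhausted.
#' @param stress_on_exposure stress level set by exposure.
#' @param drug_delay unprotected exposures tolerated before lethality.
#' @return list with elements `alive` (logical) and `bacterium` (updated;
#'   `NULL` when killed).
#' @export
antibiotic_action <- function(bact, applied_drugs = character(0), p_kill = 1,
                              stress_on_exposure = 20, drug_delay = 2L) {
  if (length(applied_drugs) == 0L) {
    bact$stress <- 0
    bact$exposures <- 0L
    return(list(alive = TRUE, bacterium = bact))
  }
  bact$stress <- stress_on_exposure
  protected <- all(applied_drugs %in% active_resistance(bact))
  if (protected) {
    bact$exposures <- 0L
    return(list(alive = TRUE, bacterium = bact))
  }
  bact$exposures <- bact$exposures + 1L
  if (bact$exposures > drug_delay && runif(1) < p_kill) {
    return(list(alive = FALSE, bacterium = NULL))
  }
  list(alive = TRUE, bacterium = bact)
}

#' Resolve the adsorption of a virion to a co-located bacterium
#'
#' Adsorption itself (the probabilistic attachment) is handled by the
#' caller; this kernel resolves what happens next.
#' A functional virion meeting a lysogen of its own immunity group is
#' blocked by superinfection immunity and destroyed. A transducing particle
#' injects its cargo regardless of immunity (the repressor acts on the phage
#' genome, which a defective particle does not carry) and is consumed. A
#' functional virion on a susceptible host triggers the lifecycle decision:
#' lysogenization appends the prophage to the host genome; lysis kills the
#' host and releases a packaged burst.
#'
#' @param bact a [bacterium()].
#' @param vir a [virion()].
#' @param n_local_free free virions in the Moore neighbourhood (drives the
#'   lysogeny decision).
#' @param p_recomb recombination probability for transduced cargo.
#' @return list with elements `event` (one of `"blocked"`, `"transduced"`,
#'   `"lysogenized"`, `"lysed"`), `bacterium` (updated; `NULL` when lysed)
#'   and `burst` (list of virions when lysed, else `NULL`).
#' @export
resolve_adsorption <- function(bact, vir, n_local_free = 0L, p_recomb = 1) {
  if (vir$cargo_kind == "bacterial_dna") {
    bact <- inject_transduced(bact, vir$cargo, p_recomb = p_recomb)
    return(list(event = "transduced", bacterium = bact, burst = NULL))
  }
  if (vir$genotype$immunity_group %in% bact$genome$prophages$immunity_group) {
    return(list(event = "blocked", bacterium = bact, burst = NULL))
  }
  if (decide_lifecycle(vir$genotype, n_local_free) == "lysogenize") {
    bact$genome <- genome_add_prophage(bact$genome, vir$genotype)
    return(list(event = "lysogenized", bacterium = bact, burst = NULL))
  }
  burst <- package_burst(bact$genome, vir$genotype)
  list(event = "lysed", bacterium = NULL, burst = burst)
}
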