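# Per-event mechanistic kernels: induction curve, lifecycle decision,
# headful packaging, transduction, fitness, antibiotic action.

test_that("induction probability matches the spontaneous-rate equivalences", {
  # alpha = 1e5 <-> spontaneous rate 1e-5; alpha = 1e3 <-> 1e-3
  expect_equal(induction_probability(0, 1e5, 0.4), 1 / 100001)
  expect_equal(induction_probability(0, 1e3, 0.4), 1 / 1001)
  expect_equal(induction_probability(1e6, 1e3, 0.4), 1)
})

test_that("induction probability is monotone in stress over a parameter grid", {
  s <- seq(0, 50, by = 0.5)
  for (alpha in c(10, 1e3, 1e5)) {
    for (kappa in c(0.1, 0.4, 2)) {
      p <- induction_probability(s, alpha, kappa)
      # nondecreasing everywhere (the curve saturates at 1 in double
      # precision for large kappa * stress) and strictly rising overall
      expect_true(all(diff(p) >= 0))
      expect_gt(p[length(p)], p[1])
      expect_equal(p[1], 1 / (1 + alpha))
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("induction probability rejects invalid parameters", {
  expect_error(induction_probability(-1, 1e3, 0.4), "stress")
  expect_error(induction_probability(0, 0, 0.4), "alpha")
  expect_error(induction_probability(0, 1e3, -1), "kappa")
  expect_error(induction_probability(NaN, 1e3, 0.4), "stress")
  expect_error(induction_probability(0, Inf, 0.4), "alpha")
})

test_that("lifecycle decision: virulent phage always lyse, p_lys = 0 never lysogenizes", {
  vir <- phage_genotype("virulent", p_lys = 0.9)
  tem0 <- phage_genotype("temperate", p_lys = 0)
  set.seed(1)
  expect_true(all(vapply(0:50, function(n) decide_lifecycle(vir, n),
                         character(1)) == "lyse"))
  expect_true(all(vapply(0:50, function(n) decide_lifecycle(tem0, n),
                         character(1)) == "lyse"))
  expect_error(decide_lifecycle(vir, -1), "nonnegative")
})

test_that("lysogeny saturates with local free phage as p_lys * n / (n + K)", {
  gt <- phage_genotype("temperate", p_lys = 0.8, K_lys = 2)
  expect_equal(lysogeny_probability(gt, c(0, 2, 1e6)),
               c(0, 0.4, 0.8 * 1e6 / (1e6 + 2)))
  # Bernoulli oracle: empirical frequency at n = 2 is 0.40 within 3 SE
  set.seed(42)
  n_draws <- 1e5
  hits <- sum(vapply(seq_len(n_draws), function(i) {
    decide_lifecycle(gt, 2L) == "lysogenize"
  }, logical(1)))
  se <- sqrt(0.4 * 0.6 / n_draws)
  expect_lt(abs(hits / n_draws - 0.4), 3 * se)
})

test_that("a burst has exactly burst_size virions and a binomial transducing share", {
  g <- marker_genome()
  expect_length(package_burst(g, tiny_phage(p_GT = 0, burst_size = 50L)), 50L)
  set.seed(7)
  b0 <- package_burst(g, tiny_phage(p_GT = 0, burst_size = 50L))
  expect_true(all(vapply(b0, `[[`, character(1), "cargo_kind") == "phage_dna"))
  b1 <- package_burst(g, tiny_phage(p_GT = 1, burst_size = 50L))
  expect_true(all(vapply(b1, `[[`, character(1), "cargo_kind") == "bacterial_dna"))
  # over many bursts the transducing fraction stays within 3 binomial SE
  p <- 0.25
  gt <- tiny_phage(p_GT = p, burst_size = 10L)
  n_tot <- 10L * 1000L
  k <- sum(vapply(seq_len(1000), function(i) {
    sum(vapply(package_burst(g, gt), `[[`, character(1), "cargo_kind") ==
          "bacterial_dna")
  }, numeric(1)))
  se <- sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(k / n_tot - p), 3 * se)
})

test_that("marker capture probability equals h/L on circular genomes (oracle)", {
  # exhaustive window enumeration vs the analytic h/L, across genome sizes
  for (L in c(10L, 37L, 100L, 200L)) {
    for (h in unique(pmin(c(1L, 5L, 10L), L))) {
      g <- marker_genome(L = L, marker_at = max(1L, L %/% 2L))
      expect_equal(capture_prob_oracle(g, h), h / L)
    }
  }
  # and the sampled windows agree with the enumeration within 3 binomial SE
  set.seed(11)
  L <- 100L; h <- 10L
  g <- marker_genome(L = L, marker_at = 51L)
  gt <- tiny_phage(p_GT = 1, burst_size = 20L, headful = h)
  n_tot <- 20L * 500L
  hits <- sum(vapply(seq_len(500), function(i) {
    sum(vapply(package_burst(g, gt), function(v) nrow(v$cargo) > 0L,
               logical(1)))
  }, numeric(1)))
  se <- sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(hits / n_tot - h / L), 3 * se)
})

test_that("packaging skips prophage DNA and respects capacity limits", {
  gt <- tiny_phage(p_GT = 1, burst_size = 30L, headful = 10L,
                   prophage_span = 8L)
  g <- phagetrans:::genome_add_prophage(marker_genome(L = 20L), gt)
  expect_length(g$loci, 28L)
  set.seed(3)
  burst <- package_burst(g, gt)
  # cargo never contains prophage-derived slots, only host genes
  for (v in burst) {
    expect_true(all(v$cargo$provenance == "donor"))
    expect_lte(nrow(v$cargo), gt$headful)
  }
  # capacity error: headful larger than the non-prophage genome
  big <- tiny_phage(p_GT = 1, headful = 25L)
  expect_error(package_burst(marker_genome(L = 20L), big), "headful")
})

test_that("transduced active resistance overrides an inactive native copy", {
  recipient <- bacterium(marker_genome(active = FALSE, provenance = "sens"),
                         strain = "sens")
  expect_length(active_resistance(recipient), 0L)
  cargo <- genes("resistance", drug = "CAM", active = TRUE, provenance = "res")
  set.seed(1)
  out <- inject_transduced(recipient, cargo, p_recomb = 1)
  expect_identical(active_resistance(out), "CAM")
  # donor provenance is preserved on the transferred copy
  got <- out$genome$genes
  expect_true(any(got$provenance == "res" & got$active %in% TRUE))
  expect_true(any(got$provenance == "sens" & got$active %in% FALSE))
})

test_that("recombination probability zero leaves the genome unchanged", {
  recipient <- bacterium(marker_genome(active = FALSE))
  cargo <- genes("resistance", drug = "ERM", active = TRUE, provenance = "res")
  out <- inject_transduced(recipient, cargo, p_recomb = 0)
  expect_identical(out$genome, recipient$genome)
})

test_that("neutral cargo is recorded with donor provenance without a phenotype change", {
  recipient <- bacterium(marker_genome(active = FALSE, provenance = "sens"))
  cargo <- genes(c("accessory", "accessory"), provenance = "res")
  out <- inject_transduced(recipient, cargo, p_recomb = 1)
  expect_length(active_resistance(out), 0L)
  expect_equal(sum(out$genome$genes$provenance == "res"), 2L)
  expect_length(out$genome$loci, length(recipient$genome$loci) + 2L)
})

test_that("fitness is (1 - cost)^k in the number of active resistance genes", {
  b0 <- bacterium(marker_genome(active = FALSE))
  b1 <- bacterium(marker_genome(active = TRUE))
  b2 <- inject_transduced(b1, genes("resistance", drug = "ERM", active = TRUE,
                                    provenance = "x"), p_recomb = 1)
  expect_equal(fitness(b0, cost = 0.05), 1.0)
  expect_equal(fitness(b1, cost = 0.05), 0.95)
  expect_equal(fitness(b2, cost = 0.05), 0.9025)
  expect_error(fitness(b1, cost = 1), "cost")
  expect_error(fitness(b1, cost = -0.1), "cost")
})

test_that("antibiotic action stresses all exposed cells and kills after the delay", {
  sens <- bacterium(marker_genome(active = FALSE))
  res <- bacterium(marker_genome(active = TRUE))
  # no drugs: stress resets
  out <- antibiotic_action(bacterium(marker_genome(), stress = 20),
                           character(0))
  expect_true(out$alive)
  expect_equal(out$bacterium$stress, 0)
  # resistant cell survives but is stressed (antibiotic-associated induction)
  out <- antibiotic_action(res, "CAM", stress_on_exposure = 20)
  expect_true(out$alive)
  expect_equal(out$bacterium$stress, 20)
  expect_equal(out$bacterium$exposures, 0L)
  # sensitive cell: tolerates drug_delay exposures, then certain death
  b <- sens
  set.seed(1)
  for (i in 1:2) {
    out <- antibiotic_action(b, "CAM", p_kill = 1, drug_delay = 2L)
    expect_true(out$alive)
    b <- out$bacterium
    expect_equal(b$exposures, i)
    expect_equal(b$stress, 20)
  }
  out <- antibiotic_action(b, "CAM", p_kill = 1, drug_delay = 2L)
  expect_false(out$alive)
})

test_that("adsorption resolution honours immunity, transduction and lifestyle", {
  gt <- tiny_phage(p_GT = 0.5, burst_size = 12L)
  lysogen <- bacterium(phagetrans:::genome_add_prophage(marker_genome(), gt))
  # functional virion on a lysogen of its own immunity group is blocked
  out <- resolve_adsorption(lysogen, virion(gt), n_local_free = 5L)
  expect_identical(out$event, "blocked")
  # a transducing particle injects regardless of immunity
  cargo <- genes("resistance", drug = "ERM", active = TRUE, provenance = "res")
  set.seed(2)
  out <- resolve_adsorption(lysogen, virion(gt, "bacterial_dna", cargo),
                            n_local_free = 5L)
  expect_identical(out$event, "transduced")
  expect_true("ERM" %in% active_resistance(out$bacterium))
  # virulent functional virion on a susceptible host always lyses
  vir <- phage_genotype("virulent", p_GT = 0, burst_size = 7L, headful = 3L,
                        id = 1L)
  out <- resolve_adsorption(bacterium(marker_genome()), virion(vir),
                            n_local_free = 100L)
  expect_identical(out$event, "lysed")
  expect_null(out$bacterium)
  expect_length(out$burst, 7L)
})

test_that("domain invariants of genes, genomes, genotypes and virions hold", {
  expect_error(genes("resistance"), "drug")
  expect_error(genes("essential", drug = "CAM"), "resistance")
  expect_error(genes("nonsense"), "category")
  g <- marker_genome()
  expect_false(is_lysogen(g))
  gt <- tiny_phage()
  gl <- phagetrans:::genome_add_prophage(g, gt)
  expect_true(is_lysogen(gl))
  # one prophage per immunity group
  expect_error(phagetrans:::genome_add_prophage(gl, gt), "immunity")
  # transducing cargo cannot exceed headful capacity
  too_big <- genes(rep("accessory", 5), provenance = "x")
  expect_error(virion(tiny_phage(headful = 3L), "bacterial_dna", too_big),
               "headful")
  expect_error(phage_genotype("temperate", p_GT = 1.5), "p_GT")
})
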