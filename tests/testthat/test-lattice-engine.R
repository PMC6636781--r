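# Lattice engine: shuffling, roulette reproduction, phase scheduling,
# conservation audits and reproducibility.

test_that("well-mixed shuffling conserves counts and single occupancy", {
  cfg <- tiny_config(n = 50L, moi = 3)
  set.seed(5)
  st <- new_lattice(cfg)
  init_population(st, "A", 50L)
  phagetrans:::add_virions(st, 150L, 1L)
  for (i in 1:10) {
    randomize_positions(st)
    expect_equal(sum(st$occ), 50L)
    expect_length(st$vsite, 150L)
    expect_true(all(st$vsite >= 1L & st$vsite <= st$n_sites))
  }
  # determinism: identical seeds give identical layouts
  set.seed(99); randomize_positions(st)
  occ1 <- st$occ; v1 <- st$vsite
  set.seed(99); randomize_positions(st)
  expect_identical(st$occ, occ1)
  expect_identical(st$vsite, v1)
})

test_that("roulette reproduction picks parents proportionally to fitness", {
  # two candidate parents with weights 2:1 -> frequencies 2/3 vs 1/3
  w <- matrix(rep(c(0.9, 0.45, 0, 0, 0, 0, 0, 0), each = 1e4), nrow = 1e4)
  set.seed(8)
  pick <- phagetrans:::roulette_pick(w)
  f1 <- mean(pick == 1L)
  se <- sqrt((2 / 3) * (1 / 3) / 1e4)
  expect_lt(abs(f1 - 2 / 3), 3 * se)
  expect_true(all(pick %in% 1:2))
})

test_that("reproduction fills free sites from neighbours and respects snapshots", {
  cfg <- tiny_config(n = 1L)
  set.seed(21)
  st <- new_lattice(cfg)
  # lone bacterium: its 8 neighbour sites are filled by exact copies
  phagetrans:::place_bacteria(st, 1L, st$ctx$founders[1], 1L)
  site <- which(st$occ)
  reproduction_step(st)
  expect_equal(sum(st$occ), 9L)
  expect_true(all(st$occ[st$nb[site, ]]))
  expect_true(all(st$gid[st$occ] == st$ctx$founders[1]))
  # a site with no living neighbour stays empty
  expect_equal(sum(st$occ), 9L)
})

test_that("a bacteria-only lattice grows to carrying capacity and stays there", {
  cfg <- tiny_config(width = 10L, height = 10L, n = 10L, record = TRUE)
  sim <- run_simulation(cfg, seed = 31)
  expect_true(all(sim$series$n_bacteria <= 100L))
  expect_gt(sim$series$n_bacteria[50], 90L)  # free space is the resource
  expect_false(sim$outcome$phage_survived)
  expect_true(sim$outcome$bacteria_survived)
})

test_that("an empty lattice steps to an empty lattice with the clock advanced", {
  cfg <- tiny_config(n = 1L, iterations = 5L)
  cfg$populations <- list()
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(sim$outcome$final_iteration, 5L)
  expect_false(sim$outcome$bacteria_survived)
  expect_false(sim$outcome$phage_survived)
  expect_true(all(sim$series$n_bacteria == 0L))
})

test_that("lysogens induce at the spontaneous rate when unstressed", {
  # alpha = 1e3: spontaneous induction probability 1/1001 per lysogen per
  # iteration; audit the realized count over ~1e5 lysogen-iterations
  cfg <- tiny_config(width = 20L, height = 20L, n = 400L, lysogen = TRUE,
                     alpha = 1e3, iterations = 250L, record = TRUE)
  sim <- run_simulation(cfg, seed = 13)
  exposure <- sum(sim$series$n_lysogens)
  expect_gt(exposure, 5e4)
  p <- 1 / 1001
  expected <- exposure * p
  se <- sqrt(exposure * p * (1 - p))
  got <- sim$series$cum_inductions[nrow(sim$series)]
  expect_lt(abs(got - expected), 3 * se + 1)
})

test_that("virion book-keeping balances bursts, adsorption and decay", {
  cfg <- tiny_config(n = 30L, moi = 2, iterations = 60L)
  set.seed(17)
  ctx <- phagetrans:::new_context(cfg$strains, cfg$genotypes, cfg$drugs)
  st <- phagetrans:::new_state(ctx, cfg)
  phagetrans:::place_bacteria(st, 30L, ctx$founders[1], 1L)
  phagetrans:::add_virions(st, 60L, 1L)
  phagetrans:::run_state(st, 60L)
  expect_equal(length(st$vsite),
               st$cum_virions_in - st$cum_adsorbed - st$cum_decayed)
  # a lysogen is never productively infected by its own immunity group
  expect_equal(st$audit_immune_lysed, 0L)
})

test_that("without transduction no genome gains genes absent from its founder", {
  cfg <- tiny_config(n = 30L, moi = 2, iterations = 80L, p_GT = 0)
  cfg$genotypes[[1]]$p_GT <- 0
  sim <- run_simulation(cfg, seed = 23, keep_state = TRUE)
  st <- sim$state
  r <- st$ctx$reg
  expect_equal(st$cum_trans, 0L)
  founder_genes <- sort(phagetrans:::reg_np(r, st$ctx$founders[1]))
  for (gid in seq_len(r$n)) {
    got <- phagetrans:::reg_np(r, gid)
    expect_true(all(got[got > 0L] %in% founder_genes))
  }
})

test_that("identical config and seed reproduce the run bitwise", {
  cfg <- tiny_config(n = 25L, moi = 1, iterations = 40L, record = TRUE)
  s1 <- run_simulation(cfg, seed = 77)
  s2 <- run_simulation(cfg, seed = 77)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$class_counts, s2$class_counts)
  expect_identical(s1$outcome, s2$outcome)
  s3 <- run_simulation(cfg, seed = 78)
  expect_false(identical(s1$series, s3$series))
})

test_that("replicate runner derives reproducible per-replicate seeds", {
  cfg <- tiny_config(n = 20L, iterations = 20L)
  rr <- run_replicates(cfg, 5L, master_seed = 3L)
  expect_equal(nrow(rr$outcomes), 5L)
  expect_true(all(rr$outcomes$bacteria_survived))
  expect_equal(rr$survival$joint, rr$survival$phage)
  # replicate k is reproducible in isolation from its recorded seed
  cfg2 <- cfg; cfg2$record <- FALSE; cfg2$record_classes <- FALSE
  again <- run_simulation(cfg2, rr$outcomes$seed[3])
  expect_equal(again$outcome$bacteria_survived, rr$outcomes$bacteria_survived[3])
  rr2 <- run_replicates(cfg, 5L, master_seed = 3L)
  expect_identical(rr$outcomes, rr2$outcomes)
})
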