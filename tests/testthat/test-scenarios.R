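# Scenario definitions, the two-phase protocol, the gene-shuffling
# experiment and the lysate-capacity arithmetic.

test_that("the four phage scenarios differ only in lifestyle and p_GT", {
  cfgs <- lapply(c("S1_temperate_GT", "S2_temperate_nonGT", "S3_virulent_GT",
                   "S4_virulent_nonGT"), scenario_config)
  expect_equal(cfgs[[1]]$genotypes[[1]]$lifestyle, "temperate")
  expect_equal(cfgs[[2]]$genotypes[[1]]$lifestyle, "temperate")
  expect_equal(cfgs[[3]]$genotypes[[1]]$lifestyle, "virulent")
  expect_equal(cfgs[[4]]$genotypes[[1]]$lifestyle, "virulent")
  expect_gt(cfgs[[1]]$p_GT, 0); expect_equal(cfgs[[2]]$p_GT, 0)
  expect_gt(cfgs[[3]]$p_GT, 0); expect_equal(cfgs[[4]]$p_GT, 0)
  # every other scalar parameter is shared across the four designs
  shared <- setdiff(names(phagetrans:::sim_defaults()), "p_GT")
  for (key in shared) {
    vals <- lapply(cfgs, `[[`, key)
    expect_length(unique(vals), 1)
  }
})

test_that("scenario initializers build the configured genomes", {
  cfg <- scenario_config("S1_temperate_GT", width = 15L, height = 15L)
  st <- new_lattice(cfg)
  ctx <- st$ctx
  r <- ctx$reg
  # resistant strain: active marker; sensitive strain: inactive copy present
  expect_gt(r$res_mask[ctx$founders["res"]], 0L)
  expect_equal(r$res_mask[ctx$founders["sens"]], 0L)
  sens_genes <- ctx$genes[ctx$genes$provenance == "sens", ]
  expect_true(any(sens_genes$category == "resistance" &
                    sens_genes$active %in% FALSE))
  # constructor contract: placed cells carry the founder genome
  init_population(st, "res", 20L)
  expect_equal(sum(st$occ), 20L)
  expect_true(all(st$gid[st$occ] == ctx$founders["res"]))
  expect_error(init_population(st, "nope", 5L), "unknown strain")
  expect_error(init_population(st, "res", 1e6), "free lattice")
})

test_that("scenario construction is pure: same config and seed, same lattice", {
  cfg <- scenario_config("FIG6_two_lysogens", width = 15L, height = 15L)
  mk <- function() {
    set.seed(4)
    st <- new_lattice(cfg)
    for (p in cfg$populations) init_population(st, p$strain, p$n)
    list(occ = st$occ, gid = st$gid, strain = st$strain)
  }
  expect_identical(mk(), mk())
})

test_that("the two-lysogen design mixes complementary resistant lysogens 1:1", {
  cfg <- scenario_config("FIG6_two_lysogens")
  expect_equal(cfg$populations[[1]]$n, cfg$populations[[2]]$n)
  st <- new_lattice(cfg)
  ctx <- st$ctx
  r <- ctx$reg
  fA <- ctx$founders["lysogenA"]; fB <- ctx$founders["lysogenB"]
  expect_true(r$is_lys[fA] && r$is_lys[fB])
  # same immunity group, complementary markers
  expect_equal(r$imm_mask[fA], r$imm_mask[fB])
  expect_equal(bitwAnd(r$res_mask[fA], r$res_mask[fB]), 0L)
  expect_equal(r$n_active[fA], 1L)
  expect_equal(r$n_active[fB], 1L)
  # dual-drug schedule at iteration 10
  expect_setequal(cfg$drugs, c("ERM", "CAM"))
  expect_equal(cfg$drug_start, 10L)
})

test_that("the phase-2 sample contains no transducing particles when p_GT = 0", {
  cfg <- scenario_config("S2_temperate_nonGT", width = 20L, height = 20L,
                         total_iterations = 15L, record = FALSE,
                         record_classes = FALSE)
  s <- run_two_phase(cfg, seed = 9)
  expect_gt(s$sample$sampled, 0L)
  expect_equal(s$sample$transducing, 0L)
})

test_that("a transducing temperate phage yields a mixed lysate sample", {
  cfg <- scenario_config("S1_temperate_GT", width = 20L, height = 20L,
                         total_iterations = 15L, record = FALSE,
                         record_classes = FALSE)
  s <- run_two_phase(cfg, seed = 9)
  expect_gt(s$sample$functional, 0L)
  expect_gt(s$sample$transducing, 0L)
  expect_equal(s$sample$functional + s$sample$transducing, s$sample$sampled)
})

test_that("an empty phase-1 lysate warns and proceeds with an empty sample", {
  cfg <- scenario_config("S1_temperate_GT", width = 12L, height = 12L,
                         moi = 0, total_iterations = 12L, record = FALSE,
                         record_classes = FALSE)
  expect_warning(s <- run_two_phase(cfg, seed = 2), "no free virions")
  expect_equal(s$sample$sampled, 0L)
  expect_true(s$outcome$bacteria_survived)   # nothing attacks the bacteria
  expect_false(s$outcome$phage_survived)
})

test_that("without prophages the gene-shuffling design never makes double resistants", {
  cfg <- scenario_config("S4A_no_prophage", width = 20L, height = 20L,
                         record = FALSE, record_classes = FALSE)
  for (seed in 1:3) {
    s <- run_gene_shuffling(cfg, seed)
    expect_equal(s$double_resistant$created, 0L)
    expect_equal(s$double_resistant$final, 0L)
    expect_false(s$outcome$bacteria_survived)  # each strain resists one drug
  }
})

test_that("lysate capacity arithmetic reproduces the worked example exactly", {
  out <- lysate_capacity(1e9, 1 / 700, 43e3, genome_bp = 2.8e6)
  expect_equal(out$transducing_per_ml, 1e9 / 700)
  expect_equal(out$transduced_bp_per_ml, 1e9 / 700 * 43e3)
  expect_equal(out$transduced_bp_per_ml, 6.142857e10, tolerance = 1e-6)
  expect_gt(out$genome_equivalents_per_ml, 2e4)
  expect_equal(out$genome_equivalents_per_ml, 21938.78, tolerance = 1e-6)
  zero <- lysate_capacity(1e9, 0, 43e3)
  expect_equal(zero$transducing_per_ml, 0)
  expect_equal(zero$transduced_bp_per_ml, 0)
  expect_equal(zero$genome_equivalents_per_ml, 0)
  expect_error(lysate_capacity(0, 1 / 700, 43e3), "pfu")
  expect_error(lysate_capacity(1e9, -1, 43e3), "ratio")
  expect_error(lysate_capacity(1e9, 1 / 700, 43e3, genome_bp = 0), "genome_bp")
})
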