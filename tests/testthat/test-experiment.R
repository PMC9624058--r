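test_that("scenario expansion prunes inapplicable factor combinations", {
  # phenotypic arm of the design: 2 policies x 3 h2 x 2 replication levels
  ph <- expand_scenarios("rsa", criteria = "phenotype")
  expect_equal(nrow(ph), 12)
  expect_false(anyDuplicated(ph$scenario_id) > 0)
  # multi-stage architecture: exactly 4 scenarios
  ay <- expand_scenarios("rsay")
  expect_equal(nrow(ay), 4)
  # genomic arm: Ne only under OCS
  gs <- expand_scenarios("rsa", criteria = "gebv")
  expect_true(all(is.na(gs$min_Ne[gs$gs_mode == "truncation"])))
  expect_equal(nrow(gs[gs$gs_mode == "ocs", ]), 36)
  expect_error(expand_scenarios("rsa", policies = character(0)),
               "empty factor list")
})

test_that("replicate seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(1, "rsa_phenotype_disc_h0.1_r1", 1)
  expect_identical(s1, derive_seed(1, "rsa_phenotype_disc_h0.1_r1", 1))
  expect_false(s1 == derive_seed(1, "rsa_phenotype_disc_h0.1_r1", 2))
  expect_false(s1 == derive_seed(1, "rsa_phenotype_over_h0.1_r1", 1))
  expect_false(s1 == derive_seed(2, "rsa_phenotype_disc_h0.1_r1", 1))
  seeds <- sapply(1:50, function(r) derive_seed(3, "x", r))
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("experiments write one reproducible CSV per scenario-replicate", {
  plan <- expand_scenarios("rsa", policies = "discrete",
                           criteria = "tbv", h2_levels = 0.5)
  dir1 <- file.path(tempdir(), "exp1")
  dir2 <- file.path(tempdir(), "exp2")
  ov <- list(n_cycles = 3L, n_founders = 30L, n_crosses = 30L,
             n_parents = 8L,
             spec = small_spec(sites = 100, qtl = 15, chip = 15))
  res <- quiet(run_experiment(plan, n_replicates = 3, base_seed = 5,
                              out_dir = dir1, scale = "reduced",
                              overrides = ov))
  expect_equal(nrow(res), 9) # 3 replicates x 3 cycles
  files1 <- list.files(dir1, full.names = TRUE)
  expect_length(files1, 3)
  quiet(run_experiment(plan, n_replicates = 3, base_seed = 5,
                       out_dir = dir2, scale = "reduced",
                       overrides = ov))
  files2 <- list.files(dir2, full.names = TRUE)
  expect_identical(lapply(files1, readLines), lapply(files2, readLines))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("timepoint contrasts behave like Welch tests on pairs", {
  mk <- function(id, vals) {
    data.frame(replicate = seq_along(vals), cycle_or_year = 20,
               scenario_id = id, mean_genetic_value = vals)
  }
  # identical replicate values: estimate 0, p = 1
  same <- rbind(mk("rsa_x_disc_h0.1", c(1, 2, 3)),
                mk("rsa_x_over_h0.1", c(1, 2, 3)))
  ct <- timepoint_contrasts(same, "mean_genetic_value", 20)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p, 1)
  # a known shift of 1 at sigma = 0.1, n = 10 is detected with power
  set.seed(1)
  shift <- rbind(mk("rsa_y_disc_h0.1", rnorm(10, 1, 0.1)),
                 mk("rsa_y_over_h0.1", rnorm(10, 0, 0.1)))
  ct2 <- timepoint_contrasts(shift, "mean_genetic_value", 20)
  expect_lt(ct2$p, 1e-6)
  expect_gt(ct2$estimate, 0.5)
  # swapping the arms flips the estimate's sign, p unchanged
  swapped <- shift
  swapped$scenario_id <- ifelse(grepl("_disc", shift$scenario_id),
                                sub("_disc", "_over", shift$scenario_id),
                                sub("_over", "_disc", shift$scenario_id))
  ct3 <- timepoint_contrasts(swapped, "mean_genetic_value", 20)
  expect_equal(ct3$estimate, -ct2$estimate)
  expect_equal(ct3$p, ct2$p)
  # missing timepoint (truncated scenario) flagged unavailable
  over_rows <- mk("rsa_z_over_h0.1", c(1, 2))
  over_rows$cycle_or_year <- 10 # truncated before the contrast point
  trunc <- rbind(mk("rsa_z_disc_h0.1", c(1, 2, 3)), over_rows)
  ct4 <- timepoint_contrasts(trunc, "mean_genetic_value", 20)
  expect_false(ct4$available)
})

test_that("one-sample tests handle structural constants", {
  mk <- function(id, vals) {
    data.frame(replicate = seq_along(vals), cycle_or_year = 40,
               scenario_id = id, mean_parental_age = vals)
  }
  # zero-variance replicates equal to the null: no difference
  const <- mk("rsay_phenotype_disc", rep(3.67, 10))
  t1 <- one_sample_tests(const, "mean_parental_age", 40, 3.67, 4)
  expect_equal(t1$p_bonferroni, 1)
  expect_false(t1$exact_difference)
  # clearly shifted values survive Bonferroni correction
  set.seed(2)
  shifted <- mk("rsay_phenotype_over", rnorm(10, 2, 0.1))
  t2 <- one_sample_tests(shifted, "mean_parental_age", 40, 1, 12)
  expect_lt(t2$p_bonferroni, 0.05)
  # zero variance away from the null: flagged exact
  t3 <- one_sample_tests(const, "mean_parental_age", 40, 1, 1)
  expect_true(t3$exact_difference)
  expect_equal(t3$p, 0)
})

test_that("scenario YAML configuration round-trips", {
  path <- system.file("extdata", "example_rsa_scenarios.yaml",
                      package = "recselsim")
  expect_true(nzchar(path))
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg$plan, "data.frame")
  expect_gt(nrow(cfg$plan), 0)
  expect_true(all(c("scenario_id", "architecture") %in% names(cfg$plan)))
})
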