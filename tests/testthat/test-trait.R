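test_that("QTL effect scaling hits the target variance exactly", {
  pop <- small_founders(50, sites = 200, qtl = 30, chip = 20)
  trait <- assign_qtl_effects(pop, target_variance = 1, seed = 3)
  tbv <- true_breeding_value(pop, trait)
  expect_equal(var(tbv), 1, tolerance = 1e-9)
  expect_equal(mean(tbv), 0, tolerance = 1e-9)
  # QTL and chip sites disjoint
  for (chr in 1:2) {
    expect_length(intersect(trait$qtl_sites[[chr]],
                            trait$chip_sites[[chr]]), 0)
  }
  # linear rescaling: target 4 doubles every effect for the same seed
  trait4 <- assign_qtl_effects(pop, target_variance = 4, seed = 3)
  tbv4 <- true_breeding_value(pop, trait4)
  expect_equal(var(tbv4), 4, tolerance = 1e-9)
  expect_equal(trait4$qtl_effects, 2 * trait$qtl_effects,
               tolerance = 1e-12)
})

test_that("single-locus scaling reproduces the closed form", {
  # five founders with dosages {0, 2, 1, 1, 1}: p = 0.5 and the dosage
  # variance equals 2p(1-p) = 0.5 exactly, so 2p(1-p) a^2 = target
  pop <- pattern_population(list(c(0L, 0L), c(1L, 1L), c(1L, 0L),
                                 c(1L, 0L), c(1L, 0L)))
  trait <- assign_qtl_effects(pop, qtl_per_chromosome = 1,
                              target_variance = 1, seed = 1)
  a <- trait$qtl_effects
  expect_equal(2 * 0.5 * 0.5 * a^2, 1, tolerance = 1e-12)
  tbv <- true_breeding_value(pop, trait)
  expect_equal(var(tbv), 1, tolerance = 1e-12)
})

test_that("true breeding values are deterministic dosage sums", {
  pop <- small_founders(10)
  trait <- assign_qtl_effects(pop, seed = 1)
  # doubled haploid: TBV equals its duplicated gamete's dosage score
  dh <- make_dh(pop, 1, birth = 1)
  d <- dosages(dh, trait$qtl_sites)
  expect_equal(unname(true_breeding_value(dh, trait)),
               as.vector(d %*% trait$qtl_effects) + trait$intercept)
  # genome spec mismatch is rejected
  other <- small_founders(4, nchr = 3, sites = 60, qtl = 5, chip = 5)
  expect_error(true_breeding_value(other, trait), "spec")
})

test_that("error variance follows sigma_G^2 (1-h2)/h2 / reps", {
  expect_equal(error_variance_for_h2(0.5, 1, 1), 1)
  expect_equal(error_variance_for_h2(0.1, 1, 1), 9)
  expect_equal(error_variance_for_h2(0.1, 1, 3), 3)
  expect_equal(error_variance_for_h2(1, 1, 1), 0)
  expect_error(error_variance_for_h2(0, 1, 1), "h2")
})

test_that("year effects are cached and correctly dispersed", {
  env0 <- environment_model(year_variance = 0)
  expect_identical(sapply(1:5, function(y) sample_year_effect(env0, y)),
                   rep(0, 5))
  env <- environment_model(year_variance = 0.2)
  set.seed(1)
  v1 <- sample_year_effect(env, 3)
  v2 <- sample_year_effect(env, 3) # cached, no redraw
  expect_identical(v1, v2)
  set.seed(2)
  ys <- sapply(1:10000, function(y) sample_year_effect(env, y + 100))
  se <- 0.2 * sqrt(2 / (length(ys) - 1))
  expect_lt(abs(var(ys) - 0.2), 3 * se)
})

test_that("genotype-by-year effects follow the scaled distribution", {
  pop <- small_founders(40, sites = 200, qtl = 30, chip = 20)
  trait <- assign_qtl_effects(pop, seed = 2)
  env0 <- environment_model(gxy_variance = 0)
  expect_identical(assign_gxy_effects(trait, env0, 1),
                   rep(0, length(trait$qtl_effects)))
  env <- environment_model()
  set.seed(3)
  b1 <- assign_gxy_effects(trait, env, 1)
  expect_identical(b1, assign_gxy_effects(trait, env, 1)) # cached
  # independent across years
  b2 <- assign_gxy_effects(trait, env, 2)
  expect_lt(abs(cor(b1, b2)), 4 / sqrt(length(b1)))
  # draw variance matches sigma_a^2 sigma_ay^2 / sigma_G^2
  set.seed(4)
  bs <- replicate(300, assign_gxy_effects(trait, environment_model(), 1))
  v_target <- trait$effect_variance * 0.2 / trait$base_genetic_variance
  expect_equal(mean(apply(bs, 2, var)), v_target, tolerance = 0.15)
})

test_that("realized GxY variance in the base population targets 0.2", {
  # averaged over replicate founder draws, trait draws and years; the
  # realized value disperses with the particular effect draw because the
  # scaling formula assumes linkage equilibrium
  set.seed(9)
  reps <- sapply(1:6, function(r) {
    pop <- quiet(generate_founders(genome_spec(), 100))
    trait <- assign_qtl_effects(pop)
    env <- environment_model()
    mean(sapply(1:15, function(y) var(gxy_deviation(pop, trait, env, y))))
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.2), 3 * se + 0.01)
})

test_that("phenotype records decompose exactly and calibrate to h2", {
  pop <- small_founders(400, sites = 150, qtl = 25, chip = 20, seed = 8)
  trait <- assign_qtl_effects(pop, seed = 8)
  # h2 = 1: phenotype is the TBV
  ph1 <- make_phenotypes(pop, trait, herit_spec("narrow", 1))
  expect_equal(ph1$phenotype, ph1$tbv)
  # h2 = 0.5: corr(phenotype, TBV) ~ sqrt(0.5)
  set.seed(10)
  ph <- make_phenotypes(pop, trait, herit_spec("narrow", 0.5), year = 1)
  r <- cor(ph$phenotype, ph$tbv)
  expect_lt(abs(r - sqrt(0.5)), 3 * (1 - 0.5) / sqrt(400) + 0.02)
  # errors independent of TBV
  expect_lt(abs(cor(ph$plot_error, ph$tbv)), 0.15)
  # thrice-replicated phenotypes at h2 = 0.1: residual variance ~ 3
  set.seed(11)
  ph3 <- make_phenotypes(pop, trait, herit_spec("narrow", 0.1, 3))
  expect_lt(abs(var(ph3$phenotype - ph3$tbv) - 3),
            3 * 3 * sqrt(2 / 399) + 0.1)
})

test_that("compound-symmetry phenotypes share year effects in a trial", {
  pop <- small_founders(30)
  trait <- assign_qtl_effects(pop, seed = 5)
  env <- environment_model()
  set.seed(6)
  ph <- make_phenotypes(pop, trait, herit_spec("broad", 0.2), year = 4,
                        env = env, stage = "pyt")
  expect_equal(length(unique(ph$year_effect)), 1L)
  expect_equal(ph$year_effect[1L], sample_year_effect(env, 4))
  # exact component bookkeeping
  expect_equal(ph$phenotype,
               ph$tbv + ph$year_effect + ph$gxy + ph$plot_error)
  expect_error(make_phenotypes(pop, trait, herit_spec("broad", 0.2)),
               "EnvironmentModel")
  # alternative H2 denominator including the GxY variance
  set.seed(7)
  ph2 <- make_phenotypes(pop, trait, herit_spec("broad", 0.5), year = 4,
                         env = env, h2_denominator = "with_gxy")
  expect_equal(nrow(ph2), 30)
})
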