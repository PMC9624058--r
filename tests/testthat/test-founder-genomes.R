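test_that("founder generation is deterministic and fully segregating", {
  spec <- genome_spec()
  p1 <- quiet(generate_founders(spec, 100, seed = 1))
  p2 <- quiet(generate_founders(spec, 100, seed = 1))
  expect_identical(p1$haplo, p2$haplo)
  expect_identical(p1$ibd, p2$ibd)
  expect_equal(n_ind(p1), 100)
  for (chr in 1:10) {
    expect_equal(dim(p1$haplo[[chr]]), c(200L, 1000L))
    cs <- colSums(p1$haplo[[chr]])
    expect_true(all(cs >= 1 & cs <= 199)) # every site segregates
    # one unique IBD label per founder haplotype per chromosome
    labs <- p1$ibd[[chr]][, 1L]
    expect_equal(sort(labs), (chr - 1L) * 200L + 0:199)
    expect_true(all(p1$ibd[[chr]] == labs[row(p1$ibd[[chr]])]))
  }
})

test_that("tiny founder populations keep every site polymorphic", {
  spec <- genome_spec(1, 4, 1, 1, 0)
  pop <- quiet(generate_founders(spec, 2, seed = 5))
  cs <- colSums(pop$haplo[[1]])
  expect_true(all(cs >= 1 & cs <= 3))
  expect_error(generate_founders(spec, 1), "n_individuals")
})

test_that("meiosis respects the genetic map", {
  # map length 0: gamete is one intact parental haplotype
  spec0 <- genome_spec(2, 50, map_length = 0, qtl_per_chromosome = 5,
                       chip_per_chromosome = 5)
  pop0 <- quiet(generate_founders(spec0, 4, seed = 2))
  g <- meiosis(pop0, 1)
  for (chr in 1:2) {
    h <- g$haplo[[chr]]
    expect_true(identical(h, pop0$haplo[[chr]][1L, ]) ||
                  identical(h, pop0$haplo[[chr]][2L, ]))
  }
  # fully homozygous parent: gamete equals either haplotype everywhere
  pop <- small_founders(6)
  dh <- make_dh(pop, 1, birth = 1)
  gdh <- meiosis(combine_pop(pop, dh), dh$meta$id)
  for (chr in 1:2) {
    expect_identical(gdh$haplo[[chr]],
                     subset_pop(dh, dh$meta$id)$haplo[[chr]][1L, ])
  }
})

test_that("crossover counts are Poisson with mean = map length", {
  # crossovers observed as IBD-label switches along founder gametes
  spec <- genome_spec(1, 500, 1.0, 10, 0)
  pop <- quiet(generate_founders(spec, 2, seed = 7))
  prog <- make_cross(pop, 1, 2, 1500, birth = 1)
  switches <- apply(prog$ibd[[1]], 1L, function(r) sum(diff(r) != 0))
  n <- length(switches) # 3000 gametes
  se <- sqrt(1 / n)     # Poisson(1) variance
  expect_lt(abs(mean(switches) - 1.0), 3 * se + 0.01)
})

test_that("crossing tracks pedigree and IBD inheritance", {
  pop <- small_founders(10)
  prog <- make_cross(pop, 1, 2, 97, birth = 3)
  expect_equal(n_ind(prog), 97)
  expect_true(all(prog$meta$birth == 3L))
  parent_labels <- c(pop$ibd[[1]][1:4, 1L], pop$ibd[[2]][1:4, 1L])
  for (chr in 1:2) {
    expect_true(all(prog$ibd[[chr]] %in% parent_labels))
  }
  expect_error(make_cross(pop, 1, 1, 5, birth = 1), "selfing")
})

test_that("crossing clones yields inbred progeny at the pedigree rate", {
  pop <- small_founders(8, sites = 200)
  # clone individual 1 under a fresh id
  clone <- subset_pop(pop, 1)
  clone$meta$id <- 99L
  both <- combine_pop(pop, clone)
  prog <- make_cross(both, 1, 99, 150, birth = 1)
  # F = coancestry of parent with itself = 0.5 for a non-inbred founder
  Fs <- sapply(seq_len(n_ind(prog)), function(i) {
    mean(unlist(lapply(1:2, function(chr) {
      prog$ibd[[chr]][2L * i - 1L, ] == prog$ibd[[chr]][2L * i, ]
    })))
  })
  expect_lt(abs(mean(Fs) - 0.5), 0.05)
})

test_that("doubled haploids are completely homozygous copies of a gamete", {
  pop <- small_founders(6)
  dh <- make_dh(pop, c(1, 2, 3), birth = 2)
  expect_equal(n_ind(dh), 3)
  for (chr in 1:2) {
    h1 <- dh$haplo[[chr]][c(TRUE, FALSE), , drop = FALSE]
    h2 <- dh$haplo[[chr]][c(FALSE, TRUE), , drop = FALSE]
    expect_identical(h1, h2)
    # every allele matches one of the source's two alleles
    for (j in 1:3) {
      src <- pop$haplo[[chr]][c(2L * j - 1L, 2L * j), , drop = FALSE]
      expect_true(all(h1[j, ] == src[1L, ] | h1[j, ] == src[2L, ]))
    }
  }
  # DH of a fully inbred source reproduces the source genotype
  dh2 <- make_dh(combine_pop(pop, dh), dh$meta$id[1L], birth = 3)
  expect_identical(dh2$haplo, subset_pop(dh, dh$meta$id[1L])$haplo)
})

test_that("IBD inbreeding matches pedigree expectations", {
  pop <- small_founders(10, sites = 200)
  expect_equal(ibd_inbreeding(pop), 0)
  # full sibs of two unrelated non-inbred parents: coancestry 0.25
  sibs <- make_cross(pop, 1, 2, 250, birth = 1)
  K <- ibd_kinship(combine_pop(pop, sibs), ids = sibs$meta$id)
  expect_lt(abs(mean(K[upper.tri(K)]) - 0.25), 0.02)
  # clonal DH copies share everything
  dh <- make_dh(pop, 1, birth = 1)
  all1 <- combine_pop(pop, dh)
  copies <- make_dh(all1, rep(dh$meta$id, 2), birth = 2)
  expect_equal(ibd_inbreeding(copies), 1)
  expect_error(ibd_inbreeding(pop, ids = 1), "at least 2")
})

test_that("ibd_inbreeding is invariant to individual ordering", {
  pop <- small_founders(8)
  prog <- make_cross(pop, 1, 2, 10, birth = 1)
  all_pop <- combine_pop(pop, prog)
  ids <- all_pop$meta$id
  expect_equal(ibd_inbreeding(all_pop, ids),
               ibd_inbreeding(all_pop, rev(ids)))
})

test_that("inbreeding accumulates under closed random mating", {
  for (seed in c(1, 2, 3, 4, 5)) {
    set.seed(seed)
    pop <- quiet(generate_founders(small_spec(sites = 80), 12))
    cur <- pop
    f <- numeric(20)
    for (gen in 1:20) {
      plan <- recselsim:::.random_cross_plan(cur$meta$id, 12)
      nxt <- make_crosses(cur, plan, birth = gen)
      nxt$meta$id <- seq_len(12) + gen * 1000L
      f[gen] <- ibd_inbreeding(nxt)
      cur <- nxt
    }
    expect_gt(stats::coef(stats::lm(f ~ seq_along(f)))[2L], 0)
  }
})

test_that("PLINK export writes consistent ped/map text", {
  pop <- small_founders(4, sites = 30, qtl = 10, chip = 10)
  tmp <- file.path(tempdir(), "plinktest")
  write_plink(pop, tmp)
  map <- read.table(paste0(tmp, ".map"))
  ped <- read.table(paste0(tmp, ".ped"))
  expect_equal(nrow(map), 60)
  expect_equal(nrow(ped), 4)
  expect_equal(ncol(ped), 6 + 2 * 60)
  unlink(paste0(tmp, c(".ped", ".map")))
})
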