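# Shared fixtures; everything is generated in code at test time.

small_spec <- function(nchr = 2, sites = 120, qtl = 20, chip = 20,
                       map = 1) {
  genome_spec(nchr, sites, map, qtl, chip)
}

small_founders <- function(n = 20, seed = 42, ...) {
  suppressMessages(generate_founders(small_spec(...), n, seed = seed))
}

quiet <- function(expr) suppressMessages(expr)

# Reduced multi-stage program sizes used throughout the suite: the same
# stage structure as the full design (crossing, DH, headrow -> 60,
# PYT -> 20, AYT -> 10, two elite years) at desk scale.
reduced_rsay <- function(policy = "discrete", criterion = "phenotype",
                         n_years = 15, ...) {
  rsay_config(policy, criterion, n_crosses = 20, progeny_per_cross = 10,
              advance = c(headrow = 60, pyt = 20, ayt = 10),
              n_years = n_years, ...)
}

.fixture_env <- new.env()

# Memoised 15-year discrete phenotypic multi-stage run (reused by the
# pipeline and acceptance tests).
rsay_discrete_fixture <- function() {
  if (is.null(.fixture_env$rsay_disc)) {
    .fixture_env$rsay_disc <-
      quiet(run_rsay_scenario(reduced_rsay(), seed = 11))
  }
  .fixture_env$rsay_disc
}

# Hand-built diploid population: one chromosome, every site carrying the
# same per-individual haplotype pattern. `hap_pairs` is a list of
# c(hap1, hap2) alleles per individual.
pattern_population <- function(hap_pairs, n_sites = 3, qtl = 1, chip = 1) {
  spec <- genome_spec(1, n_sites, 1, qtl, chip)
  n <- length(hap_pairs)
  H <- matrix(0L, 2L * n, n_sites)
  for (i in seq_len(n)) {
    H[2L * i - 1L, ] <- hap_pairs[[i]][1L]
    H[2L * i, ] <- hap_pairs[[i]][2L]
  }
  ibd <- matrix(rep(0:(2L * n - 1L), n_sites), nrow = 2L * n)
  meta <- data.frame(id = seq_len(n), mother = NA_integer_,
                     father = NA_integer_, birth = 0L, stage = "founder",
                     stringsAsFactors = FALSE)
  recselsim:::.new_population(spec, meta, list(H), list(ibd),
                              list((seq_len(n_sites) - 0.5) / n_sites))
}

# Brute-force simplex-grid maximum of g'c s.t. c'Kc <= theta, by
# enumerating compositions of `steps` into length(g) parts.
grid_ocs_oracle <- function(g, K, theta, steps) {
  n <- length(g)
  comp <- function(total, parts) {
    if (parts == 1L) return(matrix(total, ncol = 1L))
    out <- list()
    for (k in 0:total) {
      sub <- comp(total - k, parts - 1L)
      out[[k + 1L]] <- cbind(k, sub)
    }
    do.call(rbind, out)
  }
  C <- comp(steps, n) / steps
  obj <- as.vector(C %*% g)
  constr <- rowSums((C %*% K) * C)
  ok <- constr <= theta + 1e-12
  if (!any(ok)) return(NULL)
  list(objective = max(obj[ok]),
       c = C[ok, , drop = FALSE][which.max(obj[ok]), ])
}
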