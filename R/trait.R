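#' Assign additive QTL effects scaled to a target base genetic variance
#'
#' Samples QTL sites and SNP-chip sites uniformly, without replacement and
#' disjointly, from the segregating sites of each chromosome; draws raw
#' additive effects from N(0, 1); and multiplies all effects by a single
#' scalar chosen so that the sample variance of true breeding values (TBV)
#' across the founder population equals `target_variance` exactly. The
#' intercept is set so the founder mean TBV is 0.
#'
#' The variance of the scaled additive effects (sigma_a^2) is stored: it
#' enters the scaling of genotype-by-year effect draws (see
#' [assign_gxy_effects()]).
#'
#' @param founders Founder `Population`.
#' @param qtl_per_chromosome QTL count per chromosome (default from spec).
#' @param target_variance Target founder TBV variance (default 1).
#' @param seed Optional seed for locus sampling and effect draws.
#' @return A `TraitModel`: list with `qtl_sites`, `chip_sites`
#'   (per-chromosome site indices), `qtl_effects` (one vector over all
#'   QTL, chromosome-major), `intercept`, `base_genetic_variance`,
#'   `effect_variance`.
#' @export
assign_qtl_effects <- function(founders, qtl_per_chromosome = NULL,
                               target_variance = 1, seed = NULL) {
  spec <- founders$spec
  if (is.null(qtl_per_chromosome)) qtl_per_chromosome <- spec$qtl_per_chromosome
  if (qtl_per_chromosome > spec$sites_per_chromosome) {
    stop("more QTL requested than segregating sites")
  }
  if (!is.null(seed)) set.seed(seed)
  qtl_sites <- vector("list", spec$n_chromosomes)
  chip_sites <- vector("list", spec$n_chromosomes)
  for (chr in seq_len(spec$n_chromosomes)) {
    picked <- sample.int(spec$sites_per_chromosome,
                         qtl_per_chromosome + spec$chip_per_chromosome)
    qtl_sites[[chr]] <- sort(picked[seq_len(qtl_per_chromosome)])
    chip_sites[[chr]] <- sort(picked[qtl_per_chromosome +
                                       seq_len(spec$chip_per_chromosome)])
  }
  raw <- stats::rnorm(qtl_per_chromosome * spec$n_chromosomes)
  trait <- list(qtl_sites = qtl_sites, chip_sites = chip_sites,
                qtl_effects = raw, intercept = 0,
                base_genetic_variance = target_variance,
                effect_variance = NA_real_)
  class(trait) <- "TraitModel"
  d <- dosages(founders, qtl_sites)
  tbv_raw <- as.vector(d %*% raw)
  v_raw <- stats::var(tbv_raw)
  if (v_raw <= 0) stop("degenerate founder TBV variance; cannot scale effects")
  scale <- sqrt(target_variance / v_raw)
  trait$qtl_effects <- raw * scale
  trait$intercept <- -mean(tbv_raw) * scale
  trait$effect_variance <- stats::var(trait$qtl_effects)
  trait
}

#' True breeding value
#'
#' TBV = intercept + sum over QTL of allele dosage times additive effect.
#'
#' @param pop A `Population` matching the trait's genome spec.
#' @param trait A `TraitModel`.
#' @param ids Optional ids (default all).
#' @return Named numeric vector of TBVs.
#' @export
true_breeding_value <- function(pop, trait, ids = NULL) {
  if (length(trait$qtl_sites) != pop$spec$n_chromosomes) {
    stop("trait does not match the population's genome spec")
  }
  d <- dosages(pop, trait$qtl_sites, ids)
  out <- as.vector(d %*% trait$qtl_effects) + trait$intercept
  names(out) <- rownames(d)
  out
}

#' Plot-error variance for a target narrow-sense heritability
#'
#' Returns sigma_G^2 (1 - h^2) / h^2 divided by the phenotype replicate
#' count, i.e. the variance of the mean of `n_reps` independent plot
#' errors calibrated so a single unreplicated phenotype has heritability
#' `h2` against genetic variance `genetic_variance`.
#'
#' @param h2 Narrow-sense heritability in (0, 1].
#' @param genetic_variance Genetic variance (default 1).
#' @param n_reps Phenotype replicate count (default 1).
#' @return Error variance (0 when `h2` = 1).
#' @export
error_variance_for_h2 <- function(h2, genetic_variance = 1, n_reps = 1) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  stopifnot(n_reps >= 1)
  genetic_variance * (1 - h2) / h2 / n_reps
}

#' Heritability specification
#' @param kind "narrow" (h2; additive-only phenotypes) or "broad" (H2;
#'   stage-level trial precision in the multi-stage pipeline).
#' @param value Heritability in (0, 1].
#' @param n_reps Phenotype replicate count (>= 1).
#' @return A `HeritabilitySpec`.
#' @export
herit_spec <- function(kind = c("narrow", "broad"), value, n_reps = 1) {
  kind <- match.arg(kind)
  if (value <= 0 || value > 1) stop("heritability must be in (0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(kind = kind, value = value, n_reps = as.integer(n_reps)),
            class = "HeritabilitySpec")
}

#' Year and genotype-by-year effect model (compound symmetry)
#'
#' Holds the variances and the lazily drawn, cached per-year effects. Year
#' effects are N(0, `year_variance`) iid across years; per-QTL
#' genotype-by-year (GxY) effects for a year are iid
#' N(0, sigma_a^2 * sigma_ay^2 / sigma_G^2), independent across years, so
#' the realized GxY variance across the base population is approximately
#' `gxy_variance` for every year and the genetic covariance of one
#' genotype's phenotypes in two years equals sigma_G^2 (compound
#' symmetry).
#'
#' @param year_variance Variance of year effects (default 0.2).
#' @param gxy_variance Target additive-by-year variance (default 0.2).
#' @return An `EnvironmentModel` (caches draws; reuse one object per
#'   simulated program so repeated queries for a year return the identical
#'   value).
#' @export
environment_model <- function(year_variance = 0.2, gxy_variance = 0.2) {
  stopifnot(year_variance >= 0, gxy_variance >= 0)
  e <- new.env(parent = emptyenv())
  e$year_effects <- list()
  e$gxy_effects <- list()
  structure(list(year_variance = year_variance, gxy_variance = gxy_variance,
                 cache = e),
            class = "EnvironmentModel")
}

#' Year effect for a given year (drawn once, then cached)
#' @param env An `EnvironmentModel`.
#' @param year Integer year.
#' @return The year effect (numeric scalar).
#' @export
sample_year_effect <- function(env, year) {
  key <- as.character(year)
  cached <- env$cache$year_effects[[key]]
  if (!is.null(cached)) return(cached)
  val <- if (env$year_variance == 0) 0 else
    stats::rnorm(1, 0, sqrt(env$year_variance))
  env$cache$year_effects[[key]] <- val
  val
}

#' Per-QTL genotype-by-year effects for a given year (drawn once, cached)
#'
#' Each QTL's year-specific additive deviation is drawn
#' N(0, sigma_a^2 * sigma_ay^2 / sigma_G^2), independent across years,
#' where sigma_a^2 is the variance of the scaled additive effects,
#' sigma_ay^2 the target additive-by-year variance and sigma_G^2 the base
#' genetic variance.
#'
#' @param trait A `TraitModel`.
#' @param env An `EnvironmentModel`.
#' @param year Integer year.
#' @return Numeric vector of per-QTL deviations for that year.
#' @export
assign_gxy_effects <- function(trait, env, year) {
  key <- as.character(year)
  cached <- env$cache$gxy_effects[[key]]
  if (!is.null(cached)) return(cached)
  n_qtl <- length(trait$qtl_effects)
  v <- trait$effect_variance * env$gxy_variance / trait$base_genetic_variance
  val <- if (v == 0) rep(0, n_qtl) else stats::rnorm(n_qtl, 0, sqrt(v))
  env$cache$gxy_effects[[key]] <- val
  val
}

#' Per-individual genotype-by-year deviation for a year
#' @param pop A `Population`.
#' @param trait A `TraitModel`.
#' @param env An `EnvironmentModel`.
#' @param year Integer year.
#' @param ids Optional ids (default all).
#' @return Named numeric vector of GxY deviations.
#' @export
gxy_deviation <- function(pop, trait, env, year, ids = NULL) {
  b <- assign_gxy_effects(trait, env, year)
  d <- dosages(pop, trait$qtl_sites, ids)
  out <- as.vector(d %*% b)
  names(out) <- rownames(d)
  out
}

#' Simulate phenotype records
#'
#' Under a narrow-sense spec (single-cohort architecture) the phenotype is
#' TBV plus a plot error with variance from [error_variance_for_h2()].
#' Under a broad-sense spec (multi-stage architecture) the phenotype is
#' TBV + year effect + GxY deviation + plot error, with the plot-error
#' variance set per trial so sigma_G^2 / (sigma_G^2 + sigma_e^2) = H^2
#' anchored at the base genetic variance (set
#' `h2_denominator = "with_gxy"` to include the GxY variance in the
#' denominator instead). Every record stores its components separately so
#' selection error can be decomposed exactly.
#'
#' @param pop A `Population`.
#' @param trait A `TraitModel`.
#' @param herit A [herit_spec()].
#' @param year Evaluation year (stamped on records; required for broad).
#' @param env An `EnvironmentModel` (required for broad).
#' @param stage Stage tag stamped on records.
#' @param ids Optional ids (default all).
#' @param h2_denominator "base" (default) or "with_gxy".
#' @return data.frame with columns id, year, stage, reps, phenotype, tbv,
#'   year_effect, gxy, plot_error. phenotype = tbv + year_effect + gxy +
#'   plot_error holds to machine precision.
#' @export
make_phenotypes <- function(pop, trait, herit, year = NA_integer_,
                            env = NULL, stage = NA_character_, ids = NULL,
                            h2_denominator = c("base", "with_gxy")) {
  stopifnot(inherits(herit, "HeritabilitySpec"))
  h2_denominator <- match.arg(h2_denominator)
  if (is.null(ids)) ids <- pop$meta$id
  tbv <- true_breeding_value(pop, trait, ids)
  n <- length(ids)
  if (herit$kind == "narrow") {
    ev <- error_variance_for_h2(herit$value, trait$base_genetic_variance,
                                herit$n_reps)
    err <- if (ev == 0) rep(0, n) else stats::rnorm(n, 0, sqrt(ev))
    ye <- rep(0, n)
    gxy <- rep(0, n)
  } else {
    if (is.null(env)) stop("broad-sense phenotypes require an EnvironmentModel")
    if (is.na(year)) stop("broad-sense phenotypes require a year")
    base_ev <- if (h2_denominator == "base") {
      trait$base_genetic_variance * (1 - herit$value) / herit$value
    } else {
      v <- trait$base_genetic_variance / herit$value -
        trait$base_genetic_variance - env$gxy_variance
      if (v < 0) stop("H2 too high to include GxY variance in denominator")
      v
    }
    ev <- base_ev / herit$n_reps
    err <- if (ev == 0) rep(0, n) else stats::rnorm(n, 0, sqrt(ev))
    ye <- rep(sample_year_effect(env, year), n)
    gxy <- unname(gxy_deviation(pop, trait, env, year, ids))
  }
  data.frame(id = ids, year = as.integer(year), stage = stage,
             reps = herit$n_reps, phenotype = unname(tbv) + ye + gxy + err,
             tbv = unname(tbv), year_effect = ye, gxy = gxy,
             plot_error = err, stringsAsFactors = FALSE)
}
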