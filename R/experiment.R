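#' Expand a factor grid into a scenario plan
#'
#' For the single-cohort architecture the full cross of applicable
#' factors is generated with inapplicable combinations pruned: phenotype
#' replication applies only to phenotypic selection; training window,
#' selection mode and minimum Ne only to genomic selection; Ne only to
#' optimum contribution selection. The multi-stage architecture has the
#' four scenarios {discrete, overlapping} x {phenotypic, genomic}.
#'
#' @param architecture "rsa" (single-cohort) or "rsay" (multi-stage).
#' @param policies,criteria,h2_levels,reps_levels,gs_modes,trainings,ne_levels
#'   Factor levels (defaults are the full study design).
#' @return data.frame of scenarios with a unique `scenario_id` per row.
#' @export
expand_scenarios <- function(architecture = c("rsa", "rsay"),
                             policies = c("discrete", "overlapping"),
                             criteria = c("phenotype", "tbv", "gebv"),
                             h2_levels = c(0.1, 0.5, 0.9),
                             reps_levels = c(1, 3),
                             gs_modes = c("truncation", "ocs"),
                             trainings = c("allGen", "fiveGen"),
                             ne_levels = c(10, 45, 90)) {
  architecture <- match.arg(architecture)
  if (length(policies) == 0L || length(criteria) == 0L) {
    stop("empty factor list")
  }
  if (architecture == "rsay") {
    criteria <- intersect(criteria, c("phenotype", "gebv"))
    if (length(criteria) == 0L) stop("empty factor list")
    g <- expand.grid(policy = policies, criterion = criteria,
                     stringsAsFactors = FALSE)
    g$scenario_id <- mapply(function(p, cr) {
      paste0("rsay_", cr, "_", if (p == "discrete") "disc" else "over")
    }, g$policy, g$criterion)
    g$architecture <- "rsay"
    return(g)
  }
  out <- list()
  for (crit in criteria) {
    base <- expand.grid(policy = policies, criterion = crit,
                        h2 = h2_levels, stringsAsFactors = FALSE)
    if (crit == "phenotype") {
      base <- merge(base, data.frame(n_reps = reps_levels))
    } else {
      base$n_reps <- 1
    }
    if (crit == "gebv") {
      base <- merge(base, expand.grid(gs_mode = gs_modes,
                                      training = trainings,
                                      stringsAsFactors = FALSE))
      trunc <- base[base$gs_mode == "truncation", , drop = FALSE]
      trunc$min_Ne <- NA_real_
      ocs <- base[base$gs_mode == "ocs", , drop = FALSE]
      if (nrow(ocs) > 0L) {
        ocs <- merge(ocs, data.frame(min_Ne = ne_levels))
      }
      base <- rbind(trunc, ocs)
    } else {
      base$gs_mode <- NA_character_
      base$training <- NA_character_
      base$min_Ne <- NA_real_
    }
    out[[crit]] <- base
  }
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  g$scenario_id <- vapply(seq_len(nrow(g)), function(i) {
    r <- g[i, ]
    pol <- if (r$policy == "discrete") "disc" else "over"
    id <- paste0("rsa_", r$criterion, "_", pol, "_h", r$h2)
    if (r$criterion == "phenotype") id <- paste0(id, "_r", r$n_reps)
    if (r$criterion == "gebv") {
      id <- paste0(id, "_", r$gs_mode, "_", r$training)
      if (!is.na(r$min_Ne)) id <- paste0(id, "_Ne", r$min_Ne)
    }
    id
  }, character(1))
  if (anyDuplicated(g$scenario_id)) stop("duplicate scenario ids")
  g$architecture <- "rsa"
  g
}

#' Deterministic replicate seed
#'
#' Hashes (base seed, scenario id, replicate) into a 31-bit integer so
#' every run is attributable and reproducible.
#'
#' @param base_seed Base integer seed.
#' @param scenario_id Scenario id string.
#' @param replicate Replicate index.
#' @return Positive integer seed (< 2^31).
#' @export
derive_seed <- function(base_seed, scenario_id, replicate) {
  h <- as.double(base_seed) %% 2147483647
  for (ch in utf8ToInt(scenario_id)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(replicate) * 7919) %% 2147483647
  as.integer(h) + 1L
}

# Build a pipeline config from one scenario-plan row.
.scenario_config <- function(row, scale = c("full", "reduced"),
                             overrides = list()) {
  scale <- match.arg(scale)
  if (row$architecture == "rsay") {
    args <- list(policy = row$policy, criterion = row$criterion)
    if (scale == "reduced") {
      args <- utils::modifyList(args, list(
        n_crosses = 20L, progeny_per_cross = 10L,
        advance = c(headrow = 60, pyt = 20, ayt = 10), n_years = 15L))
    }
    args <- utils::modifyList(args, overrides)
    return(do.call(rsay_config, args))
  }
  args <- list(policy = row$policy, criterion = row$criterion, h2 = row$h2)
  if (row$criterion == "phenotype") args$n_reps <- row$n_reps
  if (row$criterion == "gebv") {
    args$gs_mode <- row$gs_mode
    args$training <- row$training
    if (!is.na(row$min_Ne)) args$min_Ne <- row$min_Ne
  }
  if (scale == "reduced") args$n_cycles <- 20L
  args <- utils::modifyList(args, overrides)
  do.call(rsa_config, args)
}

#' Run a planned experiment
#'
#' Runs every scenario x replicate, with replicate seeds derived from
#' the base seed via [derive_seed()], optionally writing one CSV of
#' responses per scenario x replicate. `scale = "reduced"` shrinks the
#' program (20 cycles for the single-cohort architecture; 15 years with
#' 20 crosses x 10 progeny and 60/20/10 advancement for the multi-stage
#' architecture) for desk-scale runs; `"full"` uses the study sizes.
#' Identical plan + base seed reruns are byte-identical. An OCS scenario
#' whose optimization becomes infeasible is truncated and recorded, not
#' fatal.
#'
#' @param plan Scenario plan from [expand_scenarios()] (optionally
#'   subset).
#' @param n_replicates Replicates per scenario (study design: 10).
#' @param base_seed Base integer seed.
#' @param out_dir Optional output directory for per-run CSVs.
#' @param scale "full" or "reduced".
#' @param overrides Named list of config overrides applied to every
#'   scenario (advanced use).
#' @return data.frame of all responses (one row per scenario x replicate
#'   x cycle/year).
#' @export
run_experiment <- function(plan, n_replicates = 10, base_seed = 1,
                           out_dir = NULL, scale = c("full", "reduced"),
                           overrides = list()) {
  scale <- match.arg(scale)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cfg <- .scenario_config(row, scale, overrides)
    for (r in seq_len(n_replicates)) {
      seed <- derive_seed(base_seed, row$scenario_id, r)
      res <- if (row$architecture == "rsay") {
        run_rsay_scenario(cfg, seed, row$scenario_id, r)
      } else {
        run_rsa_scenario(cfg, seed, row$scenario_id, r)
      }
      if (!is.null(out_dir)) {
        f <- file.path(out_dir,
                       sprintf("%s_rep%02d.csv", row$scenario_id, r))
        utils::write.csv(res, f, row.names = FALSE)
      }
      out[[length(out) + 1L]] <- as.data.frame(res)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discrete-vs-overlapping contrasts at a timepoint
#'
#' For each pair of otherwise identical scenarios differing only in the
#' generation policy, a Welch two-sample test on replicate-level values
#' of the response at the given cycle/year (with one observation per
#' replicate per scenario, the heteroscedastic two-group contrast
#' reduces to Welch's test). Estimates are discrete minus overlapping. A
#' pair missing the timepoint in either arm (e.g. an OCS scenario
#' truncated by infeasibility) is flagged unavailable.
#'
#' @param results Combined responses from [run_experiment()].
#' @param response Response column name.
#' @param timepoint Cycle or year at which to contrast.
#' @param alternative Test sidedness (default "two.sided").
#' @return data.frame with one row per discrete/overlapping pair:
#'   estimate, confidence limits, p value, df, availability flag.
#' @export
timepoint_contrasts <- function(results, response, timepoint,
                                alternative = "two.sided") {
  stopifnot(response %in% names(results))
  at <- results[results$cycle_or_year == timepoint, , drop = FALSE]
  disc_ids <- unique(grep("_disc", results$scenario_id, value = TRUE))
  rows <- list()
  for (d_id in sort(disc_ids)) {
    o_id <- sub("_disc", "_over", d_id)
    if (!o_id %in% results$scenario_id) next
    x <- at[[response]][at$scenario_id == d_id]
    y <- at[[response]][at$scenario_id == o_id]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      rows[[d_id]] <- data.frame(pair = paste(d_id, "vs", o_id),
                                 estimate = NA_real_, lower = NA_real_,
                                 upper = NA_real_, p = NA_real_,
                                 df = NA_real_, available = FALSE)
      next
    }
    tt <- stats::t.test(x, y, alternative = alternative)
    ci <- if (alternative == "two.sided") tt$conf.int else c(NA_real_,
                                                             NA_real_)
    rows[[d_id]] <- data.frame(pair = paste(d_id, "vs", o_id),
                               estimate = mean(x) - mean(y),
                               lower = ci[1L], upper = ci[2L],
                               p = tt$p.value,
                               df = unname(tt$parameter),
                               available = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample tests against a structural constant
#'
#' Per scenario, a one-sample t test of replicate-level values at a
#' timepoint against `mu0`, Bonferroni-corrected by the family size.
#' Zero-variance replicates equal to `mu0` give p = 1 (no evidence of
#' difference); zero-variance replicates different from `mu0` are
#' flagged as an exact difference (p = 0).
#'
#' @param results Combined responses from [run_experiment()].
#' @param response Response column name.
#' @param timepoint Cycle or year.
#' @param mu0 Null value (1 for the single-cohort mean parental age and
#'   the year-component bias; 3.67 for the multi-stage mean parental
#'   age).
#' @param family_size Number of tests in the Bonferroni family.
#' @return data.frame per scenario: mean, p, Bonferroni-adjusted p,
#'   exact-difference flag.
#' @export
one_sample_tests <- function(results, response, timepoint, mu0,
                             family_size = 1) {
  stopifnot(response %in% names(results))
  at <- results[results$cycle_or_year == timepoint, , drop = FALSE]
  rows <- list()
  for (sid in sort(unique(at$scenario_id))) {
    v <- at[[response]][at$scenario_id == sid]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    if (stats::sd(v) == 0) {
      p <- if (v[1L] == mu0) 1 else 0
      exact <- v[1L] != mu0
    } else {
      p <- stats::t.test(v, mu = mu0)$p.value
      exact <- FALSE
    }
    rows[[sid]] <- data.frame(scenario_id = sid, mean = mean(v),
                              mu0 = mu0, p = p,
                              p_bonferroni = min(1, p * family_size),
                              exact_difference = exact)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a scenario plan from a YAML configuration file
#'
#' The file holds the experiment settings (`architecture`,
#' `n_replicates`, `base_seed`, `scale`) and the factor levels by the
#' design's names (`generations`, `criterion`, `reps`, `gs_mode`,
#' `training`, `h2`, `Ne`). See
#' `system.file("extdata", "example_rsa_scenarios.yaml",
#' package = "recselsim")`.
#'
#' @param path Path to the YAML file.
#' @return List with `plan` (scenario data.frame), `n_replicates`,
#'   `base_seed`, `scale`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  arch <- cfg$architecture %||% "rsa"
  args <- list(architecture = arch)
  if (!is.null(cfg$generations)) args$policies <- cfg$generations
  if (!is.null(cfg$criterion)) args$criteria <- cfg$criterion
  if (!is.null(cfg$h2)) args$h2_levels <- cfg$h2
  if (!is.null(cfg$reps)) args$reps_levels <- cfg$reps
  if (!is.null(cfg$gs_mode)) args$gs_modes <- cfg$gs_mode
  if (!is.null(cfg$training)) args$trainings <- cfg$training
  if (!is.null(cfg$Ne)) args$ne_levels <- cfg$Ne
  list(plan = do.call(expand_scenarios, args),
       n_replicates = cfg$n_replicates %||% 10,
       base_seed = cfg$base_seed %||% 1,
       scale = cfg$scale %||% "reduced")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
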