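#' Configuration for the single-cohort recurrent mass-selection program
#'
#' One cohort of progeny per breeding cycle, phenotyped and selected
#' before flowering; 100 random crosses of the selected parents produce
#' one progeny each. Selection acts on phenotype, true breeding value, or
#' GEBV, from discrete or overlapping generations, by truncation or by
#' optimum contribution selection.
#'
#' @param h2 Narrow-sense heritability of unreplicated phenotypes
#'   (0.1, 0.5 or 0.9 in the study design).
#' @param policy "discrete" (current cohort only) or "overlapping" (all
#'   cohorts ever evaluated remain candidates).
#' @param criterion "phenotype", "tbv" or "gebv".
#' @param n_reps Phenotype replicate count (1 or 3; only meaningful under
#'   phenotypic selection).
#' @param gs_mode "truncation" or "ocs" (genomic criterion only).
#' @param training "allGen" or "fiveGen" RR-BLUP training window.
#' @param min_Ne Minimum effective population size for OCS (10, 45, 90).
#' @param n_parents Parents kept by truncation (default 20).
#' @param n_crosses Crosses per cycle (default 100).
#' @param progeny_per_cross Progeny per cross (default 1).
#' @param n_cycles Breeding cycles (default 50).
#' @param n_founders Founder population size (default 100).
#' @param spec A [genome_spec()].
#' @param rrblup_method "reml" (default) or "fixed".
#' @param fixed_ratio Variance ratio when `rrblup_method = "fixed"`.
#' @return An `RsaConfig`.
#' @export
rsa_config <- function(h2 = 0.1, policy = c("discrete", "overlapping"),
                       criterion = c("phenotype", "tbv", "gebv"),
                       n_reps = 1, gs_mode = c("truncation", "ocs"),
                       training = c("allGen", "fiveGen"), min_Ne = 45,
                       n_parents = 20, n_crosses = 100,
                       progeny_per_cross = 1, n_cycles = 50,
                       n_founders = 100, spec = genome_spec(),
                       rrblup_method = c("reml", "fixed"),
                       fixed_ratio = NULL) {
  policy <- match.arg(policy)
  criterion <- match.arg(criterion)
  gs_mode <- match.arg(gs_mode)
  training <- match.arg(training)
  rrblup_method <- match.arg(rrblup_method)
  if (criterion != "phenotype" && n_reps != 1) {
    stop("phenotype replication is only meaningful under phenotypic ",
         "selection")
  }
  structure(list(h2 = h2, policy = policy, criterion = criterion,
                 n_reps = as.integer(n_reps), gs_mode = gs_mode,
                 training = training, min_Ne = min_Ne,
                 n_parents = as.integer(n_parents),
                 n_crosses = as.integer(n_crosses),
                 progeny_per_cross = as.integer(progeny_per_cross),
                 n_cycles = as.integer(n_cycles),
                 n_founders = as.integer(n_founders), spec = spec,
                 rrblup_method = rrblup_method, fixed_ratio = fixed_ratio),
            class = "RsaConfig")
}

#' Run one single-cohort recurrent-selection scenario
#'
#' Cycle 0 draws the founders, scales the trait to base genetic variance,
#' phenotypes the founders and selects the first parents phenotypically.
#' Each subsequent cycle crosses the parents, phenotypes the new cohort,
#' refreshes GEBVs for the whole eligible pool (genomic criterion),
#' selects parents by truncation or OCS under the generation policy, and
#' records every response on the current generation and the selected
#' parents. OCS infeasibility (the inbreeding bound can no longer be met)
#' truncates the scenario; completed cycles are returned with attribute
#' `truncated_at`.
#'
#' @param cfg An [rsa_config()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param scenario_id Label written into the output (default derived from
#'   the config).
#' @param replicate Replicate index written into the output.
#' @return data.frame of per-cycle responses (see package README);
#'   attributes `truncated_at` (or NULL) and `final_parents`.
#' @export
run_rsa_scenario <- function(cfg, seed, scenario_id = NULL, replicate = 1L) {
  stopifnot(inherits(cfg, "RsaConfig"))
  if (is.null(scenario_id)) scenario_id <- rsa_scenario_id(cfg)
  set.seed(seed)
  founders <- generate_founders(cfg$spec, cfg$n_founders)
  trait <- assign_qtl_effects(founders, target_variance = 1)
  herit <- herit_spec("narrow", cfg$h2,
                      if (cfg$criterion == "phenotype") cfg$n_reps else 1L)
  cohorts <- list(founders)
  tbv_all <- true_breeding_value(founders, trait)
  ph <- make_phenotypes(founders, trait, herit, year = 0L, stage = "cohort")
  ph$cycle <- 0L
  archive <- ph
  chipM <- chip_dosages(founders, trait)
  next_id <- max(founders$meta$id) + 1L
  # first parents are always selected phenotypically
  parents <- truncation_select(ph$id, ph$phenotype, cfg$n_parents)
  contribs <- NULL
  rows <- vector("list", cfg$n_cycles)
  truncated_at <- NULL
  for (cycle in seq_len(cfg$n_cycles)) {
    plan <- if (is.null(contribs)) {
      .random_cross_plan(parents, cfg$n_crosses, cfg$progeny_per_cross)
    } else {
      contributions_to_crosses(contribs, cfg$n_crosses,
                               cfg$progeny_per_cross)
    }
    parent_pop <- .collect_pop(cohorts, unique(c(plan$mother, plan$father)))
    prog <- make_crosses(parent_pop, plan, birth = cycle, stage = "cohort")
    prog$meta$id <- next_id - 1L + seq_len(nrow(prog$meta))
    next_id <- next_id + nrow(prog$meta)
    cohorts[[length(cohorts) + 1L]] <- prog
    tbv_prog <- true_breeding_value(prog, trait)
    tbv_all <- c(tbv_all, tbv_prog)
    ph <- make_phenotypes(prog, trait, herit, year = cycle, stage = "cohort")
    ph$cycle <- cycle
    archive <- rbind(archive, ph)
    chipM <- rbind(chipM, chip_dosages(prog, trait))
    # criterion values over the eligible pool
    pool_ids <- if (cfg$policy == "discrete") prog$meta$id else archive$id
    if (cfg$criterion == "phenotype") {
      crit <- archive$phenotype[match(pool_ids, archive$id)]
    } else if (cfg$criterion == "tbv") {
      crit <- unname(tbv_all[match(pool_ids, as.integer(names(tbv_all)))])
    } else {
      train <- build_training_set(archive, chipM, cfg$training, cycle)
      model <- fit_rrblup(train, method = cfg$rrblup_method,
                          ratio = cfg$fixed_ratio)
      crit <- unname(predict_gebv(
        model, chipM[match(as.character(pool_ids), rownames(chipM)), ,
                     drop = FALSE]))
    }
    pool_tbv <- unname(tbv_all[match(pool_ids, as.integer(names(tbv_all)))])
    errors <- crit - pool_tbv
    contribs <- NULL
    if (cfg$criterion == "gebv" && cfg$gs_mode == "ocs") {
      pool_pop <- .collect_pop(cohorts, pool_ids)
      K <- ibd_kinship(pool_pop)
      res <- tryCatch(
        ocs_contributions(stats::setNames(crit, pool_ids), K,
                          min_Ne = cfg$min_Ne),
        ocs_infeasible = function(e) e)
      if (inherits(res, "ocs_infeasible")) {
        truncated_at <- cycle
        rows <- rows[seq_len(cycle - 1L)]
        break
      }
      contribs <- res$contributions
      sel <- as.integer(names(contribs)[contribs > 1e-6])
    } else {
      sel <- truncation_select(pool_ids, crit, cfg$n_parents)
    }
    sel_idx <- match(sel, pool_ids)
    gst <- genetic_stats(prog, trait)
    bias <- selection_error_bias(errors[sel_idx], errors)
    acc <- selection_accuracy(crit[sel_idx], pool_tbv[sel_idx])
    sel_pop <- .collect_pop(cohorts, sel)
    inb <- ibd_inbreeding(sel_pop)
    birth_sel <- sel_pop$meta$birth[match(sel, sel_pop$meta$id)]
    age <- mean_parental_age(birth_sel, cycle)
    rows[[cycle]] <- .metrics_row(replicate, cycle, scenario_id,
                                  gst["mean"], gst["variance"], bias,
                                  inbreeding = inb, accuracy = acc,
                                  age = age)
    parents <- sel
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truncated_at") <- truncated_at
  attr(out, "final_parents") <- parents
  out
}

#' Scenario id string for a single-cohort configuration
#' @param cfg An [rsa_config()].
#' @return Character scenario id encoding the factor levels.
#' @export
rsa_scenario_id <- function(cfg) {
  pol <- if (cfg$policy == "discrete") "disc" else "over"
  base <- paste0("rsa_", cfg$criterion, "_", pol, "_h", cfg$h2)
  if (cfg$criterion == "phenotype") {
    base <- paste0(base, "_r", cfg$n_reps)
  } else if (cfg$criterion == "gebv") {
    base <- paste0(base, "_", cfg$gs_mode, "_", cfg$training)
    if (cfg$gs_mode == "ocs") base <- paste0(base, "_Ne", cfg$min_Ne)
  }
  base
}
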