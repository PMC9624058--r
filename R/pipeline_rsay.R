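#' Configuration for the multi-stage doubled-haploid pipeline
#'
#' A yield-trial breeding program with additive, year and
#' additive-by-year trait effects under compound symmetry. Each year the
#' selected parents are crossed (stage 1), doubled haploids are produced
#' from the previous year's progeny (stage 2), and DH cohorts move
#' through headrows (stage 3, initial H2 = 0.1), a preliminary yield
#' trial (stage 4, H2 = 0.2), an advanced yield trial (stage 5,
#' H2 = 0.5) and two elite-yield-trial years (stages 6-7, H2 = 0.8),
#' with a variety picked from the elite means (stage 8). Each stage takes
#' one year.
#'
#' Parents (30 per year in steady state) are the top-ranked individuals
#' from the current preliminary yield trial plus the cohort advanced out
#' of last year's advanced yield trial (the current first-year elite
#' entries); under overlapping generations both groups are ranked across
#' all cycles ever evaluated.
#'
#' @param policy "discrete" or "overlapping".
#' @param criterion "phenotype" or "gebv".
#' @param n_founders Founder population size (default 100).
#' @param n_crosses Biparental crosses per year (default 100).
#' @param progeny_per_cross Progeny per cross (default 97).
#' @param advance Named counts advanced out of each phenotyping stage:
#'   `c(headrow = 500, pyt = 50, ayt = 10)`; elite entries all advance.
#' @param stage_h2 Initial broad-sense heritabilities per stage:
#'   `c(headrow = 0.1, pyt = 0.2, ayt = 0.5, eyt = 0.8)`.
#' @param n_parents_stage4,n_parents_stage5 Parent-group sizes
#'   (defaults 20 and 10).
#' @param n_years Program length in years (default 40).
#' @param year_variance Variance of year effects (default 0.2).
#' @param gxy_variance Target additive-by-year variance (default 0.2).
#' @param spec A [genome_spec()].
#' @param rrblup_method,fixed_ratio RR-BLUP settings (genomic criterion).
#' @param h2_denominator "base" or "with_gxy" (see [make_phenotypes()]).
#' @return An `RsayConfig`.
#' @export
rsay_config <- function(policy = c("discrete", "overlapping"),
                        criterion = c("phenotype", "gebv"),
                        n_founders = 100, n_crosses = 100,
                        progeny_per_cross = 97,
                        advance = c(headrow = 500, pyt = 50, ayt = 10),
                        stage_h2 = c(headrow = 0.1, pyt = 0.2, ayt = 0.5,
                                     eyt = 0.8),
                        n_parents_stage4 = 20, n_parents_stage5 = 10,
                        n_years = 40, year_variance = 0.2,
                        gxy_variance = 0.2, spec = genome_spec(),
                        rrblup_method = c("reml", "fixed"),
                        fixed_ratio = NULL,
                        h2_denominator = c("base", "with_gxy")) {
  policy <- match.arg(policy)
  criterion <- match.arg(criterion)
  rrblup_method <- match.arg(rrblup_method)
  h2_denominator <- match.arg(h2_denominator)
  stopifnot(all(c("headrow", "pyt", "ayt") %in% names(advance)),
            all(c("headrow", "pyt", "ayt", "eyt") %in% names(stage_h2)))
  n_dh <- n_crosses * progeny_per_cross
  if (!(n_dh >= advance[["headrow"]] &&
        advance[["headrow"]] > advance[["pyt"]] &&
        advance[["pyt"]] > advance[["ayt"]])) {
    stop("stage sizes must be strictly decreasing through advancement")
  }
  if (advance[["pyt"]] < n_parents_stage4 ||
      advance[["ayt"]] < n_parents_stage5) {
    stop("advancement counts too small for the parent rule")
  }
  structure(list(policy = policy, criterion = criterion,
                 n_founders = as.integer(n_founders),
                 n_crosses = as.integer(n_crosses),
                 progeny_per_cross = as.integer(progeny_per_cross),
                 advance = advance, stage_h2 = stage_h2,
                 n_parents_stage4 = as.integer(n_parents_stage4),
                 n_parents_stage5 = as.integer(n_parents_stage5),
                 n_years = as.integer(n_years),
                 year_variance = year_variance,
                 gxy_variance = gxy_variance, spec = spec,
                 rrblup_method = rrblup_method, fixed_ratio = fixed_ratio,
                 h2_denominator = h2_denominator),
            class = "RsayConfig")
}

#' Run one multi-stage doubled-haploid scenario
#'
#' Years 1-5 fill the pipeline from a single founder draw: the first
#' parents are the top founders by a preliminary-yield-trial-precision
#' phenotype, and parent groups switch to the pipeline rule as their
#' source stages come online (these fill years are flagged in the
#' output and should be excluded from steady-state comparisons). From
#' year 6 the full rule applies: 20 top stage-4 individuals plus the 10
#' stage-5-derived elite entries.
#'
#' Selection error bias is computed over the discretionary selection
#' decisions only (candidate groups where fewer are selected than are
#' eligible); in discrete scenarios that is the stage-4 decision alone,
#' whose candidates all share one trial year, so the year-component bias
#' is exactly 1.
#'
#' @param cfg An [rsay_config()].
#' @param seed Integer seed.
#' @param scenario_id Label written into the output.
#' @param replicate Replicate index written into the output.
#' @return data.frame of per-year responses (one row per year, metrics on
#'   the parents selected at the end of that year); attributes
#'   `varieties` (per-year variety picks), `pedigree`, `archive` (all
#'   phenotype records) and `final_parents`.
#' @export
run_rsay_scenario <- function(cfg, seed, scenario_id = NULL,
                              replicate = 1L) {
  stopifnot(inherits(cfg, "RsayConfig"))
  if (is.null(scenario_id)) scenario_id <- rsay_scenario_id(cfg)
  set.seed(seed)
  founders <- generate_founders(cfg$spec, cfg$n_founders)
  founders$meta$birth <- 1L
  trait <- assign_qtl_effects(founders, target_variance = 1)
  env <- environment_model(cfg$year_variance, cfg$gxy_variance)
  Hs <- cfg$stage_h2
  train_stages <- c("pyt", "ayt", "eyt1", "eyt2")
  phen <- function(pop, ids, h2, year, stage) {
    make_phenotypes(pop, trait, herit_spec("broad", h2), year = year,
                    env = env, stage = stage, ids = ids,
                    h2_denominator = cfg$h2_denominator)
  }
  # founder evaluation (year 1) at preliminary-yield-trial precision
  fnd_ph <- phen(founders, NULL, Hs[["pyt"]], 1L, "founder")
  fnd_ph$cycle <- 1L
  archive <- fnd_ph
  tbv_store <- true_breeding_value(founders, trait)
  chipM <- NULL
  pedigree <- founders$meta
  cohorts <- list()   # keyed by cross year
  next_id <- max(founders$meta$id) + 1L
  all_pops <- function() {
    c(list(founders), lapply(cohorts, function(ck) ck$pop))
  }
  founder_rank <- truncation_select(fnd_ph$id, fnd_ph$phenotype,
                                    nrow(fnd_ph))
  parents <- founder_rank[seq_len(cfg$n_parents_stage4 +
                                    cfg$n_parents_stage5)]
  varieties <- list()
  rows <- vector("list", cfg$n_years)
  stage_rec <- function(stage) archive[archive$stage == stage, , drop = FALSE]
  for (Y in seq_len(cfg$n_years)) {
    ## stage 1: crossing
    plan <- .random_cross_plan(parents, cfg$n_crosses,
                               cfg$progeny_per_cross)
    parent_pop <- .collect_pop(all_pops(), unique(c(plan$mother,
                                                    plan$father)))
    f1 <- make_crosses(parent_pop, plan, birth = Y, stage = "f1")
    f1$meta$id <- next_id - 1L + seq_len(nrow(f1$meta))
    next_id <- next_id + nrow(f1$meta)
    pedigree <- rbind(pedigree, f1$meta)
    cohorts[[as.character(Y)]] <- list(f1 = f1, pop = NULL)
    ## stage 2: DH production from last year's progeny
    k <- as.character(Y - 1L)
    if (!is.null(cohorts[[k]]$f1)) {
      src <- cohorts[[k]]$f1
      dh <- make_dh(src, src$meta$id, birth = Y)
      dh$meta$id <- next_id - 1L + seq_len(nrow(dh$meta))
      next_id <- next_id + nrow(dh$meta)
      pedigree <- rbind(pedigree, dh$meta)
      tbv_store <- c(tbv_store, true_breeding_value(dh, trait))
      cohorts[[k]]$pop <- dh
      cohorts[[k]]$f1 <- NULL
    }
    ## stage 3: headrows
    k <- as.character(Y - 2L)
    if (!is.null(cohorts[[k]]$pop)) {
      ck <- cohorts[[k]]
      rec <- phen(ck$pop, NULL, Hs[["headrow"]], Y, "headrow")
      rec$cycle <- Y
      archive <- rbind(archive, rec)
      adv <- truncation_select(rec$id, rec$phenotype,
                               cfg$advance[["headrow"]])
      cohorts[[k]]$pop <- subset_pop(ck$pop, adv) # culled lines dropped
      cohorts[[k]]$pyt_ids <- adv
    }
    ## stage 4: preliminary yield trial
    k <- as.character(Y - 3L)
    if (!is.null(cohorts[[k]]$pyt_ids)) {
      ck <- cohorts[[k]]
      rec <- phen(ck$pop, ck$pyt_ids, Hs[["pyt"]], Y, "pyt")
      rec$cycle <- Y
      archive <- rbind(archive, rec)
      chipM <- rbind(chipM, chip_dosages(ck$pop, trait, ck$pyt_ids))
      cohorts[[k]]$ayt_ids <- truncation_select(rec$id, rec$phenotype,
                                                cfg$advance[["pyt"]])
    }
    ## stage 5: advanced yield trial
    k <- as.character(Y - 4L)
    if (!is.null(cohorts[[k]]$ayt_ids)) {
      ck <- cohorts[[k]]
      rec <- phen(ck$pop, ck$ayt_ids, Hs[["ayt"]], Y, "ayt")
      rec$cycle <- Y
      archive <- rbind(archive, rec)
      cohorts[[k]]$eyt_ids <- truncation_select(rec$id, rec$phenotype,
                                                cfg$advance[["ayt"]])
    }
    ## stages 6-7: elite yield trial, two years
    k <- as.character(Y - 5L)
    if (!is.null(cohorts[[k]]$eyt_ids)) {
      rec <- phen(cohorts[[k]]$pop, cohorts[[k]]$eyt_ids, Hs[["eyt"]], Y,
                  "eyt1")
      rec$cycle <- Y
      archive <- rbind(archive, rec)
    }
    k <- as.character(Y - 6L)
    if (!is.null(cohorts[[k]]$eyt_ids)) {
      rec <- phen(cohorts[[k]]$pop, cohorts[[k]]$eyt_ids, Hs[["eyt"]], Y,
                  "eyt2")
      rec$cycle <- Y
      archive <- rbind(archive, rec)
    }
    ## stage 8: variety pick from elite means (recorded, no feedback)
    k <- as.character(Y - 7L)
    if (!is.null(cohorts[[k]]$eyt_ids)) {
      ids <- cohorts[[k]]$eyt_ids
      e1 <- stage_rec("eyt1")
      e2 <- stage_rec("eyt2")
      means <- (e1$phenotype[match(ids, e1$id)] +
                  e2$phenotype[match(ids, e2$id)]) / 2
      best <- ids[order(-means, ids)[1L]]
      varieties[[length(varieties) + 1L]] <-
        data.frame(year = Y, id = best, varietal_mean = max(means))
    }
    ## end-of-year parent selection (for year Y + 1) + responses
    model <- NULL
    if (cfg$criterion == "gebv") {
      tr_rec <- archive[archive$stage %in% train_stages, , drop = FALSE]
      if (nrow(tr_rec) > 0L) {
        train <- build_training_set(tr_rec, chipM, "allGen", Y,
                                    stage_filter = train_stages)
        model <- fit_rrblup(train, method = cfg$rrblup_method,
                            ratio = cfg$fixed_ratio)
      }
    }
    gebv_of <- function(ids) {
      unname(predict_gebv(model, chipM[match(as.character(ids),
                                             rownames(chipM)), ,
                                       drop = FALSE]))
    }
    groups <- list()
    pyt_rec <- stage_rec("pyt")
    ayt_rec <- stage_rec("ayt")
    ## group A: stage-4 derived
    if (nrow(pyt_rec) > 0L) {
      a_rec <- if (cfg$policy == "discrete") {
        pyt_rec[pyt_rec$year == Y, , drop = FALSE]
      } else {
        pyt_rec[!pyt_rec$id %in% ayt_rec$id, , drop = FALSE]
      }
      if (nrow(a_rec) >= cfg$n_parents_stage4) {
        crit <- if (cfg$criterion == "gebv" && !is.null(model)) {
          gebv_of(a_rec$id)
        } else {
          a_rec$phenotype
        }
        groups$A <- list(rec = a_rec, crit = crit,
                         n_sel = cfg$n_parents_stage4)
      }
    }
    ## group B: stage-5 derived (evaluated in the advanced trial by
    ## year Y - 1; the discrete pool is the current elite first-year
    ## cohort, i.e. last year's AYT graduates)
    b_rec <- ayt_rec[ayt_rec$year <= Y - 1L, , drop = FALSE]
    if (cfg$policy == "discrete") {
      b_rec <- b_rec[b_rec$year == Y - 1L, , drop = FALSE]
      k5 <- as.character(Y - 5L)
      if (nrow(b_rec) > 0L) {
        b_rec <- b_rec[b_rec$id %in% cohorts[[k5]]$eyt_ids, , drop = FALSE]
      }
    }
    if (nrow(b_rec) >= cfg$n_parents_stage5) {
      crit <- if (cfg$criterion == "gebv" && !is.null(model)) {
        gebv_of(b_rec$id)
      } else {
        b_rec$phenotype
      }
      groups$B <- list(rec = b_rec, crit = crit,
                       n_sel = cfg$n_parents_stage5)
    }
    ## founder fallback while the pipeline fills
    n_missing <- cfg$n_parents_stage4 + cfg$n_parents_stage5
    sel_ids <- integer(0)
    sel_crit <- numeric(0)
    if (!is.null(groups$A)) {
      gA <- groups$A
      idsA <- truncation_select(gA$rec$id, gA$crit, gA$n_sel)
      sel_ids <- c(sel_ids, idsA)
      sel_crit <- c(sel_crit, gA$crit[match(idsA, gA$rec$id)])
      n_missing <- n_missing - gA$n_sel
    }
    if (!is.null(groups$B)) {
      gB <- groups$B
      idsB <- truncation_select(gB$rec$id, gB$crit, gB$n_sel)
      sel_ids <- c(sel_ids, idsB)
      sel_crit <- c(sel_crit, gB$crit[match(idsB, gB$rec$id)])
      n_missing <- n_missing - gB$n_sel
    }
    if (n_missing > 0L) {
      fill_ids <- founder_rank[seq_len(n_missing)]
      sel_ids <- c(sel_ids, fill_ids)
      sel_crit <- c(sel_crit,
                    fnd_ph$phenotype[match(fill_ids, fnd_ph$id)])
      groups$F <- list(rec = fnd_ph, crit = fnd_ph$phenotype,
                       n_sel = n_missing, sel = fill_ids)
    }
    ## responses: bias over discretionary decisions only
    disc <- Filter(function(g) nrow(g$rec) > g$n_sel, groups)
    bias <- bias_y <- bias_g <- bias_p <- NA_real_
    if (length(disc) > 0L) {
      all_err <- numeric(0)
      sel_err <- numeric(0)
      all_cmp <- NULL
      sel_cmp <- NULL
      for (g in disc) {
        ids_g <- if (!is.null(g$sel)) g$sel else
          truncation_select(g$rec$id, g$crit, g$n_sel)
        err <- g$crit - g$rec$tbv
        i_sel <- match(ids_g, g$rec$id)
        all_err <- c(all_err, err)
        sel_err <- c(sel_err, err[i_sel])
        cmp <- g$rec[, c("year_effect", "gxy", "plot_error")]
        all_cmp <- rbind(all_cmp, cmp)
        sel_cmp <- rbind(sel_cmp, cmp[i_sel, , drop = FALSE])
      }
      bias <- selection_error_bias(sel_err, all_err)
      if (cfg$criterion == "phenotype") {
        d <- decompose_error_bias(sel_cmp, all_cmp)
        bias_y <- d[["year_bias"]]
        bias_g <- d[["gxy_bias"]]
        bias_p <- d[["plot_bias"]]
      }
    }
    sel_tbv <- unname(tbv_store[match(sel_ids,
                                      as.integer(names(tbv_store)))])
    acc <- selection_accuracy(sel_crit, sel_tbv)
    sel_pop <- .collect_pop(all_pops(), sel_ids)
    inb <- ibd_inbreeding(sel_pop)
    birth_sel <- sel_pop$meta$birth[match(sel_ids, sel_pop$meta$id)]
    rows[[Y]] <- .metrics_row(replicate, Y, scenario_id,
                              mean(sel_tbv), stats::var(sel_tbv), bias,
                              bias_y, bias_g, bias_p, inb, acc,
                              mean_parental_age(birth_sel, Y),
                              fill = Y < 6L)
    parents <- sel_ids
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "varieties") <- do.call(rbind, varieties)
  attr(out, "pedigree") <- pedigree
  attr(out, "archive") <- archive
  attr(out, "final_parents") <- parents
  out
}

#' Scenario id string for a multi-stage configuration
#' @param cfg An [rsay_config()].
#' @return Character scenario id.
#' @export
rsay_scenario_id <- function(cfg) {
  pol <- if (cfg$policy == "discrete") "disc" else "over"
  paste0("rsay_", cfg$criterion, "_", pol)
}
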