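#' Selection error bias
#'
#' The ratio of mean absolute criterion error in the selected parents to
#' mean absolute criterion error in all selection candidates, where error
#' is the deviation of the phenotype or GEBV from the true breeding
#' value. Values above 1 mean the selected tail carries inflated errors.
#' When all candidate errors are zero (selection on TBV) the ratio is
#' undefined and `NaN` is returned rather than inventing a value.
#'
#' @param selected_errors Errors (criterion - TBV) of the selected
#'   parents.
#' @param all_errors Errors of all candidates (the selected are a subset).
#' @return mean(|selected|) / mean(|all|), or `NaN` if the denominator
#'   is 0.
#' @export
selection_error_bias <- function(selected_errors, all_errors) {
  if (length(selected_errors) == 0L || length(all_errors) == 0L) {
    stop("selection_error_bias requires non-empty inputs")
  }
  denom <- mean(abs(all_errors))
  if (denom == 0) return(NaN)
  mean(abs(selected_errors)) / denom
}

#' Decompose selection error bias into year, GxY and plot components
#'
#' Each phenotype record stores its year, genotype-by-year and plot-error
#' components, which reconstruct the total error exactly. The bias of a
#' component is the ratio of mean absolute component error in the
#' selected parents to that in all candidates. When every candidate was
#' evaluated in the same year the year-component bias is exactly 1.
#'
#' @param selected data.frame with columns `year_effect`, `gxy`,
#'   `plot_error` for the selected parents.
#' @param all Same columns for all candidates.
#' @return Named numeric vector `c(year_bias, gxy_bias, plot_bias)`
#'   (components with zero candidate error give `NaN`).
#' @export
decompose_error_bias <- function(selected, all) {
  need <- c("year_effect", "gxy", "plot_error")
  if (!all(need %in% names(selected)) || !all(need %in% names(all))) {
    stop("component columns year_effect/gxy/plot_error are required")
  }
  c(year_bias = selection_error_bias(selected$year_effect, all$year_effect),
    gxy_bias = selection_error_bias(selected$gxy, all$gxy),
    plot_bias = selection_error_bias(selected$plot_error, all$plot_error))
}

#' Selection accuracy
#'
#' Pearson correlation of the selection criterion (phenotype or GEBV)
#' with the simulated true breeding value. By construction it is 1 when
#' selection acts on TBV itself.
#'
#' @param criterion_values Criterion values.
#' @param tbvs True breeding values (same length).
#' @return Correlation in `[-1, 1]`, or `NaN` when either vector has zero
#'   variance.
#' @export
selection_accuracy <- function(criterion_values, tbvs) {
  stopifnot(length(criterion_values) == length(tbvs))
  if (length(tbvs) < 2L) stop("at least 2 pairs required")
  if (stats::sd(criterion_values) == 0 || stats::sd(tbvs) == 0) return(NaN)
  stats::cor(criterion_values, tbvs)
}

#' Mean parental age
#'
#' Age convention: age = current time - creation time + 1, i.e. an
#' individual created and selected in the same cycle has age 1 (a
#' doubled-haploid line's creation time is the DH-production year).
#'
#' @param birth_times Creation cycle/year of each selected parent.
#' @param current_time Current cycle/year.
#' @return Mean age in cycles/years.
#' @export
mean_parental_age <- function(birth_times, current_time) {
  if (length(birth_times) == 0L) stop("no selected parents")
  mean(current_time - birth_times + 1)
}

#' Genetic mean and variance of a cohort
#' @param pop A `Population`.
#' @param trait A `TraitModel`.
#' @param ids Optional ids (default all).
#' @return Named vector `c(mean, variance)` of TBVs (sample variance).
#' @export
genetic_stats <- function(pop, trait, ids = NULL) {
  tbv <- true_breeding_value(pop, trait, ids)
  if (length(tbv) == 0L) stop("empty cohort")
  c(mean = mean(tbv),
    variance = if (length(tbv) > 1L) stats::var(tbv) else 0)
}
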