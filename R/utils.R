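# Internal helpers shared by the breeding pipelines.

# Gather the named individuals out of a list of cohort Populations into
# one small Population (grouped by cohort; all uses downstream are
# order-insensitive or reference individuals by id).
.collect_pop <- function(cohorts, ids) {
  found <- NULL
  remaining <- ids
  for (pop in cohorts) {
    if (is.null(pop)) next
    hit <- remaining[remaining %in% pop$meta$id]
    if (length(hit) == 0L) next
    sub <- subset_pop(pop, hit)
    found <- if (is.null(found)) sub else combine_pop(found, sub)
    remaining <- setdiff(remaining, hit)
    if (length(remaining) == 0L) break
  }
  if (length(remaining) > 0L) {
    stop("individuals not found in any cohort: ",
         paste(utils::head(remaining, 5L), collapse = ", "))
  }
  found
}

# Random biparental crossing plan: each cross draws two distinct parents
# uniformly at random.
.random_cross_plan <- function(parent_ids, n_crosses, n_progeny = 1L) {
  stopifnot(length(parent_ids) >= 2L)
  m <- integer(n_crosses)
  f <- integer(n_crosses)
  for (k in seq_len(n_crosses)) {
    pair <- sample(parent_ids, 2L)
    m[k] <- pair[1L]
    f[k] <- pair[2L]
  }
  data.frame(mother = m, father = f, n_progeny = n_progeny)
}

# One metrics row in the standard response layout.
.metrics_row <- function(replicate, time, scenario_id, gmean, gvar,
                         bias = NA_real_, bias_year = NA_real_,
                         bias_gxy = NA_real_, bias_plot = NA_real_,
                         inbreeding = NA_real_, accuracy = NA_real_,
                         age = NA_real_, fill = FALSE) {
  data.frame(replicate = replicate, cycle_or_year = time,
             scenario_id = scenario_id, mean_genetic_value = gmean,
             genetic_variance = gvar, selection_error_bias = bias,
             bias_year = bias_year, bias_gxy = bias_gxy,
             bias_plot = bias_plot, inbreeding = inbreeding,
             accuracy = accuracy, mean_parental_age = age, fill = fill,
             stringsAsFactors = FALSE)
}
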