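#' Chip-site dosages for a cohort
#' @param pop A `Population`.
#' @param trait A `TraitModel` (its `chip_sites` define the SNP chip).
#' @param ids Optional ids (default all).
#' @return Matrix individuals x chip sites, rownames = ids.
#' @export
chip_dosages <- function(pop, trait, ids = NULL) {
  dosages(pop, trait$chip_sites, ids)
}

#' Assemble an RR-BLUP training set
#'
#' @param records Phenotype archive: data.frame with columns `id`,
#'   `cycle` (breeding cycle or year of the record), `stage`, `phenotype`.
#' @param geno Chip dosage matrix for at least all archived ids
#'   (rownames = id).
#' @param mode "allGen" (every phenotyped record to date) or "fiveGen"
#'   (records from the five most recent previous cycles plus the current
#'   cycle's own records).
#' @param current_cycle Current breeding cycle/year.
#' @param stage_filter Optional character vector of stages to keep (the
#'   multi-stage pipeline trains on yield-trial stages only).
#' @return A `TrainingSet`: list(M, y, ids, cycle, stage).
#' @export
build_training_set <- function(records, geno, mode = c("allGen", "fiveGen"),
                               current_cycle, stage_filter = NULL) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("empty phenotype archive")
  keep <- rep(TRUE, nrow(records))
  if (!is.null(stage_filter)) keep <- keep & records$stage %in% stage_filter
  if (mode == "fiveGen") {
    keep <- keep & records$cycle >= current_cycle - 5L &
      records$cycle <= current_cycle
  }
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("training set empty (mode = ", mode, ", cycle = ", current_cycle,
         if (!is.null(stage_filter))
           paste0(", stages = ", paste(stage_filter, collapse = "/")),
         ")")
  }
  M <- geno[match(as.character(rec$id), rownames(geno)), , drop = FALSE]
  if (anyNA(M[, 1L])) stop("genotypes missing for some training ids")
  structure(list(M = M, y = rec$phenotype, ids = rec$id, cycle = rec$cycle,
                 stage = rec$stage),
            class = "TrainingSet")
}

#' Fit RR-BLUP marker effects
#'
#' Solves the mixed model y = 1 mu + Z m + e with m ~ N(0, I sigma_m^2)
#' and e ~ N(0, I sigma_e^2) on centered chip dosages. The variance ratio
#' lambda = sigma_e^2 / sigma_m^2 is estimated by REML: the marker
#' cross-product is eigendecomposed once and the profile restricted
#' likelihood is maximized by a bounded scalar search in log(lambda)
#' (tolerance 1e-6). Alternatively a known ratio can be supplied
#' (`method = "fixed"`), e.g. derived from the simulated heritability.
#'
#' Monomorphic chip columns are dropped from the solve and assigned zero
#' effect. Adding a constant to all phenotypes changes only the intercept.
#' Constant phenotypes give all-zero effects with the intercept equal to
#' the common value.
#'
#' @param training A `TrainingSet` from [build_training_set()], or a list
#'   with elements `M` (dosage matrix) and `y`.
#' @param method "reml" (default) or "fixed".
#' @param ratio Variance ratio sigma_e^2 / sigma_m^2 when
#'   `method = "fixed"`.
#' @return A `MarkerModel`: list(effects, intercept, centers, lambda,
#'   sigma_m2, sigma_e2, n_records).
#' @export
fit_rrblup <- function(training, method = c("reml", "fixed"), ratio = NULL) {
  method <- match.arg(method)
  M <- training$M
  y <- training$y
  n <- length(y)
  if (n < 2L) stop("at least 2 training records required")
  p <- ncol(M)
  centers <- colMeans(M)
  out0 <- function(lambda, sm2, se2) {
    structure(list(effects = rep(0, p), intercept = mean(y),
                   centers = centers, lambda = lambda, sigma_m2 = sm2,
                   sigma_e2 = se2, n_records = n),
              class = "MarkerModel")
  }
  if (stats::var(y) == 0) return(out0(Inf, 0, 0))
  v <- apply(M, 2L, stats::var)
  keep <- which(v > 0)
  if (length(keep) == 0L) stop("no polymorphic chip site in the training set")
  Mc <- sweep(M[, keep, drop = FALSE], 2L, centers[keep])
  ys <- y - mean(y)
  G <- crossprod(Mc)
  eg <- eigen(G, symmetric = TRUE)
  tol_d <- max(eg$values) * 1e-10
  pos <- which(eg$values > tol_d)
  d <- eg$values[pos]
  ty <- as.vector(crossprod(eg$vectors, crossprod(Mc, ys)))[pos] # T_i' y*
  w2 <- ty^2 / d                                                 # squared rotated data
  rss <- max(sum(ys^2) - sum(w2), 0)
  n_res <- n - 1L - length(d)
  neg2reml <- function(log_lambda) {
    lam <- exp(log_lambda)
    sm2 <- (sum(w2 / (d + lam)) + rss / lam) / (n - 1L)
    (n - 1L) * log(sm2) + sum(log(d + lam)) + n_res * log(lam)
  }
  if (method == "fixed") {
    if (is.null(ratio) || ratio <= 0) stop("method 'fixed' requires ratio > 0")
    lam <- ratio
    sm2 <- (sum(w2 / (d + lam)) + rss / lam) / (n - 1L)
  } else {
    opt <- stats::optimize(neg2reml, interval = c(-25, 25), tol = 1e-6)
    lam <- exp(opt$minimum)
    sm2 <- (sum(w2 / (d + lam)) + rss / lam) / (n - 1L)
  }
  a <- ty / (d + lam)
  m_keep <- as.vector(eg$vectors[, pos, drop = FALSE] %*% a)
  effects <- rep(0, p)
  effects[keep] <- m_keep
  names(effects) <- colnames(M)
  structure(list(effects = effects, intercept = mean(y), centers = centers,
                 lambda = lam, sigma_m2 = sm2, sigma_e2 = sm2 * lam,
                 n_records = n),
            class = "MarkerModel")
}

#' Predict genomic estimated breeding values
#'
#' GEBV = intercept + (dosage - training center) . marker effects. In the
#' overlapping-generation schemes every candidate, however old, is
#' re-scored with the current model each cycle.
#'
#' @param model A `MarkerModel`.
#' @param geno Chip dosage matrix (rownames = id), columns matching the
#'   training chip sites.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, geno) {
  if (ncol(geno) != length(model$effects)) {
    stop("chip sites of genotypes do not match the fitted model")
  }
  out <- as.vector(sweep(geno, 2L, model$centers) %*% model$effects) +
    model$intercept
  names(out) <- rownames(geno)
  out
}
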