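#' Assemble a candidate pool under a generation policy
#'
#' Under discrete generations only the cohort evaluated in the current
#' cycle is eligible; under overlapping generations every cohort ever
#' evaluated remains eligible. Phenotype criteria stay frozen at their
#' original evaluation; GEBV criteria are refreshed each cycle by the
#' caller before pooling.
#'
#' @param records data.frame with at least columns `id`, `birth`
#'   (evaluation cycle) and `criterion`.
#' @param policy "discrete" or "overlapping".
#' @param current_cycle Current cycle.
#' @return The eligible subset of `records`, with attribute `policy`.
#' @export
candidate_pool <- function(records, policy = c("discrete", "overlapping"),
                           current_cycle) {
  policy <- match.arg(policy)
  out <- if (policy == "discrete") {
    records[records$birth == current_cycle, , drop = FALSE]
  } else {
    records
  }
  attr(out, "policy") <- policy
  out
}

#' Truncation selection
#'
#' Selects the `n` candidates with the largest criterion values; ties are
#' broken by smallest id (stable and documented).
#'
#' @param ids Candidate ids.
#' @param values Criterion values (same length).
#' @param n Number to select.
#' @return The selected ids, best first.
#' @export
truncation_select <- function(ids, values, n) {
  stopifnot(length(ids) == length(values))
  if (length(ids) < n) stop("pool smaller than the number to select")
  ord <- order(-values, ids)
  ids[ord[seq_len(n)]]
}

# max g'c - rho * c'Kc over the simplex {c >= 0, sum(c) = 1}, active set.
.qp_simplex_max <- function(g, K, rho, tol = 1e-10) {
  n <- length(g)
  if (rho <= 0) {
    c <- numeric(n)
    c[which.max(g)] <- 1
    return(c)
  }
  S <- which.max(g)
  for (iter in seq_len(100L * n)) {
    A <- 2 * rho * K[S, S, drop = FALSE]
    k <- length(S)
    lhs <- rbind(cbind(A, rep(1, k)), c(rep(1, k), 0))
    rhs <- c(g[S], 1)
    sol <- tryCatch(solve(lhs, rhs), error = function(e) {
      solve(lhs + diag(1e-10, k + 1L), rhs)
    })
    cS <- sol[seq_len(k)]
    mu <- sol[k + 1L]
    if (any(cS < -tol)) {
      S <- S[-which.min(cS)]
      next
    }
    cS[cS < 0] <- 0
    grad <- g - 2 * rho * as.vector(K[, S, drop = FALSE] %*% cS)
    outside <- setdiff(seq_len(n), S)
    if (length(outside) > 0L && max(grad[outside]) > mu + 1e-9) {
      S <- c(S, outside[which.max(grad[outside])])
      next
    }
    c <- numeric(n)
    c[S] <- cS / sum(cS)
    return(c)
  }
  stop("active-set solver failed to converge")
}

#' Optimum contribution selection
#'
#' Maximizes the expected genetic merit of the next generation, c'g,
#' over contribution vectors c (c >= 0, sum(c) = 1) subject to the mean
#' kinship of the offspring generation, c'Kc, not exceeding
#' theta = k_bar + (1 - k_bar) * deltaF, where k_bar is the current mean
#' kinship and deltaF = 1 / (2 Ne) the per-cycle inbreeding-rate bound.
#' The convex problem is solved by an active-set simplex QP nested in a
#' bisection on the Lagrange multiplier of the kinship constraint. Among
#' merit-equivalent optima the minimum-c'Kc solution is returned
#' (deterministic tie-breaking for degenerate merit ties).
#'
#' When even the minimum achievable c'Kc exceeds theta the problem is
#' infeasible and a condition of class `ocs_infeasible` is signalled,
#' carrying the minimum achievable value; long-running schemes with tight
#' Ne eventually hit this as kinship accumulates.
#'
#' @param gebv Genetic merit per candidate (GEBV).
#' @param kinship Symmetric coancestry matrix (IBD-based; see
#'   [ibd_kinship()], or a marker-based alternative).
#' @param min_Ne Minimum effective population size (deltaF = 1/(2 Ne)).
#' @param delta_F Per-cycle inbreeding-rate bound; overrides `min_Ne`.
#' @param mean_kinship Current population mean kinship k_bar (default:
#'   mean over all entries of `kinship`).
#' @param tol Convergence tolerance on the constraint (default 1e-8).
#' @return List with `contributions` (named, sums to 1), `theta`,
#'   `constraint_value`, `objective`.
#' @export
ocs_contributions <- function(gebv, kinship, min_Ne = NULL, delta_F = NULL,
                              mean_kinship = NULL, tol = 1e-8) {
  n <- length(gebv)
  if (n < 2L) stop("OCS requires at least 2 candidates")
  stopifnot(nrow(kinship) == n, ncol(kinship) == n)
  K <- (kinship + t(kinship)) / 2
  if (is.null(delta_F)) {
    if (is.null(min_Ne)) stop("provide min_Ne or delta_F")
    delta_F <- 1 / (2 * min_Ne)
  }
  if (delta_F <= 0 || delta_F > 0.05) {
    stop("delta_F must lie in (0, 0.05] (Ne >= 10)")
  }
  k_bar <- if (is.null(mean_kinship)) mean(K) else mean_kinship
  theta <- k_bar + (1 - k_bar) * delta_F
  ids <- names(gebv)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  finish <- function(c) {
    names(c) <- ids
    list(contributions = c, theta = theta,
         constraint_value = as.vector(c %*% K %*% c),
         objective = sum(c * gebv))
  }
  # minimum achievable mean kinship (feasibility check)
  c_min <- .qp_simplex_max(rep(0, n), K, rho = 1)
  v_min <- as.vector(c_min %*% K %*% c_min)
  if (v_min > theta + 1e-12) {
    cond <- structure(class = c("ocs_infeasible", "error", "condition"),
                      list(message = sprintf(
                        paste0("OCS infeasible: minimum achievable mean ",
                               "kinship %.6f exceeds bound %.6f"),
                        v_min, theta),
                        call = sys.call(-1),
                        min_achievable = v_min, theta = theta))
    stop(cond)
  }
  # unconstrained (truncation-limit) solution
  g_max <- max(gebv)
  ties <- which(gebv >= g_max - 1e-12)
  if (length(ties) == 1L) {
    c0 <- numeric(n)
    c0[ties] <- 1
    if (as.vector(c0 %*% K %*% c0) <= theta) return(finish(c0))
  } else {
    # merit tie: minimum-kinship point within the tie set
    ct <- .qp_simplex_max(rep(0, length(ties)), K[ties, ties, drop = FALSE],
                          rho = 1)
    c0 <- numeric(n)
    c0[ties] <- ct
    if (as.vector(c0 %*% K %*% c0) <= theta) return(finish(c0))
  }
  # constraint binds: bisection on the kinship penalty rho
  val_at <- function(rho) {
    c <- .qp_simplex_max(gebv, K, rho)
    list(c = c, v = as.vector(c %*% K %*% c))
  }
  rho_hi <- 1
  hi <- val_at(rho_hi)
  while (hi$v > theta && rho_hi < 1e14) {
    rho_hi <- rho_hi * 10
    hi <- val_at(rho_hi)
  }
  rho_lo <- 0
  best <- hi
  for (i in 1:200) {
    rho <- (rho_lo + rho_hi) / 2
    cur <- val_at(rho)
    if (cur$v <= theta) {
      rho_hi <- rho
      best <- cur
    } else {
      rho_lo <- rho
    }
    if (abs(best$v - theta) < tol || (rho_hi - rho_lo) < 1e-14 * (1 + rho_hi))
      break
  }
  finish(best$c)
}

#' Convert OCS contributions into a crossing plan
#'
#' Each cross samples two distinct parents with probability proportional
#' to their contributions, so expected parental usage is proportional to
#' c under the distinct-pair sampling scheme.
#'
#' @param contributions Named nonnegative weights summing to 1.
#' @param n_crosses Number of crosses.
#' @param n_progeny_per_cross Progeny per cross (default 1).
#' @param threshold Contributions below this are treated as zero
#'   (default 1e-6).
#' @return data.frame(cross_id, mother, father, n_progeny).
#' @export
contributions_to_crosses <- function(contributions, n_crosses,
                                     n_progeny_per_cross = 1,
                                     threshold = 1e-6) {
  ids <- names(contributions)
  if (is.null(ids)) ids <- as.character(seq_along(contributions))
  pos <- which(contributions > threshold)
  if (length(pos) < 2L) {
    stop("fewer than 2 candidates with positive contribution ",
         "(selfing is disabled)")
  }
  w <- contributions[pos]
  mi <- integer(n_crosses)
  fi <- integer(n_crosses)
  for (k in seq_len(n_crosses)) {
    pair <- sample(seq_along(pos), 2L, prob = w)
    mi[k] <- pos[pair[1L]]
    fi[k] <- pos[pair[2L]]
  }
  out <- data.frame(cross_id = seq_len(n_crosses), mother = ids[mi],
                    father = ids[fi], n_progeny = n_progeny_per_cross,
                    stringsAsFactors = FALSE)
  suppressWarnings({
    mi_int <- as.integer(out$mother)
    if (!anyNA(mi_int)) {
      out$mother <- mi_int
      out$father <- as.integer(out$father)
    }
  })
  out
}
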