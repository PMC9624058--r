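#' Genome specification
#'
#' Defines the simulated genome: number of chromosomes, segregating sites per
#' chromosome, genetic map length, and how many sites per chromosome carry
#' additive (QTL) effects or are genotyped by the simulated SNP chip.
#'
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param sites_per_chromosome Segregating biallelic sites per chromosome
#'   (default 1000).
#' @param map_length Genetic map length per chromosome, in Morgans
#'   (default 1.0; uniform site spacing, Poisson crossovers, no interference).
#' @param qtl_per_chromosome Sites per chromosome assigned additive effects
#'   (default 100).
#' @param chip_per_chromosome Sites per chromosome on the SNP chip
#'   (default 50). QTL and chip sites are sampled disjointly.
#' @return An object of class `GenomeSpec`.
#' @export
genome_spec <- function(n_chromosomes = 10, sites_per_chromosome = 1000,
                        map_length = 1.0, qtl_per_chromosome = 100,
                        chip_per_chromosome = 50) {
  stopifnot(n_chromosomes >= 1, sites_per_chromosome >= 1, map_length >= 0,
            qtl_per_chromosome >= 1, chip_per_chromosome >= 0)
  if (qtl_per_chromosome + chip_per_chromosome > sites_per_chromosome) {
    stop("qtl_per_chromosome + chip_per_chromosome must not exceed ",
         "sites_per_chromosome (disjoint sampling)")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 sites_per_chromosome = as.integer(sites_per_chromosome),
                 map_length = map_length,
                 qtl_per_chromosome = as.integer(qtl_per_chromosome),
                 chip_per_chromosome = as.integer(chip_per_chromosome)),
            class = "GenomeSpec")
}

.new_population <- function(spec, meta, haplo, ibd, positions) {
  structure(list(spec = spec, meta = meta, haplo = haplo, ibd = ibd,
                 positions = positions),
            class = "Population")
}

#' @export
print.Population <- function(x, ...) {
  cat("Population:", nrow(x$meta), "individuals,",
      x$spec$n_chromosomes, "chromosomes x",
      x$spec$sites_per_chromosome, "sites\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `Population`.
#' @return Integer count.
#' @export
n_ind <- function(pop) nrow(pop$meta)

.rows_of <- function(pop, ids) {
  idx <- match(ids, pop$meta$id)
  if (anyNA(idx)) stop("unknown individual id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# haplotype row indices (2 per individual) for individual indices idx
.hap_rows <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Generate an outbred diploid founder population
#'
#' Founder haplotypes are built as Markov mosaics of a small panel of
#' ancestral haplotypes: site allele frequencies are drawn from
#' Beta(0.5, 0.5), each ancestral haplotype carries Bernoulli(p) alleles,
#' and each founder haplotype copies ancestral segments with a switch rate
#' of one per Morgan. This induces realistic linkage disequilibrium while
#' remaining fully reproducible. Any site monomorphic across the founder
#' haplotypes is resampled (and a message emitted) so that every site
#' segregates at generation 0.
#'
#' Every founder haplotype receives a unique identity-by-descent (IBD)
#' label per chromosome; labels run 0 .. (2 * n_individuals *
#' n_chromosomes - 1). All IBD in descendants is traced back to these
#' labels exactly.
#'
#' @param spec A [genome_spec()].
#' @param n_individuals Number of founders (>= 2).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   populations. When `NULL` the current RNG stream is used.
#' @param n_ancestral Size of the ancestral haplotype panel (default 20).
#' @return A `Population` with fields `spec`, `meta` (id, mother, father,
#'   birth, stage), `haplo` and `ibd` (per-chromosome 2N x L integer
#'   matrices; individual i occupies rows 2i-1 and 2i), and `positions`
#'   (per-chromosome genetic-map positions in Morgans).
#' @export
generate_founders <- function(spec, n_individuals = 100, seed = NULL,
                              n_ancestral = 20) {
  stopifnot(inherits(spec, "GenomeSpec"))
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  L <- spec$sites_per_chromosome
  n_hap <- 2L * n_individuals
  positions <- lapply(seq_len(spec$n_chromosomes), function(c) {
    (seq_len(L) - 0.5) / L * spec$map_length
  })
  haplo <- vector("list", spec$n_chromosomes)
  ibd <- vector("list", spec$n_chromosomes)
  n_resampled <- 0L
  for (chr in seq_len(spec$n_chromosomes)) {
    p <- stats::rbeta(L, 0.5, 0.5)
    anc <- matrix(stats::rbinom(n_ancestral * L, 1L, rep(p, each = n_ancestral)),
                  nrow = n_ancestral)
    pos <- positions[[chr]]
    # mosaic source: which ancestral haplotype each founder haplotype copies
    src <- matrix(0L, nrow = n_hap, ncol = L)
    for (h in seq_len(n_hap)) {
      n_sw <- stats::rpois(1L, spec$map_length)
      seg <- sample.int(n_ancestral, n_sw + 1L, replace = TRUE)
      if (n_sw == 0L) {
        src[h, ] <- seg
      } else {
        bp <- sort(stats::runif(n_sw, 0, spec$map_length))
        src[h, ] <- seg[1L + findInterval(pos, bp)]
      }
    }
    H <- matrix(anc[cbind(as.vector(src), rep(seq_len(L), each = n_hap))],
                nrow = n_hap)
    # enforce segregation at every site
    bad <- which(colSums(H) %in% c(0L, n_hap))
    for (s in bad) {
      ok <- FALSE
      for (try in 1:50) {
        ps <- stats::rbeta(1, 0.5, 0.5)
        a_new <- stats::rbinom(n_ancestral, 1L, ps)
        col <- a_new[src[, s]]
        if (any(col == 1L) && any(col == 0L)) {
          H[, s] <- col
          ok <- TRUE
          break
        }
      }
      if (!ok) { # forced balanced column (keeps the invariant)
        col <- integer(n_hap)
        col[sample.int(n_hap, max(1L, n_hap %/% 2L))] <- 1L
        H[, s] <- col
      }
      n_resampled <- n_resampled + 1L
    }
    storage.mode(H) <- "integer"
    haplo[[chr]] <- H
    labels <- (chr - 1L) * n_hap + (seq_len(n_hap) - 1L)
    ibd[[chr]] <- matrix(rep(labels, times = L), nrow = n_hap)
  }
  if (n_resampled > 0L) {
    message("generate_founders: resampled ", n_resampled,
            " non-segregating site(s)")
  }
  meta <- data.frame(id = seq_len(n_individuals), mother = NA_integer_,
                     father = NA_integer_, birth = 0L, stage = "founder",
                     stringsAsFactors = FALSE)
  .new_population(spec, meta, haplo, ibd, positions)
}

# Batched meiosis: one gamete per entry of par_idx (individual indices,
# repeats allowed). Returns per-chromosome matrices with gamete g in row g.
# RNG draws are batched per chromosome; the mosaic construction is inlined
# for speed (identical model to .gamete_chr).
.make_gametes <- function(pop, par_idx) {
  n_g <- length(par_idx)
  L <- pop$spec$sites_per_chromosome
  nchr <- pop$spec$n_chromosomes
  ml <- pop$spec$map_length
  haplo <- vector("list", nchr)
  ibd <- vector("list", nchr)
  r1 <- 2L * par_idx - 1L
  for (chr in seq_len(nchr)) {
    H <- pop$haplo[[chr]]
    I <- pop$ibd[[chr]]
    pos <- pop$positions[[chr]]
    nco <- if (ml > 0) stats::rpois(n_g, ml) else integer(n_g)
    start <- sample.int(2L, n_g, replace = TRUE) - 1L
    Hg <- matrix(0L, n_g, L)
    Ig <- matrix(0L, n_g, L)
    for (g in seq_len(n_g)) {
      a <- r1[g] + start[g]
      if (nco[g] == 0L) {
        Hg[g, ] <- H[a, ]
        Ig[g, ] <- I[a, ]
      } else {
        bp <- sort.int(stats::runif(nco[g], 0, ml))
        src <- (start[g] + findInterval(pos, bp)) %% 2L
        h <- H[r1[g], ]
        i <- I[r1[g], ]
        t2 <- src == 1L
        b <- r1[g] + 1L
        h[t2] <- H[b, t2]
        i[t2] <- I[b, t2]
        Hg[g, ] <- h
        Ig[g, ] <- i
      }
    }
    haplo[[chr]] <- Hg
    ibd[[chr]] <- Ig
  }
  list(haplo = haplo, ibd = ibd)
}

# One recombined gamete for a single chromosome.
# H, I: 2 x L matrices (the parent's two haplotypes / IBD labels).
.gamete_chr <- function(H, I, pos, map_length) {
  n_co <- if (map_length > 0) stats::rpois(1L, map_length) else 0L
  start <- sample.int(2L, 1L)
  if (n_co == 0L) {
    return(list(h = H[start, ], i = I[start, ]))
  }
  bp <- sort(stats::runif(n_co, 0, map_length))
  src <- (start - 1L + findInterval(pos, bp)) %% 2L + 1L
  h <- H[1L, ]
  i <- I[1L, ]
  take2 <- src == 2L
  h[take2] <- H[2L, take2]
  i[take2] <- I[2L, take2]
  list(h = h, i = i)
}

#' Simulate one meiosis
#'
#' Produces a single recombined gamete from one parent. Per chromosome the
#' crossover count is Poisson(map length in Morgans) with breakpoints
#' uniform on the map and no interference; the gamete copies alleles and
#' IBD labels from the resulting parental haplotype mosaic.
#'
#' @param pop A `Population`.
#' @param id Identifier of the parent.
#' @return A list with per-chromosome `haplo` and `ibd` vectors.
#' @export
meiosis <- function(pop, id) {
  idx <- .rows_of(pop, id)
  rows <- c(2L * idx - 1L, 2L * idx)
  out_h <- vector("list", pop$spec$n_chromosomes)
  out_i <- vector("list", pop$spec$n_chromosomes)
  for (chr in seq_len(pop$spec$n_chromosomes)) {
    g <- .gamete_chr(pop$haplo[[chr]][rows, , drop = FALSE],
                     pop$ibd[[chr]][rows, , drop = FALSE],
                     pop$positions[[chr]], pop$spec$map_length)
    out_h[[chr]] <- g$h
    out_i[[chr]] <- g$i
  }
  list(haplo = out_h, ibd = out_i)
}

#' Make crosses according to a crossing plan
#'
#' Each progeny is formed from one maternal and one paternal meiosis.
#' Progeny ids continue from the maximum id present in `pop`.
#'
#' @param pop A `Population` containing all parents.
#' @param plan A data.frame with columns `mother`, `father`, `n_progeny`.
#' @param birth Integer birth cycle/year stamped on the progeny.
#' @param stage Stage tag for the progeny cohort (default "progeny").
#' @param allow_selfing Permit mother == father (default FALSE).
#' @return A `Population` containing only the progeny.
#' @export
make_crosses <- function(pop, plan, birth, stage = "progeny",
                         allow_selfing = FALSE) {
  stopifnot(is.data.frame(plan),
            all(c("mother", "father", "n_progeny") %in% names(plan)))
  if (!allow_selfing && any(plan$mother == plan$father)) {
    stop("selfing requested but disabled (mother == father in plan)")
  }
  n <- sum(plan$n_progeny)
  if (n < 1L) stop("plan produces no progeny")
  mothers <- rep(plan$mother, plan$n_progeny)
  fathers <- rep(plan$father, plan$n_progeny)
  m_idx <- .rows_of(pop, mothers)
  f_idx <- .rows_of(pop, fathers)
  # gamete g = 2j-1 (maternal) or 2j (paternal) copies from parent row pair
  par_idx <- as.vector(rbind(m_idx, f_idx))
  gam <- .make_gametes(pop, par_idx)
  haplo <- gam$haplo
  ibd <- gam$ibd
  ids <- max(pop$meta$id) + seq_len(n)
  meta <- data.frame(id = ids, mother = mothers, father = fathers,
                     birth = as.integer(birth), stage = stage,
                     stringsAsFactors = FALSE)
  .new_population(pop$spec, meta, haplo, ibd, pop$positions)
}

#' Cross two parents
#'
#' @param pop A `Population` containing both parents.
#' @param mother,father Parent ids.
#' @param n_progeny Number of progeny to produce.
#' @param birth Birth cycle/year stamped on progeny.
#' @param allow_selfing Permit mother == father (default FALSE).
#' @return A `Population` of progeny.
#' @export
make_cross <- function(pop, mother, father, n_progeny, birth,
                       allow_selfing = FALSE) {
  make_crosses(pop,
               data.frame(mother = mother, father = father,
                          n_progeny = n_progeny),
               birth = birth, allow_selfing = allow_selfing)
}

#' Produce doubled haploids
#'
#' One meiosis per source individual produces a gamete, which is duplicated
#' onto both haplotypes: the resulting line is fully homozygous at every
#' site and fully traced by the gamete's IBD labels.
#'
#' @param pop A `Population` containing the source individuals.
#' @param ids Source individual ids (one DH line per id).
#' @param birth Birth cycle/year stamped on the DH lines.
#' @return A `Population` of DH lines (stage "dh").
#' @export
make_dh <- function(pop, ids, birth) {
  idx <- .rows_of(pop, ids)
  n <- length(idx)
  dup <- rep(seq_len(n), each = 2L) # gamete doubled onto both haplotypes
  gam <- .make_gametes(pop, idx)
  haplo <- lapply(gam$haplo, function(G) G[dup, , drop = FALSE])
  ibd <- lapply(gam$ibd, function(G) G[dup, , drop = FALSE])
  new_ids <- max(pop$meta$id) + seq_len(n)
  meta <- data.frame(id = new_ids, mother = pop$meta$id[idx],
                     father = pop$meta$id[idx], birth = as.integer(birth),
                     stage = "dh", stringsAsFactors = FALSE)
  .new_population(pop$spec, meta, haplo, ibd, pop$positions)
}

#' Combine two populations sharing a genome specification
#' @param x,y `Population` objects with identical specs.
#' @return Combined `Population`.
#' @export
combine_pop <- function(x, y) {
  stopifnot(identical(x$spec, y$spec))
  if (any(y$meta$id %in% x$meta$id)) stop("duplicate ids in combine_pop")
  haplo <- Map(rbind, x$haplo, y$haplo)
  ibd <- Map(rbind, x$ibd, y$ibd)
  .new_population(x$spec, rbind(x$meta, y$meta), haplo, ibd, x$positions)
}

#' Subset a population by ids
#' @param pop A `Population`.
#' @param ids Ids to keep (order preserved as given).
#' @return A `Population`.
#' @export
subset_pop <- function(pop, ids) {
  idx <- .rows_of(pop, ids)
  rows <- .hap_rows(idx)
  haplo <- lapply(pop$haplo, function(H) H[rows, , drop = FALSE])
  ibd <- lapply(pop$ibd, function(H) H[rows, , drop = FALSE])
  .new_population(pop$spec, pop$meta[idx, , drop = FALSE], haplo, ibd,
                  pop$positions)
}

#' Allele dosages at chosen sites
#'
#' @param pop A `Population`.
#' @param sites List (per chromosome) of site indices.
#' @param ids Optional ids (default all, in meta order).
#' @return Numeric matrix, individuals x sites (0/1/2), rownames = ids.
#' @export
dosages <- function(pop, sites, ids = NULL) {
  if (is.null(ids)) ids <- pop$meta$id
  idx <- .rows_of(pop, ids)
  out <- lapply(seq_len(pop$spec$n_chromosomes), function(chr) {
    H <- pop$haplo[[chr]][, sites[[chr]], drop = FALSE]
    H[2L * idx - 1L, , drop = FALSE] + H[2L * idx, , drop = FALSE]
  })
  m <- do.call(cbind, out)
  rownames(m) <- ids
  m
}

# Sparse (individual x site-label) incidence used for exact IBD coancestry.
.ibd_design <- function(pop, ids) {
  idx <- .rows_of(pop, ids)
  n <- length(idx)
  L <- pop$spec$sites_per_chromosome
  rows <- .hap_rows(idx)
  i_all <- j_all <- vector("list", pop$spec$n_chromosomes)
  for (chr in seq_len(pop$spec$n_chromosomes)) {
    lab <- pop$ibd[[chr]][rows, , drop = FALSE] # 2n x L
    i_all[[chr]] <- rep(rep(seq_len(n), each = 2L), times = L)
    j_all[[chr]] <- as.double(lab) * L + rep(seq_len(L), each = 2L * n)
  }
  i <- unlist(i_all, use.names = FALSE)
  j <- unlist(j_all, use.names = FALSE)
  keys <- sort(unique(j))
  j <- match(j, keys)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(n, length(keys)))
}

#' Exact IBD coancestry matrix
#'
#' Entry (i, j) is the probability that one allele drawn at random from
#' individual i and one from individual j at a site drawn at random are
#' identical by descent (carry the same founder label). Diagonal entries
#' equal (1 + F_i) / 2 where F_i is the individual's inbreeding
#' coefficient; founders have diagonal 0.5.
#'
#' @param pop A `Population`.
#' @param ids Optional ids (default all).
#' @return Dense symmetric matrix with dimnames = ids.
#' @export
ibd_kinship <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- pop$meta$id
  X <- .ibd_design(pop, ids)
  L_tot <- pop$spec$n_chromosomes * pop$spec$sites_per_chromosome
  C <- as.matrix(Matrix::tcrossprod(X)) / (4 * L_tot)
  dimnames(C) <- list(ids, ids)
  C
}

#' Mean pairwise IBD inbreeding
#'
#' The average over all unordered pairs of distinct individuals of the
#' probability of allelic identity by descent at a random site, computed
#' exactly from the tracked founder labels over all segregating sites.
#'
#' @param pop A `Population`.
#' @param ids Optional ids (default all); at least 2 required.
#' @return A probability in `[0, 1]`.
#' @export
ibd_inbreeding <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- pop$meta$id
  if (length(ids) < 2L) stop("ibd_inbreeding requires at least 2 individuals")
  C <- ibd_kinship(pop, ids)
  n <- length(ids)
  (sum(C) - sum(diag(C))) / (n * (n - 1))
}

#' Export genotypes as PLINK .ped/.map text files
#'
#' @param pop A `Population`.
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param ids Optional ids (default all).
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(pop, prefix, ids = NULL) {
  if (is.null(ids)) ids <- pop$meta$id
  idx <- .rows_of(pop, ids)
  L <- pop$spec$sites_per_chromosome
  map <- do.call(rbind, lapply(seq_len(pop$spec$n_chromosomes), function(chr) {
    data.frame(chr = chr, snp = sprintf("chr%d_s%d", chr, seq_len(L)),
               cm = pop$positions[[chr]] * 100,
               bp = round(pop$positions[[chr]] * 1e6))
  }))
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  alleles <- do.call(cbind, lapply(seq_len(pop$spec$n_chromosomes),
    function(chr) {
      H <- pop$haplo[[chr]]
      h1 <- H[2L * idx - 1L, , drop = FALSE] + 1L
      h2 <- H[2L * idx, , drop = FALSE] + 1L
      out <- matrix("", nrow = length(idx), ncol = 2L * L)
      out[, seq(1L, 2L * L, by = 2L)] <- as.character(h1)
      out[, seq(2L, 2L * L, by = 2L)] <- as.character(h2)
      out
    }))
  ped <- cbind("FAM", ids, 0, 0, 0, -9, alleles)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}
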