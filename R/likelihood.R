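#' Estimate per-locus allele frequencies from a genotype table
#'
#' Allele-count frequencies of the minor allele per locus, computed over
#' non-missing genotypes and clamped to `[1/(4n), 1 - 1/(4n)]` (with `n` the
#' number of non-missing genotypes at the locus) so that downstream
#' Hardy-Weinberg priors never place zero mass on an observable genotype.
#'
#' @param genotypes matrix of 0/1/2 codes (`NA` = missing), individuals in
#'   rows and loci in columns.
#' @return numeric vector of frequencies, one per locus.
#' @export
estimate_allele_freqs <- function(genotypes) {
  n_ok <- colSums(!is.na(genotypes))
  bad <- which(n_ok < 2L)
  if (length(bad)) {
    nm <- colnames(genotypes)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(genotypes)))
    stop("loci with fewer than 2 non-missing genotypes: ",
         paste(nm[bad], collapse = ", "))
  }
  p <- colSums(genotypes, na.rm = TRUE) / (2 * n_ok)
  pmin(pmax(p, 1 / (4 * n_ok)), 1 - 1 / (4 * n_ok))
}

# Internal: Mendelian transmission probabilities M[t+1, gs+1, gd+1] =
# P(offspring true genotype t | sire gs, dam gd) under fair segregation.
mendel_array <- function() {
  M <- array(0, dim = c(3, 3, 3))
  for (gs in 0:2) for (gd in 0:2) {
    ps <- c(1 - gs / 2, gs / 2)  # P(sire transmits 0 / 1 minor copies)
    pd <- c(1 - gd / 2, gd / 2)
    for (a in 0:1) for (b in 0:1) {
      M[a + b + 1, gs + 1, gd + 1] <- M[a + b + 1, gs + 1, gd + 1] +
        ps[a + 1] * pd[b + 1]
    }
  }
  M
}

# Internal: 9 x 4 table of P(observed code | sire genotype, dam genotype)
# folding in the uniform miscall model with rate e. Rows are indexed by
# k = 3 * gs + gd + 1; columns are observed codes 0, 1, 2, and missing
# (weight 1, i.e., marginalised out).
pair_weight_table <- function(e) {
  M <- mendel_array()
  E <- matrix(e / 2, 3, 3)
  diag(E) <- 1 - e
  W <- matrix(1, 9, 4)
  for (gs in 0:2) for (gd in 0:2) {
    k <- 3 * gs + gd + 1
    for (obs in 0:2) {
      W[k, obs + 1] <- sum(M[, gs + 1, gd + 1] * E[obs + 1, ])
    }
  }
  W
}

# Internal: Hardy-Weinberg genotype priors, 3 x L.
hw_matrix <- function(freqs) {
  rbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2)
}

# Internal: per-locus priors of ordered (sire, dam) genotype pairs, 9 x L,
# row index k = 3 * gs + gd + 1.
pair_prior_matrix <- function(freqs) {
  hw <- hw_matrix(freqs)
  out <- matrix(0, 9, length(freqs))
  for (gs in 0:2) for (gd in 0:2) {
    out[3 * gs + gd + 1, ] <- hw[gs + 1, ] * hw[gd + 1, ]
  }
  out
}

#' Construct a sibship partition
#'
#' A sibship partition assigns every offspring a latent (anonymous) sire
#' and dam label. Full-sib clusters are the groups sharing both labels;
#' half-sib dyads share exactly one. Structural constraints are enforced per
#' mating system: under monogamy sires and dams pair one-to-one (so no
#' half-sib dyad is derivable), under male polygamy / female monogamy each
#' dam has exactly one sire while a sire may span dams.
#'
#' @param offspring_id character vector of offspring IDs (unique).
#' @param sire,dam latent parent labels, parallel to `offspring_id`.
#' @param mating_system one of `"monogamy"`,
#'   `"male_polygamy_female_monogamy"`, `"polygamy"`.
#' @param log_lik optional log-likelihood of the configuration.
#' @return an object of class `sibship_partition`.
#' @export
sibship_partition <- function(offspring_id, sire, dam,
                              mating_system = c("polygamy", "monogamy",
                                                "male_polygamy_female_monogamy"),
                              log_lik = NA_real_) {
  mating_system <- match.arg(mating_system)
  offspring_id <- as.character(offspring_id)
  sire <- as.character(sire); dam <- as.character(dam)
  stopifnot(length(sire) == length(offspring_id),
            length(dam) == length(offspring_id))
  if (anyDuplicated(offspring_id)) stop("duplicate offspring IDs")
  if (mating_system == "monogamy") {
    map <- unique(data.frame(sire, dam))
    if (anyDuplicated(map$sire) || anyDuplicated(map$dam)) {
      stop("monogamy requires a one-to-one pairing of latent sires and dams")
    }
  } else if (mating_system == "male_polygamy_female_monogamy") {
    map <- unique(data.frame(sire, dam))
    if (anyDuplicated(map$dam)) {
      stop("male polygamy / female monogamy requires each dam to have exactly one sire")
    }
  }
  structure(list(offspring_id = offspring_id, sire = sire, dam = dam,
                 mating_system = mating_system, log_lik = log_lik),
            class = "sibship_partition")
}

#' @export
print.sibship_partition <- function(x, ...) {
  cl <- table(table(paste(x$sire, x$dam, sep = "\r")))
  cat(sprintf("Sibship partition (%s): %d offspring, %d full-sib clusters\n",
              x$mating_system, length(x$offspring_id),
              length(unique(paste(x$sire, x$dam, sep = "\r")))))
  cat("Cluster sizes:\n"); print(cl)
  if (!is.na(x$log_lik)) cat(sprintf("log-likelihood: %.3f\n", x$log_lik))
  invisible(x)
}

#' Classify all dyads implied by a sibship partition
#'
#' Pairs sharing both latent parents are full-sibs, exactly one half-sibs,
#' none unrelated. Counts always sum to `choose(n, 2)`; monogamy partitions
#' never yield half-sib dyads.
#'
#' @param partition a [sibship_partition()].
#' @return a `dyad_labels` object (see [label_dyads()]).
#' @export
classify_dyads <- function(partition) {
  dyads_from_parents(partition$offspring_id, partition$sire, partition$dam)
}

# Internal: connected components of the latent-parent graph. Returns a list
# of components, each with parent labels and the offspring rows they cover.
parent_components <- function(sire, dam) {
  ps <- paste0("S\r", sire)
  pd <- paste0("D\r", dam)
  parents <- unique(c(ps, pd))
  idx <- seq_along(parents)
  find <- function(i) { while (idx[i] != i) { idx[i] <<- idx[idx[i]]; i <- idx[i] }; i }
  si <- match(ps, parents); di <- match(pd, parents)
  for (o in seq_along(si)) {
    ri <- find(si[o]); rj <- find(di[o])
    if (ri != rj) idx[ri] <- rj
  }
  roots <- vapply(seq_along(parents), find, integer(1))
  comp_of_off <- roots[si]
  lapply(split(seq_along(si), comp_of_off), function(rows) {
    pid <- unique(c(ps[rows], pd[rows]))
    list(parents = pid,
         offspring = rows,
         si = match(ps[rows], pid),
         di = match(pd[rows], pid))
  })
}

#' Exact log-likelihood of a sibship configuration
#'
#' Computes the full likelihood of observed offspring genotypes given a
#' sibship partition: per locus, latent parental genotypes receive
#' Hardy-Weinberg priors at the supplied allele frequencies, offspring
#' genotypes follow Mendelian transmission, and observations pass through a
#' uniform miscall model with rate `error_rate`; loci multiply. Latent
#' parents shared across crosses are marginalised jointly: each connected
#' component of the latent parent-cross graph is summed exactly over all
#' parental genotype combinations when it has at most
#' `max_component_parents` parents, and otherwise approximated by iterated
#' single-parent conditional updates (flagged via the
#' `approximated_components` attribute and a warning).
#'
#' Missing genotypes contribute probability 1 at their locus. Because every
#' locus contributes a log-probability `<= 0`, the log-likelihood is
#' monotone non-increasing as loci are added.
#'
#' @param partition a [sibship_partition()].
#' @param genotypes genotype matrix (rows must cover the partition's
#'   offspring IDs).
#' @param freqs per-locus allele frequencies; default
#'   [estimate_allele_freqs()] on `genotypes`.
#' @param error_rate assumed miscall rate (may differ from the simulated
#'   rate).
#' @param max_component_parents cap on exact joint summation (default 12).
#' @param approx if `FALSE`, components over the cap are an error instead
#'   of being approximated.
#' @return the log-likelihood (scalar), with attribute
#'   `approximated_components` giving the number of over-cap components.
#' @export
config_log_likelihood <- function(partition, genotypes,
                                  freqs = estimate_allele_freqs(genotypes),
                                  error_rate = 0.01,
                                  max_component_parents = 12L,
                                  approx = TRUE) {
  stopifnot(inherits(partition, "sibship_partition"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (max_component_parents < 2L) stop("max_component_parents must be >= 2")
  rows <- match(partition$offspring_id, rownames(genotypes))
  if (anyNA(rows)) stop("genotypes missing for some partition offspring")
  codes <- genotypes[rows, , drop = FALSE]
  codes[is.na(codes)] <- 3L  # missing -> weight-1 column of the pair table
  wtab <- pair_weight_table(error_rate)
  hw <- hw_matrix(freqs)
  comps <- parent_components(partition$sire, partition$dam)
  n_approx <- 0L
  ll <- 0
  for (cp in comps) {
    P <- length(cp$parents)
    if (P <= max_component_parents) {
      ll <- ll + component_loglik_exact(cp, codes, wtab, hw)
    } else if (approx) {
      n_approx <- n_approx + 1L
      ll <- ll + component_loglik_icm(cp, codes, wtab, hw)
    } else {
      stop(sprintf(
        "component with %d parents exceeds max_component_parents = %d and approximation is disabled",
        P, max_component_parents))
    }
  }
  if (n_approx > 0L) {
    warning(sprintf("%d component(s) over the parent cap were approximated by iterated conditional updates",
                    n_approx))
  }
  structure(ll, approximated_components = n_approx)
}

# Internal: exact component log-likelihood by summation over all 3^P
# parental genotype combinations. Vectorised across loci when the
# combos x loci table fits comfortably in memory, per-locus otherwise.
component_loglik_exact <- function(cp, codes, wtab, hw) {
  P <- length(cp$parents)
  L <- ncol(codes)
  G <- as.matrix(expand.grid(rep(list(0:2), P), KEEP.OUT.ATTRS = FALSE))
  nC <- nrow(G)
  idx9 <- lapply(seq_along(cp$offspring), function(k) {
    3L * G[, cp$si[k]] + G[, cp$di[k]] + 1L
  })
  if (nC * L <= 2^23) {
    acc <- matrix(1, nC, L)
    for (p in seq_len(P)) acc <- acc * hw[G[, p] + 1L, , drop = FALSE]
    for (k in seq_along(cp$offspring)) {
      wsel <- wtab[, codes[cp$offspring[k], ] + 1L, drop = FALSE]  # 9 x L
      acc <- acc * wsel[idx9[[k]], , drop = FALSE]
    }
    sum(log(colSums(acc)))
  } else {
    ll <- 0
    for (l in seq_len(L)) {
      acc <- rep(1, nC)
      for (p in seq_len(P)) acc <- acc * hw[G[, p] + 1L, l]
      for (k in seq_along(cp$offspring)) {
        acc <- acc * wtab[idx9[[k]], codes[cp$offspring[k], l] + 1L]
      }
      ll <- ll + log(sum(acc))
    }
    ll
  }
}

# Internal: approximate component log-likelihood for over-cap components.
# Structured mean-field (coordinate ascent): each parent keeps an
# independent per-locus genotype distribution, updated one parent at a time
# against the others' current distributions; the returned value is the
# variational lower bound (ELBO), so large components are never overrated
# relative to exactly summed ones.
component_loglik_icm <- function(cp, codes, wtab, hw, max_sweeps = 25L,
                                 tol = 1e-8) {
  P <- length(cp$parents)
  L <- ncol(codes)
  K <- length(cp$offspring)
  loghw <- log(hw)
  # per-offspring log pair weights, floored away from -Inf so that
  # zero-probability cells (possible when the assumed error rate is 0)
  # stay finite in expectations
  logw <- lapply(seq_len(K), function(k) {
    log(pmax(wtab[, codes[cp$offspring[k], ] + 1L, drop = FALSE], 1e-300))
  })
  q <- replicate(P, hw, simplify = FALSE)  # 3 x L each, init at HW prior
  # E_{q_other}[log w(g_p, g_other)] as a 3 x L matrix
  exp_logw <- function(k, role) {
    out <- matrix(0, 3, L)
    for (g in 0:2) {
      ks <- if (role == "sire") 3L * g + (0:2) + 1L else 3L * (0:2) + g + 1L
      qo <- if (role == "sire") q[[cp$di[k]]] else q[[cp$si[k]]]
      out[g + 1L, ] <- colSums(logw[[k]][ks, , drop = FALSE] * qo)
    }
    out
  }
  elbo <- function() {
    v <- 0
    for (p in seq_len(P)) {
      qp <- q[[p]]
      v <- v + sum(qp * loghw) - sum(qp * log(pmax(qp, 1e-300)))
    }
    for (k in seq_len(K)) {
      qs <- q[[cp$si[k]]]; qd <- q[[cp$di[k]]]
      for (gs in 0:2) {
        ks <- 3L * gs + (0:2) + 1L
        v <- v + sum(qs[gs + 1L, ] *
                       colSums(logw[[k]][ks, , drop = FALSE] * qd))
      }
    }
    v
  }
  prev <- -Inf
  for (it in seq_len(max_sweeps)) {
    for (p in seq_len(P)) {
      m <- loghw
      for (k in seq_len(K)) {
        if (cp$si[k] == p) m <- m + exp_logw(k, "sire")
        else if (cp$di[k] == p) m <- m + exp_logw(k, "dam")
      }
      m <- exp(sweep(m, 2L, apply(m, 2L, max), "-"))
      q[[p]] <- sweep(m, 2L, colSums(m), "/")
    }
    cur <- elbo()
    if (cur - prev < tol) break
    prev <- cur
  }
  elbo()
}
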