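# Independent oracles, written from the definitions (not the package's
# internals): Crow-Denniston closed form, O(n^2) dyad scans, and full
# enumeration of the sibship likelihood over all parental genotypes.

# Crow-Denniston inbreeding effective size, mean/variance form
oracle_crow_denniston <- function(ki) {
  N <- length(ki)
  kbar <- mean(ki)
  vk <- mean((ki - kbar)^2)
  (N * kbar - 1) / (kbar - 1 + vk / kbar)
}

# brute-force dyad counts from parallel sire/dam vectors
oracle_dyad_counts <- function(sire, dam) {
  n <- length(sire)
  counts <- c(FS = 0L, HS = 0L, U = 0L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- (sire[i] == sire[j]) + (dam[i] == dam[j])
      lab <- c("U", "HS", "FS")[shared + 1]
      counts[lab] <- counts[lab] + 1L
    }
  }
  counts
}

# P(offspring true genotype t | gs, gd) by explicit allele accounting
oracle_mendel <- function(t, gs, gd) {
  ps <- c(1 - gs / 2, gs / 2)
  pd <- c(1 - gd / 2, gd / 2)
  tot <- 0
  for (a in 0:1) for (b in 0:1) if (a + b == t) tot <- tot + ps[a + 1] * pd[b + 1]
  tot
}

# P(observed | gs, gd) with the uniform miscall model
oracle_pobs <- function(obs, gs, gd, e) {
  tot <- 0
  for (t in 0:2) {
    pe <- if (obs == t) 1 - e else e / 2
    tot <- tot + oracle_mendel(t, gs, gd) * pe
  }
  tot
}

# full-enumeration log-likelihood of a sibship configuration: sires and
# dams live in separate label spaces; every parent's genotype is summed
# over with Hardy-Weinberg priors. Exponential in the number of parents,
# so only for tiny examples.
oracle_partition_loglik <- function(sire, dam, geno, freqs, e) {
  parents <- unique(c(paste0("S.", sire), paste0("D.", dam)))
  P <- length(parents)
  si <- match(paste0("S.", sire), parents)
  di <- match(paste0("D.", dam), parents)
  grid <- as.matrix(expand.grid(rep(list(0:2), P)))
  pobs <- array(NA_real_, c(3, 3, 3))  # [obs+1, gs+1, gd+1]
  for (obs in 0:2) for (gs in 0:2) for (gd in 0:2) {
    pobs[obs + 1, gs + 1, gd + 1] <- oracle_pobs(obs, gs, gd, e)
  }
  ll <- 0
  for (l in seq_len(ncol(geno))) {
    p <- freqs[l]
    hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      term <- prod(hw[grid[r, ] + 1])
      for (o in seq_len(nrow(geno))) {
        obs <- geno[o, l]
        if (is.na(obs)) next
        term <- term * pobs[obs + 1, grid[r, si[o]] + 1, grid[r, di[o]] + 1]
      }
      tot <- tot + term
    }
    ll <- ll + log(tot)
  }
  ll
}

# tiny simulated cohort used across tests
quick_cohort <- function(seed = 1, n = 24, n_loci = 95, theta = 0.8,
                         reuse = 0, contamination = 0, error_rate = 0.01,
                         n_females = n %/% 2, n_males = n %/% 2) {
  cfg <- sim_config(n_females = n_females, n_males = n_males,
                    total_offspring = n, male_reuse_rate = reuse,
                    contamination_rate = contamination,
                    fecundity_dispersion = theta, n_loci = n_loci,
                    error_rate = error_rate, seed = seed)
  ped <- simulate_pedigree(cfg)
  list(config = cfg, pedigree = ped, genotypes = simulate_genotypes(ped))
}

# true-pedigree partition: latent labels are the real parent IDs
truth_partition <- function(pedigree, ids = pedigree$offspring$offspring_id) {
  off <- pedigree$offspring
  off <- off[match(ids, off$offspring_id), ]
  sibship_partition(off$offspring_id, off$sire_id, off$dam_id, "polygamy")
}
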