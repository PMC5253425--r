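#' Simulation configuration for a hatchery-style cohort
#'
#' Bundles and validates all parameters of the pedigree and genotype
#' simulator. The defaults emulate the spawning protocols of the steelhead
#' hatcheries the package is benchmarked against: predominantly monogamous
#' crosses, occasional reuse of a male in a second cross, occasional
#' contamination merging two crosses into a 2-male x 2-female matrix, and a
#' long zero tail of unsuccessful parents governed by a single
#' Dirichlet-multinomial concentration parameter.
#'
#' @param n_females,n_males number of female/male broodstock spawned (the
#'   census size is `n_females + n_males`).
#' @param total_offspring number of offspring `S` in the sampled cohort.
#' @param male_reuse_rate probability that a cross reuses an already-used
#'   male (each male serves at most two crosses; reuse is also forced when
#'   females outnumber males).
#' @param contamination_rate probability that a cross is merged with another
#'   into a 2-male x 2-female cross matrix in which each offspring draws its
#'   sire and dam uniformly.
#' @param fecundity_dispersion concentration `theta` of the
#'   Dirichlet-multinomial family-size model over crosses. Smaller values
#'   give more zero-offspring parents and a lower Nb/NC ratio; `Inf` gives
#'   exactly equal allocation.
#' @param n_loci number of biallelic SNP loci (default 95).
#' @param maf_low,maf_high bounds of the uniform minor-allele-frequency
#'   distribution for simulated loci, both in (0, 0.5].
#' @param error_rate per-genotype miscall probability `e`: with probability
#'   `e` the observed genotype is replaced by one of the other two codes,
#'   uniformly.
#' @param missing_rate probability a genotype is set missing.
#' @param seed integer RNG seed; the same configuration and seed reproduce
#'   byte-identical pedigrees and genotype tables.
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_pedigree()], [simulate_genotypes()],
#'   [hatchery_populations()], [population_config()]
#' @export
sim_config <- function(n_females, n_males, total_offspring,
                       male_reuse_rate = 0.05,
                       contamination_rate = 0.01,
                       fecundity_dispersion = 1,
                       n_loci = 95L,
                       maf_low = 0.1, maf_high = 0.5,
                       error_rate = 0.01,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    total_offspring = as.integer(total_offspring),
    male_reuse_rate = male_reuse_rate,
    contamination_rate = contamination_rate,
    fecundity_dispersion = fecundity_dispersion,
    n_loci = as.integer(n_loci),
    maf_low = maf_low, maf_high = maf_high,
    error_rate = error_rate, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c("male_reuse_rate", "contamination_rate", "error_rate",
             "missing_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1]", p))
    }
  }
  if (cfg$n_females < 1L || cfg$n_males < 1L) {
    stop("need at least one female and one male")
  }
  if (cfg$total_offspring < 2L) stop("'total_offspring' must be at least 2")
  if (cfg$n_loci < 1L) stop("'n_loci' must be at least 1")
  if (!(cfg$maf_low > 0 && cfg$maf_high <= 0.5 &&
        cfg$maf_low <= cfg$maf_high)) {
    stop("need 0 < maf_low <= maf_high <= 0.5")
  }
  if (!(is.numeric(cfg$fecundity_dispersion) &&
        cfg$fecundity_dispersion > 0)) {
    stop("'fecundity_dispersion' must be positive (Inf allowed)")
  }
  invisible(cfg)
}

#' Study-population design table
#'
#' The five hatchery populations the package's simulator is benchmarked
#' against, with broodstock counts split by sex, cohort sizes, the true
#' effective number of breeders obtained from complete pedigrees, and the
#' Nb/NC ratio. These rows are design inputs for [population_config()]; the
#' `theta` column is the package's default Dirichlet-multinomial
#' concentration, calibrated with [calibrate_dispersion()] so that simulated
#' cohorts reproduce each population's Nb/NC ratio.
#'
#' @return a data frame with one row per population.
#' @export
hatchery_populations <- function() {
  data.frame(
    population   = c("dworshak", "pahsimeroi", "sawtooth", "oxbow",
                     "lyons_ferry"),
    n_total      = c(1873L, 1279L, 979L, 592L, 215L),
    n_females    = c(1096L, 627L, 489L, 296L, 106L),
    n_males      = c(777L, 652L, 490L, 296L, 109L),
    n_successful = c(799L, 545L, 389L, 238L, 81L),
    true_nb      = c(573L, 353L, 315L, 200L, 58L),
    nb_nc_ratio  = c(0.306, 0.276, 0.322, 0.337, 0.270),
    n_offspring  = c(1516L, 1481L, 739L, 400L, 80L),
    theta        = c(0.396, 0.396, 0.478, 0.501, 0.328),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for one of the study populations
#'
#' Builds a [sim_config()] from a row of [hatchery_populations()], using the
#' per-population calibrated dispersion `theta` as the family-size
#' concentration. Any field can be overridden through `...`.
#'
#' @param population one of `"dworshak"`, `"pahsimeroi"`, `"sawtooth"`,
#'   `"oxbow"`, `"lyons_ferry"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
population_config <- function(population, ...) {
  tbl <- hatchery_populations()
  row <- tbl[tbl$population == population, ]
  if (nrow(row) != 1L) {
    stop("unknown population: ", population, " (see hatchery_populations())")
  }
  args <- list(
    n_females = row$n_females, n_males = row$n_males,
    total_offspring = row$n_offspring,
    fecundity_dispersion = row$theta
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a hatchery-style pedigree
#'
#' Builds crosses by pairing each female with a male. Males are drawn fresh
#' while unused males remain, but with probability `male_reuse_rate` (and
#' always once fresh males run out) an already-used male is reused for a
#' second cross; no male serves more than two crosses. With probability
#' `contamination_rate` a cross is merged with another flagged cross into a
#' 2-male x 2-female matrix in which each offspring draws its sire and dam
#' uniformly. `total_offspring` offspring are then allocated to cross units
#' by a Dirichlet-multinomial with concentration `fecundity_dispersion` per
#' cross (zero-offspring crosses are allowed and expected).
#'
#' The parent roster lists every spawned parent, including those that
#' produce no offspring; the true Nb is obtained by
#' `pwop_nb(ki_vector(pedigree))`.
#'
#' @param config a [sim_config()].
#' @return an object of class `hatchery_pedigree`: list with `parents`
#'   (data frame `parent_id`, `sex`), `crosses` (list of mating units, each
#'   with `sires` and `dams` ID vectors), `offspring` (data frame
#'   `offspring_id`, `sire_id`, `dam_id`) and the `config`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  if (config$n_females > 2L * config$n_males) {
    stop(sprintf(
      "cannot form %d crosses from %d males reused at most once each (max %d)",
      config$n_females, config$n_males, 2L * config$n_males))
  }
  with_seed(derive_seed(config$seed, "pedigree"), {
    females <- sprintf("F%04d", seq_len(config$n_females))
    males <- sprintf("M%04d", seq_len(config$n_males))

    # one cross per female; fresh male unless reuse fires or males run out
    unused <- sample(males)  # random spawning order of males
    used_once <- character(0)
    sire_of <- character(config$n_females)
    for (i in seq_len(config$n_females)) {
      reuse <- length(used_once) > 0L &&
        (length(unused) == 0L || runif(1) < config$male_reuse_rate)
      if (reuse) {
        pick <- if (length(used_once) == 1L) used_once else
          sample(used_once, 1L)
        used_once <- setdiff(used_once, pick)
      } else {
        if (length(unused) == 0L) {
          stop("ran out of males: more reused males requested than available")
        }
        pick <- unused[1L]
        unused <- unused[-1L]
        used_once <- c(used_once, pick)
      }
      sire_of[i] <- pick
    }

    crosses <- lapply(seq_len(config$n_females), function(i) {
      list(sires = sire_of[i], dams = females[i])
    })

    # contamination: flagged crosses merged pairwise into 2x2 matrices
    flagged <- which(runif(length(crosses)) < config$contamination_rate)
    if (length(flagged) >= 2L) {
      npair <- length(flagged) %/% 2L
      drop <- integer(0)
      for (k in seq_len(npair)) {
        a <- flagged[2L * k - 1L]; b <- flagged[2L * k]
        crosses[[a]] <- list(
          sires = unique(c(crosses[[a]]$sires, crosses[[b]]$sires)),
          dams = c(crosses[[a]]$dams, crosses[[b]]$dams))
        drop <- c(drop, b)
      }
      crosses <- crosses[-drop]
    }

    # Dirichlet-multinomial allocation of offspring over cross units
    K <- length(crosses)
    theta <- config$fecundity_dispersion
    S <- config$total_offspring
    if (is.infinite(theta)) {
      counts <- rep(S %/% K, K) + as.integer(seq_len(K) <= S %% K)
    } else {
      w <- rgamma(K, shape = theta, rate = 1)
      if (sum(w) <= 0) w[sample.int(K, 1L)] <- 1
      counts <- as.integer(rmultinom(1L, S, w))
    }

    sire_id <- character(S); dam_id <- character(S)
    pos <- 1L
    for (k in seq_len(K)) {
      ck <- counts[k]
      if (ck == 0L) next
      cr <- crosses[[k]]
      idx <- pos:(pos + ck - 1L)
      sire_id[idx] <- if (length(cr$sires) == 1L) cr$sires else
        sample(cr$sires, ck, replace = TRUE)
      dam_id[idx] <- if (length(cr$dams) == 1L) cr$dams else
        sample(cr$dams, ck, replace = TRUE)
      pos <- pos + ck
    }

    structure(list(
      parents = data.frame(
        parent_id = c(females, males),
        sex = rep(c("F", "M"), c(length(females), length(males))),
        stringsAsFactors = FALSE),
      crosses = crosses,
      offspring = data.frame(
        offspring_id = sprintf("O%05d", seq_len(S)),
        sire_id = sire_id, dam_id = dam_id, stringsAsFactors = FALSE),
      config = config
    ), class = "hatchery_pedigree")
  })
}

#' @export
print.hatchery_pedigree <- function(x, ...) {
  ki <- ki_vector(x)
  cat(sprintf(
    "Hatchery pedigree: %d parents (%d F, %d M), %d crosses, %d offspring\n",
    nrow(x$parents), sum(x$parents$sex == "F"), sum(x$parents$sex == "M"),
    length(x$crosses), nrow(x$offspring)))
  cat(sprintf("Successful parents: %d; true Nb (PwoP) = %.1f; Nb/NC = %.3f\n",
              length(ki), pwop_nb(ki), pwop_nb(ki) / nrow(x$parents)))
  invisible(x)
}

#' Drop SNP genotypes through a pedigree with genotyping error
#'
#' Draws a minor-allele frequency per locus uniformly in
#' `[maf_low, maf_high]`, assigns founder (parent) genotypes from
#' Hardy-Weinberg proportions, and transmits one allele from each parent to
#' each offspring by fair Mendelian segregation. Genotyping error is then
#' applied per genotype: with probability `error_rate` the observed code is
#' replaced by one of the other two codes uniformly, and with probability
#' `missing_rate` the genotype is set to `NA`.
#'
#' The error and missingness stages use RNG streams separate from the
#' transmission stage, so re-simulating the same pedigree and seed with a
#' different `error_rate` perturbs only the miscalled cells.
#'
#' @param pedigree a `hatchery_pedigree`.
#' @param config a [sim_config()]; locus count, MAF bounds, error and
#'   missingness rates and the seed are taken from it.
#' @return an integer matrix (offspring x loci) of codes 0/1/2 counting
#'   copies of the minor allele, `NA` for missing, with attribute `freqs`
#'   (the simulating per-locus allele frequencies) and class
#'   `genotype_table`.
#' @export
simulate_genotypes <- function(pedigree, config = pedigree$config) {
  validate_sim_config(config)
  off <- pedigree$offspring
  n <- nrow(off)
  L <- config$n_loci
  base <- with_seed(derive_seed(config$seed, "genotypes"), {
    p <- runif(L, config$maf_low, config$maf_high)
    parents <- pedigree$parents$parent_id
    gp <- matrix(rbinom(length(parents) * L, 2L, rep(p, each = length(parents))),
                 nrow = length(parents), ncol = L,
                 dimnames = list(parents, NULL))
    si <- match(off$sire_id, parents)
    di <- match(off$dam_id, parents)
    a1 <- matrix(rbinom(n * L, 1L, gp[si, , drop = FALSE] / 2), n, L)
    a2 <- matrix(rbinom(n * L, 1L, gp[di, , drop = FALSE] / 2), n, L)
    list(p = p, g = a1 + a2)
  })
  g <- base$g
  if (config$error_rate > 0) {
    g <- with_seed(derive_seed(config$seed, "error"), {
      hit <- runif(n * L) < config$error_rate
      shift <- sample(1:2, n * L, replace = TRUE)
      gv <- as.integer(g)
      gv[hit] <- (gv[hit] + shift[hit]) %% 3L
      matrix(gv, n, L)
    })
  }
  if (config$missing_rate > 0) {
    g <- with_seed(derive_seed(config$seed, "missing"), {
      g[matrix(runif(n * L) < config$missing_rate, n, L)] <- NA_integer_
      g
    })
  }
  mode(g) <- "integer"
  dimnames(g) <- list(off$offspring_id, sprintf("L%03d", seq_len(L)))
  structure(g, freqs = base$p, class = c("genotype_table", class(g)))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Calibrate the family-size dispersion to a target Nb/NC ratio
#'
#' Finds the Dirichlet-multinomial concentration `theta` such that the mean
#' true Nb/NC ratio (PwoP on complete simulated pedigrees) over `n_reps`
#' replicate simulations matches `target_ratio` within a relative
#' `tolerance`. The mean ratio is monotone increasing in `theta`, so the
#' search is a bisection on `log(theta)`.
#'
#' Targets above what even the most even allocation can achieve (equal
#' family sizes arise only in the `theta -> Inf` limit) return the upper
#' bound of `theta_range` with attribute `at_ceiling = TRUE` and a warning.
#' Targets below the ratio achievable at the lower bound are an error that
#' names the achievable bound.
#'
#' @param config a [sim_config()]; its `fecundity_dispersion` is ignored.
#' @param target_ratio desired mean Nb/NC, in (0, 1].
#' @param tolerance relative tolerance on the achieved mean ratio
#'   (default 0.1).
#' @param n_reps replicate pedigrees per ratio evaluation (minimum 20).
#' @param theta_range search interval for `theta`.
#' @param max_iter bisection iteration cap.
#' @return the calibrated `theta`, with attributes `achieved_ratio` and
#'   `at_ceiling`.
#' @export
calibrate_dispersion <- function(config, target_ratio, tolerance = 0.1,
                                 n_reps = 20L,
                                 theta_range = c(1e-3, 1e4),
                                 max_iter = 40L) {
  validate_sim_config(config)
  if (!is.numeric(target_ratio) || length(target_ratio) != 1L ||
      target_ratio <= 0 || target_ratio > 1) {
    stop("'target_ratio' must be in (0, 1]")
  }
  n_reps <- max(20L, as.integer(n_reps))
  nc <- config$n_females + config$n_males
  mean_ratio <- function(theta) {
    r <- vapply(seq_len(n_reps), function(i) {
      cfg <- config
      cfg$fecundity_dispersion <- theta
      cfg$seed <- derive_seed(config$seed, paste0("calib", i))
      pwop_nb(ki_vector(simulate_pedigree(cfg))) / nc
    }, numeric(1))
    mean(r[is.finite(r)])
  }
  lo <- theta_range[1]; hi <- theta_range[2]
  r_hi <- mean_ratio(hi)
  # a ratio of 1 is the ideal-population limit, attained only as theta
  # grows without bound, so targets at or above min(1, achievable mean)
  # return the ceiling
  if (target_ratio >= min(1, r_hi)) {
    warning(sprintf(
      "target ratio %.3f is at or above the achievable mean %.3f at theta = %g; returning the ceiling",
      target_ratio, r_hi, hi))
    return(structure(hi, achieved_ratio = r_hi, at_ceiling = TRUE))
  }
  r_lo <- mean_ratio(lo)
  if (target_ratio < r_lo) {
    stop(sprintf(
      "target ratio %.3f is below the achievable minimum %.3f (at theta = %g)",
      target_ratio, r_lo, lo))
  }
  theta <- sqrt(lo * hi); r <- mean_ratio(theta)
  for (it in seq_len(max_iter)) {
    if (abs(r - target_ratio) <= tolerance * target_ratio) break
    if (r < target_ratio) lo <- theta else hi <- theta
    theta <- sqrt(lo * hi)
    r <- mean_ratio(theta)
  }
  structure(theta, achieved_ratio = r, at_ceiling = FALSE)
}
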