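#' Reconstruction configuration
#'
#' Settings for the simulated-annealing maximum-likelihood sibship search.
#' Defaults: 20 restarts of `50 * n` proposed moves each, geometric cooling
#' by 0.95 every `n` proposals, initial temperature chosen from a pilot so
#' that a typical uphill-cost move accepts with ~50% probability, ties
#' broken by first-found.
#'
#' @param mating_system assumed mating system: `"monogamy"` (full-sib
#'   clusters only), `"male_polygamy_female_monogamy"` (sires may span
#'   dams), or `"polygamy"` (both parents free).
#' @param error_rate assumed per-genotype miscall rate; may deliberately
#'   differ from the rate used in simulation.
#' @param seed RNG seed for the stochastic search.
#' @param restarts independent annealing restarts; the best configuration
#'   over restarts is returned.
#' @param moves_factor proposals per restart, as a multiple of the number
#'   of offspring.
#' @param cooling geometric cooling factor applied every `n` proposals.
#' @param init_temp starting temperature; `NULL` selects it automatically.
#' @param greedy_sweeps maximum hill-climbing sweeps after each restart.
#' @param max_component_parents cap for exact joint marginalisation of a
#'   latent-parent component (larger components are approximated and
#'   flagged).
#' @param sibship_prior only `"uniform"` is implemented: no prior over
#'   configurations, so the search maximises the genotype likelihood alone.
#' @return a list of class `recon_config`.
#' @export
recon_config <- function(mating_system = c("monogamy",
                                           "male_polygamy_female_monogamy",
                                           "polygamy"),
                         error_rate = 0.01, seed = 1L,
                         restarts = 20L, moves_factor = 50L,
                         cooling = 0.95, init_temp = NULL,
                         greedy_sweeps = 10L,
                         max_component_parents = 12L,
                         sibship_prior = "uniform") {
  mating_system <- match.arg(mating_system)
  sibship_prior <- match.arg(sibship_prior, "uniform")
  stopifnot(error_rate >= 0, error_rate < 1, restarts >= 1,
            moves_factor >= 1, cooling > 0, cooling < 1,
            max_component_parents >= 2)
  structure(list(mating_system = mating_system, error_rate = error_rate,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 moves_factor = as.integer(moves_factor), cooling = cooling,
                 init_temp = init_temp,
                 greedy_sweeps = as.integer(greedy_sweeps),
                 max_component_parents = as.integer(max_component_parents),
                 sibship_prior = sibship_prior),
            class = "recon_config")
}

#' Maximum-likelihood sibship reconstruction from offspring genotypes
#'
#' Infers sibship structure from offspring genotypes alone by maximising
#' the full configuration likelihood (see [config_log_likelihood()]) under
#' an assumed mating system and genotyping error rate. The search starts
#' from the all-singleton configuration and explores moves (move one
#' offspring between families, merge two families, split a family, and -
#' under polygamous assumptions - reassign an offspring's latent sire or
#' dam independently) with Metropolis acceptance under a geometric
#' annealing schedule, followed by greedy hill-climbing; the best
#' configuration over restarts is returned. The returned log-likelihood is
#' never below that of the all-singleton start, and the result is
#' deterministic given the seed.
#'
#' Individuals with no non-missing genotypes carry no information and are
#' excluded with a warning.
#'
#' @param genotypes matrix of 0/1/2 codes (`NA` missing), individuals x
#'   loci, with row names.
#' @param config a [recon_config()]; individual settings may also be passed
#'   through `...` as overrides.
#' @param ... overrides for fields of `config`.
#' @return an object of class `sibship_fit` with components `partition`
#'   (a [sibship_partition()]), `log_lik`, `start_log_lik`, `freqs`,
#'   `config`, `excluded`, and the genotype table used.
#' @examples
#' cfg <- sim_config(n_females = 12, n_males = 12, total_offspring = 24,
#'                   male_reuse_rate = 0, contamination_rate = 0,
#'                   n_loci = 60, error_rate = 0.001, seed = 7)
#' ped <- simulate_pedigree(cfg)
#' g <- simulate_genotypes(ped)
#' fit <- reconstruct_sibships(g, recon_config(restarts = 4, seed = 7,
#'                                             error_rate = 0.001))
#' fit
#' @export
reconstruct_sibships <- function(genotypes, config = recon_config(), ...) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(config))
    if (length(bad)) stop("unknown recon_config fields: ",
                          paste(bad, collapse = ", "))
    config[names(over)] <- over
    config <- do.call(recon_config, config)
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("I%05d", seq_len(nrow(genotypes)))
  }
  all_missing <- rowSums(!is.na(genotypes)) == 0L
  excluded <- rownames(genotypes)[all_missing]
  if (length(excluded)) {
    warning("excluding individuals with no genotypes: ",
            paste(excluded, collapse = ", "))
    genotypes <- genotypes[!all_missing, , drop = FALSE]
  }
  n <- nrow(genotypes)
  if (n < 2L) stop("need at least 2 genotyped offspring")
  freqs <- estimate_allele_freqs(genotypes)

  if (config$mating_system == "monogamy") {
    res <- anneal_monogamy(genotypes, freqs, config)
  } else {
    res <- anneal_general(genotypes, freqs, config)
  }
  part <- sibship_partition(rownames(genotypes), res$sire, res$dam,
                            mating_system = config$mating_system,
                            log_lik = res$log_lik)
  structure(list(partition = part, log_lik = res$log_lik,
                 start_log_lik = res$start_log_lik,
                 init_temp = res$init_temp,
                 freqs = freqs, config = config,
                 excluded = excluded, genotypes = genotypes,
                 n = n, n_loci = ncol(genotypes)),
            class = "sibship_fit")
}

# Internal: monogamy search through the compiled annealer.
anneal_monogamy <- function(genotypes, freqs, config) {
  codes <- genotypes
  codes[is.na(codes)] <- 3L
  storage.mode(codes) <- "integer"
  wtab <- pair_weight_table(config$error_rate)
  prior9 <- pair_prior_matrix(freqs)
  n <- nrow(codes)
  res <- with_seed(derive_seed(config$seed, "anneal"), {
    .anneal_monogamy_cpp(codes, wtab, prior9,
                         restarts = config$restarts,
                         moves_per_restart = config$moves_factor * n,
                         cooling = config$cooling,
                         cool_interval = n,
                         init_temp = if (is.null(config$init_temp)) -1
                                     else config$init_temp,
                         greedy_sweeps = config$greedy_sweeps)
  })
  list(sire = paste0("S", res$assign), dam = paste0("D", res$assign),
       log_lik = res$log_lik, start_log_lik = res$start_log_lik,
       init_temp = res$init_temp)
}

# Internal: annealer for the polygamous mating assumptions, in R, with a
# component-level likelihood cache. States are latent sire/dam label
# vectors; under male polygamy / female monogamy the dam label determines
# the sire.
anneal_general <- function(genotypes, freqs, config) {
  n <- nrow(genotypes)
  codes <- genotypes
  codes[is.na(codes)] <- 3L
  storage.mode(codes) <- "integer"
  wtab <- pair_weight_table(config$error_rate)
  hw <- hw_matrix(freqs)
  cap <- config$max_component_parents
  mpfm <- config$mating_system == "male_polygamy_female_monogamy"

  # Search-time component likelihood: exact up to 8 parents, fast mean-field
  # beyond, and proposals creating components over 16 parents rejected
  # outright (returned as -Inf) to keep move evaluation bounded. The final
  # configuration is re-scored at the configured cap before returning.
  cache <- new.env(hash = TRUE, parent = emptyenv())
  comp_ll <- function(cp) {
    key <- paste(paste(cp$offspring, collapse = ","),
                 paste(cp$si, collapse = ","),
                 paste(cp$di, collapse = ","), sep = "|")
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    P <- length(cp$parents)
    v <- if (P <= min(cap, 8L)) {
      component_loglik_exact(cp, codes, wtab, hw)
    } else if (P <= 16L) {
      component_loglik_icm(cp, codes, wtab, hw, max_sweeps = 6L)
    } else {
      -Inf
    }
    cache[[key]] <- v
    v
  }
  total_ll <- function(sire, dam) {
    sum(vapply(parent_components(sire, dam), comp_ll, numeric(1)))
  }

  with_seed(derive_seed(config$seed, "anneal"), {
    new_label <- function(v) max(v) + 1L
    propose <- function(sire, dam) {
      o <- sample.int(n, 1L)
      u <- runif(1)
      if (mpfm) {
        if (u < 0.5) {             # move o into another dam's family
          o2 <- sample.int(n, 1L)
          if (o2 == o || dam[o2] == dam[o]) return(NULL)
          dam[o] <- dam[o2]; sire[o] <- sire[o2]
        } else if (u < 0.7) {      # fresh dam mated to an existing sire
          us <- unique(sire)
          s <- if (length(us) == 1L) us else sample(us, 1L)
          dam[o] <- new_label(dam); sire[o] <- s
        } else if (u < 0.9) {      # remate o's dam to another sire
          d <- dam[o]
          cand <- c(setdiff(unique(sire), sire[o]), new_label(sire))
          s <- if (length(cand) == 1L) cand else sample(cand, 1L)
          sire[dam == d] <- s
        } else {                   # fresh dam and fresh sire
          dam[o] <- new_label(dam); sire[o] <- new_label(sire)
        }
      } else {
        if (u < 0.4) {             # adopt another offspring's parent pair
          o2 <- sample.int(n, 1L)
          if (o2 == o || (sire[o2] == sire[o] && dam[o2] == dam[o]))
            return(NULL)
          sire[o] <- sire[o2]; dam[o] <- dam[o2]
        } else if (u < 0.6) {      # reassign sire only
          cand <- c(setdiff(unique(sire), sire[o]), new_label(sire))
          sire[o] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        } else if (u < 0.8) {      # reassign dam only
          cand <- c(setdiff(unique(dam), dam[o]), new_label(dam))
          dam[o] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        } else {                   # fresh singleton
          sire[o] <- new_label(sire); dam[o] <- new_label(dam)
        }
      }
      list(sire = sire, dam = dam)
    }

    start_sire <- seq_len(n); start_dam <- seq_len(n)
    start_ll <- total_ll(start_sire, start_dam)
    best <- list(sire = start_sire, dam = start_dam, ll = start_ll)

    moves <- config$moves_factor * n
    for (r in seq_len(config$restarts)) {
      sire <- start_sire; dam <- start_dam
      ll <- start_ll
      # pilot temperature from downhill costs at the start
      T <- config$init_temp
      if (is.null(T)) {
        drops <- c()
        for (t in seq_len(40L)) {
          pp <- propose(sire, dam)
          if (is.null(pp)) next
          d <- total_ll(pp$sire, pp$dam) - ll
          if (is.finite(d) && d < 0) drops <- c(drops, -d)
        }
        T <- if (length(drops)) stats::median(drops) / log(2) else 1
      }
      for (t in seq_len(moves)) {
        if (t %% n == 0L) T <- T * config$cooling
        pp <- propose(sire, dam)
        if (is.null(pp)) next
        ll_new <- total_ll(pp$sire, pp$dam)
        d <- ll_new - ll
        if (d >= 0 || runif(1) < exp(d / T)) {
          sire <- pp$sire; dam <- pp$dam; ll <- ll_new
        }
      }
      # greedy polish: accept only improving proposals
      for (s in seq_len(config$greedy_sweeps)) {
        improved <- FALSE
        for (t in seq_len(2L * n)) {
          pp <- propose(sire, dam)
          if (is.null(pp)) next
          ll_new <- total_ll(pp$sire, pp$dam)
          if (ll_new > ll + 1e-12) {
            sire <- pp$sire; dam <- pp$dam; ll <- ll_new
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (ll > best$ll) best <- list(sire = sire, dam = dam, ll = ll)
    }
    # re-score the best configuration at the configured component cap; if
    # the search-time approximation overrated it, fall back to singletons
    final_part <- sibship_partition(rownames(genotypes),
                                    paste0("S", best$sire),
                                    paste0("D", best$dam),
                                    mating_system = config$mating_system)
    ll_final <- suppressWarnings(as.numeric(config_log_likelihood(
      final_part, genotypes, freqs, config$error_rate,
      max_component_parents = cap)))
    if (ll_final < start_ll) {
      best <- list(sire = start_sire, dam = start_dam)
      ll_final <- start_ll
    }
    rs <- match(best$sire, unique(best$sire))
    rd <- match(best$dam, unique(best$dam))
    list(sire = paste0("S", rs), dam = paste0("D", rd),
         log_lik = ll_final, start_log_lik = start_ll, init_temp = NA_real_)
  })
}

#' @export
print.sibship_fit <- function(x, ...) {
  cat(sprintf("Sibship reconstruction (%s, assumed e = %g)\n",
              x$config$mating_system, x$config$error_rate))
  cat(sprintf("  %d offspring x %d loci; log-likelihood %.2f (start %.2f)\n",
              x$n, x$n_loci, x$log_lik, x$start_log_lik))
  cl <- table(paste(x$partition$sire, x$partition$dam, sep = "\r"))
  cat(sprintf("  %d full-sib clusters; size distribution:\n", length(cl)))
  print(table(as.integer(cl)))
  if (length(x$excluded)) {
    cat("  excluded (all genotypes missing): ",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
logLik.sibship_fit <- function(object, ...) {
  structure(object$log_lik,
            df = length(unique(paste(object$partition$sire,
                                     object$partition$dam))),
            nobs = object$n, class = "logLik")
}

#' @rdname reconstruct_sibships
#' @param object,x a `sibship_fit`.
#' @export
summary.sibship_fit <- function(object, ...) {
  q <- sibship_frequencies(object$partition)
  alpha <- estimate_alpha(object$genotypes, object$freqs)
  sa <- sa_nb(q, alpha)
  pwop <- pwop_nb_from_partition(object$partition)
  out <- list(mating_system = object$config$mating_system,
              error_rate = object$config$error_rate,
              n = object$n, n_loci = object$n_loci,
              log_lik = object$log_lik, q = q, alpha = alpha,
              nb_sa = sa, nb_pwop = pwop,
              dyads = classify_dyads(object$partition)$counts)
  class(out) <- "summary.sibship_fit"
  out
}

#' @export
print.summary.sibship_fit <- function(x, ...) {
  cat(sprintf("Sibship fit summary (%s, assumed e = %g)\n",
              x$mating_system, x$error_rate))
  cat(sprintf("  n = %d offspring, %d loci, log-likelihood %.2f\n",
              x$n, x$n_loci, x$log_lik))
  cat(sprintf("  dyads: FS %d, HS %d, U %d\n",
              x$dyads["FS"], x$dyads["HS"], x$dyads["U"]))
  cat(sprintf("  Q1 = %.5f, Q2 = %.5f, Q3 = %.5f, alpha = %.4f\n",
              x$q$q1, x$q$q2, x$q$q3, x$alpha))
  cat(sprintf("  Nb (SA)   = %s\n  Nb (PwoP) = %s\n",
              format(round(unclass(x$nb_sa))),
              format(round(unclass(x$nb_pwop)))))
  invisible(x)
}

#' @rdname reconstruct_sibships
#' @export
coef.sibship_fit <- function(object, ...) {
  s <- summary(object)
  c(nb_sa = as.numeric(s$nb_sa), nb_pwop = as.numeric(s$nb_pwop))
}

#' @rdname reconstruct_sibships
#' @param ... further arguments (passed to plotting internals or ignored).
#' @export
plot.sibship_fit <- function(x, ...) {
  sizes <- as.integer(table(paste(x$partition$sire, x$partition$dam,
                                  sep = "\r")))
  barplot(table(factor(sizes, levels = seq_len(max(sizes)))),
          xlab = "inferred full-sib family size", ylab = "families",
          main = sprintf("Inferred family sizes (%s)",
                         x$config$mating_system), ...)
  invisible(x)
}
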