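#' Confusion matrix between true and inferred dyad labels
#'
#' Cross-tabulates every offspring pair's true relationship (full-sib,
#' half-sib, unrelated) against the inferred one, and totals the two error
#' types: type I (true unrelated pairs called full- or half-sib) and type
#' II (true related pairs called unrelated).
#'
#' @param true,inferred `dyad_labels` objects (see [label_dyads()],
#'   [classify_dyads()]) over the same individuals.
#' @return an object of class `dyad_confusion`: list with `table` (3x3
#'   counts, rows true, columns inferred), `percent` (row percentages),
#'   `type_I`, `type_II`, and `n`.
#' @export
confusion <- function(true, inferred) {
  stopifnot(inherits(true, "dyad_labels"), inherits(inferred, "dyad_labels"))
  if (!setequal(true$ids, inferred$ids) ||
      length(true$ids) != length(inferred$ids)) {
    stop("true and inferred dyad labels cover different individual sets")
  }
  inf_lab <- inferred$labels$label
  if (!identical(as.character(true$ids), as.character(inferred$ids))) {
    # realign inferred pairs to the true pair ordering
    pos <- match(true$ids, inferred$ids)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    inf_key <- key(inferred$labels$i, inferred$labels$j)
    want <- key(pos[true$labels$i], pos[true$labels$j])
    inf_lab <- inferred$labels$label[match(want, inf_key)]
  }
  tab <- table(true = true$labels$label, inferred = inf_lab)
  tab <- unclass(tab)[c("FS", "HS", "U"), c("FS", "HS", "U")]
  pct <- 100 * tab / pmax(rowSums(tab), 1)
  structure(list(
    table = tab, percent = pct,
    type_I = sum(tab["U", c("FS", "HS")]),
    type_II = sum(tab[c("FS", "HS"), "U"]),
    n = length(true$ids)
  ), class = "dyad_confusion")
}

#' @export
print.dyad_confusion <- function(x, ...) {
  cat(sprintf("Dyad confusion (%d individuals, %d pairs):\n",
              x$n, sum(x$table)))
  print(x$table)
  cat(sprintf("Type I (U -> sib): %d; type II (sib -> U): %d\n",
              x$type_I, x$type_II))
  invisible(x)
}

#' Percent root-mean-squared bias of Nb estimates
#'
#' `100 * sqrt(mean(((est - true) / true)^2))` over the finite estimates;
#' infinite estimates are excluded and counted (their count is returned in
#' the `excluded` attribute). When every estimate is infinite the result is
#' `NA`.
#'
#' @param estimates numeric vector of Nb estimates (`Inf` allowed).
#' @param true_nb the true Nb (positive).
#' @return percent RMSB (scalar, `NA` if no finite estimate), with
#'   attribute `excluded`.
#' @export
#' @examples
#' rmsb(c(110, 90), 100)  # 10
rmsb <- function(estimates, true_nb) {
  stopifnot(is.numeric(true_nb), length(true_nb) == 1, true_nb > 0)
  estimates <- as.numeric(estimates)
  fin <- estimates[is.finite(estimates)]
  excl <- length(estimates) - length(fin)
  if (!length(fin)) {
    return(structure(NA_real_, excluded = excl))
  }
  structure(100 * sqrt(mean(((fin - true_nb) / true_nb)^2)), excluded = excl)
}

#' Subsampling design
#'
#' The random-draw design used to probe how many offspring must be sampled
#' for accurate Nb estimation: fractions of the cohort from 10% to 90%,
#' several draws per fraction, each draw sampled without replacement and
#' all individuals replaced before the next draw. Draw sizes are
#' `floor(fraction * n)`.
#'
#' @param n cohort size.
#' @param fractions sampled fractions (default `seq(0.1, 0.9, by = 0.1)`).
#' @param replicates random draws per fraction (default 10, minimum 2).
#' @param seed seed governing all draws.
#' @return a list of class `subsample_design` with a `draws` data frame
#'   (fraction, draw size, replicate) and the settings.
#' @export
subsample_design <- function(n, fractions = seq(0.1, 0.9, by = 0.1),
                             replicates = 10L, seed = 1L) {
  stopifnot(n >= 2, all(fractions > 0), all(fractions <= 1),
            replicates >= 2)
  sizes <- as.integer(floor(fractions * n))
  draws <- data.frame(
    fraction = rep(fractions, each = replicates),
    draw_size = rep(sizes, each = replicates),
    replicate = rep(seq_len(replicates), length(fractions))
  )
  structure(list(n = as.integer(n), fractions = fractions,
                 draw_sizes = sizes, replicates = as.integer(replicates),
                 seed = as.integer(seed), draws = draws),
            class = "subsample_design")
}

#' Subsampling experiment: Nb accuracy versus sample size
#'
#' For each draw of the design, reconstructs sibships from the drawn
#' offspring's genotypes (monogamy with an assumed error rate of 0.01 by
#' default) and estimates Nb by the SA method (alpha estimated from the
#' draw) and by PwoP; per-fraction summaries report average bias, average
#' percent bias, absolute average percent bias, percent RMSB, the standard
#' deviation of estimates, and the number of infinite estimates excluded.
#'
#' @param genotypes full-cohort genotype matrix.
#' @param true_nb true Nb of the cohort (from the complete pedigree).
#' @param design a [subsample_design()].
#' @param recon a [recon_config()] (its seed is re-derived per draw).
#' @return a list of class `subsample_summary` with `runs` (one row per
#'   draw: estimates by both methods) and `summary` (one row per fraction,
#'   based on the SA estimates).
#' @export
subsample_experiment <- function(genotypes, true_nb,
                                 design = subsample_design(nrow(genotypes)),
                                 recon = recon_config()) {
  stopifnot(inherits(design, "subsample_design"))
  n <- nrow(genotypes)
  runs <- design$draws
  runs$nb_sa <- NA_real_
  runs$nb_pwop <- NA_real_
  keep <- runs$draw_size >= 2L
  if (any(!keep)) {
    warning("skipping fractions with draw size < 2: ",
            paste(unique(runs$fraction[!keep]), collapse = ", "))
  }
  for (r in which(keep)) {
    dseed <- derive_seed(design$seed,
                         paste0("draw", runs$fraction[r], "_", runs$replicate[r]))
    idx <- with_seed(dseed, sample.int(n, runs$draw_size[r]))
    g <- genotypes[idx, , drop = FALSE]
    cfg <- recon
    cfg$seed <- derive_seed(dseed, "recon")
    fit <- reconstruct_sibships(g, cfg)
    q <- sibship_frequencies(fit$partition)
    alpha <- estimate_alpha(g, fit$freqs)
    runs$nb_sa[r] <- as.numeric(sa_nb(q, alpha))
    runs$nb_pwop[r] <- as.numeric(pwop_nb_from_partition(fit$partition))
  }
  runs <- runs[keep, , drop = FALSE]
  smry <- do.call(rbind, lapply(split(runs, runs$fraction), function(d) {
    est <- d$nb_sa
    fin <- est[is.finite(est)]
    r <- rmsb(est, true_nb)
    data.frame(
      fraction = d$fraction[1], draw_size = d$draw_size[1],
      n_runs = nrow(d), n_infinite = sum(!is.finite(est)),
      avg_bias = if (length(fin)) mean(fin - true_nb) else NA_real_,
      avg_pct_bias = if (length(fin)) 100 * mean((fin - true_nb) / true_nb)
                     else NA_real_,
      abs_avg_pct_bias = if (length(fin))
        100 * mean(abs(fin - true_nb) / true_nb) else NA_real_,
      rmsb_pct = as.numeric(r),
      s = if (length(fin) > 1) sd(fin) else NA_real_
    )
  }))
  rownames(smry) <- NULL
  structure(list(runs = runs, summary = smry, true_nb = true_nb,
                 design = design),
            class = "subsample_summary")
}

#' @export
print.subsample_summary <- function(x, ...) {
  cat(sprintf("Subsampling experiment: true Nb = %.1f, %d runs\n",
              x$true_nb, nrow(x$runs)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.subsample_summary <- function(x, ...) {
  s <- x$summary
  fin <- x$runs[is.finite(x$runs$nb_sa), ]
  plot(fin$fraction, fin$nb_sa, xlab = "fraction of offspring sampled",
       ylab = "Nb estimate (SA)", main = "Nb vs sample fraction", ...)
  abline(h = x$true_nb, lty = 2)
  op <- par(new = TRUE)
  on.exit(par(op))
  plot(s$fraction, s$rmsb_pct, type = "l", col = "grey40", axes = FALSE,
       xlab = "", ylab = "")
  axis(4)
  mtext("percent RMSB", side = 4, line = 2)
  invisible(x)
}

#' SA versus PwoP concordance over a set of reconstruction runs
#'
#' For each run, computes Nb by the SA method (alpha estimated from the
#' run's genotypes) and by PwoP from the identical sibship partition, and
#' summarises the ratio SA/PwoP and the percent difference
#' `100 * |SA - PwoP| / PwoP`. Runs with an infinite PwoP estimate are
#' excluded and counted.
#'
#' @param runs a list whose elements are either `sibship_fit` objects or
#'   lists with elements `partition` and `genotypes`.
#' @return a list of class `concordance_summary` with per-run results, the
#'   maximum percent difference, a ratio histogram, and the excluded count.
#' @export
sa_pwop_concordance <- function(runs) {
  stopifnot(length(runs) >= 1)
  rows <- lapply(runs, function(r) {
    part <- r$partition
    g <- r$genotypes
    q <- sibship_frequencies(part)
    alpha <- if (is.null(g)) 0 else estimate_alpha(g)
    sa <- as.numeric(sa_nb(q, alpha))
    pw <- as.numeric(pwop_nb_from_partition(part))
    data.frame(n = length(part$offspring_id), alpha = alpha,
               nb_sa = sa, nb_pwop = pw,
               ratio = sa / pw,
               pct_diff = 100 * abs(sa - pw) / pw)
  })
  tab <- do.call(rbind, rows)
  excluded <- sum(!is.finite(tab$nb_pwop))
  ok <- tab[is.finite(tab$nb_pwop) & is.finite(tab$nb_sa), , drop = FALSE]
  h <- if (nrow(ok)) hist(ok$ratio, plot = FALSE) else NULL
  structure(list(runs = tab,
                 max_pct_diff = if (nrow(ok)) max(ok$pct_diff) else NA_real_,
                 histogram = h, n_excluded = excluded),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "SA vs PwoP concordance: %d runs (%d excluded), max %% difference %.3f\n",
    nrow(x$runs), x$n_excluded, x$max_pct_diff))
  invisible(x)
}

#' Full-cohort evaluation grid
#'
#' Runs sibship reconstruction for every combination of population, assumed
#' mating system, and assumed genotype error rate, producing a confusion
#' matrix against the true dyad labels and SA / PwoP Nb estimates per cell.
#'
#' @param genotypes a genotype matrix for one population, or a named list
#'   of matrices for several.
#' @param truth matching `dyad_labels` object (or named list of them).
#' @param mating_systems assumed mating systems to cross.
#' @param error_rates assumed genotype error rates to cross.
#' @param recon base [recon_config()]; mating system, error rate and seed
#'   are overridden per cell.
#' @param true_nb optional named vector of true Nb values, reported
#'   alongside the estimates.
#' @param dry_run if `TRUE`, return the schedule of cells without running
#'   anything.
#' @return a list of class `cohort_grid` with `schedule` (one row per
#'   cell) and, unless `dry_run`, `cells` (per-cell confusion + estimates).
#' @export
full_cohort_experiment <- function(genotypes, truth,
                                   mating_systems = c("monogamy",
                                                      "male_polygamy_female_monogamy",
                                                      "polygamy"),
                                   error_rates = c(1e-4, 1e-3, 1e-2),
                                   recon = recon_config(),
                                   true_nb = NULL,
                                   dry_run = FALSE) {
  if (!is.list(genotypes)) {
    genotypes <- list(population = genotypes)
    truth <- list(population = truth)
  }
  pops <- names(genotypes)
  schedule <- expand.grid(population = pops, mating_system = mating_systems,
                          error_rate = error_rates,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  if (dry_run) {
    return(structure(list(schedule = schedule, cells = NULL),
                     class = "cohort_grid"))
  }
  cells <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    pop <- schedule$population[i]
    cfg <- recon
    cfg$mating_system <- schedule$mating_system[i]
    cfg$error_rate <- schedule$error_rate[i]
    cfg$seed <- derive_seed(recon$seed, paste0("cell", i))
    fit <- reconstruct_sibships(genotypes[[pop]], cfg)
    cm <- confusion(truth[[pop]], classify_dyads(fit$partition))
    q <- sibship_frequencies(fit$partition)
    alpha <- estimate_alpha(genotypes[[pop]], fit$freqs)
    cells[[i]] <- list(
      population = pop,
      mating_system = schedule$mating_system[i],
      error_rate = schedule$error_rate[i],
      confusion = cm,
      nb_sa = as.numeric(sa_nb(q, alpha)),
      nb_pwop = as.numeric(pwop_nb_from_partition(fit$partition)),
      true_nb = if (!is.null(true_nb)) unname(true_nb[pop]) else NA_real_,
      log_lik = fit$log_lik)
  }
  structure(list(schedule = schedule, cells = cells), class = "cohort_grid")
}

#' @export
print.cohort_grid <- function(x, ...) {
  cat(sprintf("Evaluation grid: %d cells scheduled%s\n", nrow(x$schedule),
              if (is.null(x$cells)) " (dry run)" else ""))
  if (!is.null(x$cells)) {
    df <- do.call(rbind, lapply(x$cells, function(cl) {
      data.frame(population = cl$population,
                 mating_system = cl$mating_system,
                 error_rate = cl$error_rate,
                 nb_sa = round(cl$nb_sa), nb_pwop = round(cl$nb_pwop),
                 true_nb = cl$true_nb)
    }))
    print(df)
  }
  invisible(x)
}
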