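make_labels <- function(ids, sire, dam) {
  part <- sibship_partition(ids, sire, dam, "polygamy")
  classify_dyads(part)
}

test_that("confusion matrices tabulate agreement and both error types", {
  ids <- paste0("o", 1:6)
  truth <- make_labels(ids, c("s1", "s1", "s2", "s2", "s3", "s4"),
                       c("d1", "d1", "d2", "d3", "d4", "d5"))
  # perfect inference: diagonal, no errors
  cm <- confusion(truth, truth)
  expect_identical(cm$type_I, 0L)
  expect_identical(cm$type_II, 0L)
  expect_identical(sum(cm$table), as.integer(choose(6, 2)))
  expect_equal(as.numeric(diag(cm$table)), as.numeric(rowSums(cm$table)))
  # everything called unrelated: type II counts all true related pairs
  allu <- make_labels(ids, paste0("x", 1:6), paste0("y", 1:6))
  cm2 <- confusion(truth, allu)
  expect_identical(cm2$type_II,
                   as.integer(truth$counts["FS"] + truth$counts["HS"]))
  expect_identical(cm2$type_I, 0L)
  # row sums equal the true label counts
  expect_identical(unname(rowSums(cm2$table)), as.numeric(truth$counts))
})

test_that("confusion matches a brute-force pair tally on random labels", {
  set.seed(12)
  ids <- paste0("o", 1:12)
  truth <- make_labels(ids, sample(paste0("s", 1:5), 12, TRUE),
                       sample(paste0("d", 1:5), 12, TRUE))
  inf <- make_labels(ids, sample(paste0("s", 1:5), 12, TRUE),
                     sample(paste0("d", 1:5), 12, TRUE))
  cm <- confusion(truth, inf)
  tally <- matrix(0L, 3, 3, dimnames = list(c("FS", "HS", "U"),
                                            c("FS", "HS", "U")))
  for (k in seq_len(nrow(truth$labels))) {
    tally[as.character(truth$labels$label[k]),
          as.character(inf$labels$label[k])] <-
      tally[as.character(truth$labels$label[k]),
            as.character(inf$labels$label[k])] + 1L
  }
  expect_identical(unname(cm$table), unname(tally))
})

test_that("confusion realigns shuffled individual orderings", {
  ids <- paste0("o", 1:8)
  sire <- c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s5")
  dam <- c("d1", "d1", "d2", "d2", "d3", "d4", "d5", "d6")
  truth <- make_labels(ids, sire, dam)
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  inf <- make_labels(ids[perm], sire[perm], dam[perm])
  cm <- confusion(truth, inf)
  expect_equal(as.numeric(diag(cm$table)), as.numeric(truth$counts))
  expect_error(confusion(truth, make_labels(paste0("z", 1:8), sire, dam)),
               "different individual sets")
})

test_that("percent RMSB follows its definition and exclusion rules", {
  expect_equal(as.numeric(rmsb(c(110, 90), 100)), 10)
  expect_equal(as.numeric(rmsb(rep(123, 5), 123)), 0)
  r <- rmsb(c(Inf, 100), 100)
  expect_equal(as.numeric(r), 0)
  expect_identical(attr(r, "excluded"), 1L)
  r2 <- rmsb(c(Inf, Inf), 50)
  expect_true(is.na(r2))
  expect_identical(attr(r2, "excluded"), 2L)
  # RMSB dominates |mean percent bias| (Jensen)
  set.seed(2)
  for (rep in 1:10) {
    est <- runif(10, 50, 200)
    expect_gte(as.numeric(rmsb(est, 100)) + 1e-9,
               abs(100 * mean((est - 100) / 100)))
  }
})

test_that("draw sizes reproduce the published design tables", {
  sizes <- list(
    dworshak = c(151, 303, 454, 606, 758, 909, 1061, 1212, 1364),
    pahsimeroi = c(148, 296, 444, 592, 740, 888, 1036, 1184, 1332),
    sawtooth = c(73, 147, 221, 295, 369, 443, 517, 591, 665),
    oxbow = c(40, 80, 120, 160, 200, 240, 280, 320, 360),
    lyons_ferry = c(8, 16, 24, 32, 40, 48, 56, 64, 72))
  tbl <- hatchery_populations()
  for (pop in names(sizes)) {
    n <- tbl$n_offspring[tbl$population == pop]
    expect_identical(subsample_design(n)$draw_sizes, as.integer(sizes[[pop]]))
  }
  # 5 populations x 9 fractions x 10 replicates = 450 scheduled runs
  total <- sum(vapply(tbl$n_offspring,
                      function(n) nrow(subsample_design(n)$draws), numeric(1)))
  expect_equal(total, 450)
  expect_error(subsample_design(100, replicates = 1), "replicates")
})

test_that("the full-cohort grid schedules one run per design cell", {
  fake <- setNames(vector("list", 5), hatchery_populations()$population)
  grid <- full_cohort_experiment(fake, fake, dry_run = TRUE)
  expect_identical(nrow(grid$schedule), 45L)
  g1 <- full_cohort_experiment(fake[1], fake[1], mating_systems = "monogamy",
                               error_rates = 0.01, dry_run = TRUE)
  expect_identical(nrow(g1$schedule), 1L)
})

test_that("a one-cell grid produces a complete confusion matrix", {
  cc <- quick_cohort(seed = 51, n = 20, n_loci = 60)
  out <- full_cohort_experiment(cc$genotypes, label_dyads(cc$pedigree),
                                mating_systems = "monogamy",
                                error_rates = 0.01,
                                recon = recon_config(restarts = 2, seed = 6))
  expect_length(out$cells, 1L)
  expect_identical(sum(out$cells[[1]]$confusion$table),
                   as.integer(choose(20, 2)))
  # monogamy: the inferred-HS column is identically zero
  expect_equal(unname(out$cells[[1]]$confusion$table[, "HS"]), c(0, 0, 0))
})

test_that("subsampling experiment runs, summarises, and is reproducible", {
  cc <- quick_cohort(seed = 61, n = 60, n_loci = 95, theta = 0.5,
                     n_females = 35, n_males = 25)
  true_nb <- pwop_nb(ki_vector(cc$pedigree))
  des <- subsample_design(60, fractions = c(0.3, 0.6), replicates = 2,
                          seed = 5)
  rc <- recon_config(restarts = 2, seed = 1)
  out <- subsample_experiment(cc$genotypes, true_nb, des, rc)
  expect_identical(nrow(out$runs), 4L)
  expect_identical(out$summary$draw_size, c(18L, 36L))
  ok <- !is.na(out$summary$rmsb_pct)
  expect_true(all(out$summary$rmsb_pct[ok] + 1e-9 >=
                    abs(out$summary$avg_pct_bias[ok])))
  out2 <- subsample_experiment(cc$genotypes, true_nb, des, rc)
  expect_identical(out$runs, out2$runs)
  # fractions below two individuals are skipped with a warning
  des2 <- subsample_design(60, fractions = c(0.02, 0.5), replicates = 2)
  expect_warning(out3 <- subsample_experiment(cc$genotypes, true_nb, des2, rc),
                 "draw size")
  expect_identical(unique(out3$runs$fraction), 0.5)
})

test_that("SA/PwoP concordance reduces to the ratio identity", {
  # n = 100 in clusters of two, alpha forced to zero
  part <- sibship_partition(paste0("o", 1:100), paste0("s", rep(1:50, each = 2)),
                            paste0("d", rep(1:50, each = 2)), "monogamy")
  out <- sa_pwop_concordance(list(list(partition = part, genotypes = NULL)))
  expect_equal(out$runs$ratio, 2 * 99 / 199, tolerance = 1e-12)
  expect_identical(sum(out$histogram$counts), 1L)
  # truth partitions across synthetic cohorts stay within the 7% bound
  runs <- lapply(1:20, function(s) {
    cc <- quick_cohort(seed = 100 + s, n = 80 + 3 * s, n_loci = 5,
                       theta = 0.45, reuse = 0.05, contamination = 0.01,
                       n_females = 50 + 2 * s, n_males = 40 + s)
    list(partition = truth_partition(cc$pedigree), genotypes = NULL)
  })
  out2 <- sa_pwop_concordance(runs)
  expect_lte(out2$max_pct_diff, 7)
  # runs with infinite PwoP are excluded and counted
  singles <- sibship_partition(paste0("o", 1:10), paste0("s", 1:10),
                               paste0("d", 1:10), "monogamy")
  out3 <- sa_pwop_concordance(list(list(partition = singles, genotypes = NULL),
                                   list(partition = part, genotypes = NULL)))
  expect_identical(out3$n_excluded, 1L)
})
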