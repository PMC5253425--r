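test_that("allele frequency estimates count alleles and clamp", {
  g <- matrix(1L, 10, 3, dimnames = list(sprintf("i%d", 1:10), NULL))
  expect_equal(estimate_allele_freqs(g), rep(0.5, 3))
  g2 <- matrix(c(0L, 0L, 2L), 3, 1)
  expect_equal(estimate_allele_freqs(g2), 1 / 3)
  # monomorphic locus clamps away from 0
  g3 <- matrix(0L, 5, 1)
  expect_equal(estimate_allele_freqs(g3), 1 / 20)
  # a locus without at least two calls is an error naming the locus
  g4 <- cbind(L1 = c(0L, 1L), L2 = c(NA_integer_, NA_integer_))
  expect_error(estimate_allele_freqs(g4), "L2")
})

test_that("allele frequency estimator converges on large samples", {
  set.seed(5)
  p <- 0.3
  g <- matrix(rbinom(2000 * 10, 2, p), 2000, 10)
  se <- sqrt(p * (1 - p) / (2 * 2000))
  expect_true(all(abs(estimate_allele_freqs(g) - p) < 4 * se))
})

test_that("singleton cluster likelihood is the HW marginal with error folded in", {
  p <- 0.27; e <- 0.01
  g <- matrix(1L, 1, 1, dimnames = list("a", "L1"))
  part <- sibship_partition("a", "s", "d", "monogamy")
  ll <- config_log_likelihood(part, g, freqs = p, error_rate = e)
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pe <- c(e / 2, 1 - e, e / 2)  # P(obs = 1 | true t)
  expect_equal(as.numeric(ll), log(sum(hw * pe)), tolerance = 1e-12)
})

test_that("configuration likelihood matches full enumeration on small components", {
  set.seed(11)
  for (e in c(0, 0.01)) {
    for (rep in 1:4) {
      n <- 6; L <- 8
      freqs <- runif(L, 0.1, 0.5)
      geno <- matrix(rbinom(n * L, 2, rep(freqs, each = n)), n, L,
                     dimnames = list(letters[1:n], NULL))
      geno[sample(length(geno), 3)] <- NA
      # random partition with components of at most 4 parents
      sire <- c("s1", "s1", "s2", "s2", "s3", "s4")
      dam <- sample(c("d1", "d1", "d2", "d3", "d3", "d4"))
      part <- sibship_partition(letters[1:n], sire, dam, "polygamy")
      got <- config_log_likelihood(part, geno, freqs, error_rate = e)
      want <- oracle_partition_loglik(sire, dam, geno, freqs, e)
      expect_equal(as.numeric(got), want, tolerance = 1e-10)
    }
  }
})

test_that("polygamous star component matches the 27-term enumeration", {
  p <- 0.4; e <- 0.01
  g <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  part <- sibship_partition(c("a", "b", "c"), c("s", "s", "s"),
                            c("d1", "d1", "d2"), "polygamy")
  got <- config_log_likelihood(part, g, freqs = p, error_rate = e)
  want <- oracle_partition_loglik(c("s", "s", "s"), c("d1", "d1", "d2"),
                                  g, p, e)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
})

test_that("log-likelihood is monotone non-increasing in the number of loci", {
  cc <- quick_cohort(seed = 3, n = 10, n_loci = 30)
  part <- truth_partition(cc$pedigree)
  lls <- sapply(c(5, 10, 20, 30), function(k) {
    config_log_likelihood(part, cc$genotypes[, 1:k, drop = FALSE],
                          freqs = attr(cc$genotypes, "freqs")[1:k],
                          error_rate = 0.01)
  })
  expect_true(all(diff(lls) < 0))
})

test_that("missing genotypes are marginalised out (weight one)", {
  p <- c(0.3, 0.4)
  g <- matrix(c(0L, 2L, NA, NA), 2, 2, dimnames = list(c("a", "b"), NULL))
  part <- sibship_partition(c("a", "b"), c("s", "s"), c("d", "d"), "monogamy")
  ll2 <- config_log_likelihood(part, g, freqs = p, error_rate = 0.01)
  ll1 <- config_log_likelihood(part, g[, 1, drop = FALSE], freqs = p[1],
                               error_rate = 0.01)
  expect_equal(as.numeric(ll2), as.numeric(ll1), tolerance = 1e-12)
})

test_that("a positive assumed error rate keeps every configuration possible", {
  # opposite homozygotes forced into one full-sib family: only double-het
  # parents can explain them, so the error-free probability is small but
  # finite, and any e > 0 keeps all merges finite too
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), NULL))
  part <- sibship_partition(c("a", "b"), c("s", "s"), c("d", "d"), "monogamy")
  ll <- config_log_likelihood(part, g, freqs = 0.5, error_rate = 0.001)
  expect_true(is.finite(ll))
  p <- 0.5
  hw_het <- 2 * p * (1 - p)
  # e = 0 closed form: both offspring need one allele of each kind, every
  # parent pair contributes P(0|.) * P(2|.)
  want <- log(sum(outer(c((1 - p)^2, hw_het, p^2), c((1 - p)^2, hw_het, p^2)) *
                    outer(0:2, 0:2, function(a, b) {
                      (1 - a / 2) * (1 - b / 2) * (a / 2) * (b / 2)
                    })))
  expect_equal(as.numeric(config_log_likelihood(part, g, freqs = p,
                                                error_rate = 0)),
               want, tolerance = 1e-12)
})

test_that("compiled monogamy likelihood agrees with the R implementation", {
  cc <- quick_cohort(seed = 12, n = 30, n_loci = 95)
  g <- cc$genotypes
  freqs <- estimate_allele_freqs(g)
  set.seed(30)
  for (rep in 1:3) {
    cl <- sample(1:12, nrow(g), replace = TRUE)
    part <- sibship_partition(rownames(g), paste0("S", cl), paste0("D", cl),
                              "monogamy")
    llR <- config_log_likelihood(part, g, freqs, error_rate = 0.01)
    codes <- g; codes[is.na(codes)] <- 3L; storage.mode(codes) <- "integer"
    llC <- sibnb:::.partition_loglik_mono_cpp(
      codes, sibnb:::pair_weight_table(0.01),
      sibnb:::pair_prior_matrix(freqs), cl)
    expect_equal(as.numeric(llR), llC, tolerance = 1e-10)
  }
})

test_that("over-cap components are approximated, flagged, and never overrated", {
  # a chain of 7 dams sharing one sire: 8 parents, cap of 4 forces the
  # mean-field path, which must lower-bound the exact sum
  set.seed(44)
  n <- 7; L <- 20
  freqs <- runif(L, 0.2, 0.5)
  geno <- matrix(rbinom(n * L, 2, rep(freqs, each = n)), n, L,
                 dimnames = list(letters[1:n], NULL))
  part <- sibship_partition(letters[1:n], rep("s", n), paste0("d", 1:n),
                            "polygamy")
  exact <- config_log_likelihood(part, geno, freqs, error_rate = 0.01,
                                 max_component_parents = 12)
  expect_warning(
    approx <- config_log_likelihood(part, geno, freqs, error_rate = 0.01,
                                    max_component_parents = 4),
    "approximated")
  expect_identical(attr(approx, "approximated_components"), 1L)
  expect_lte(as.numeric(approx), as.numeric(exact) + 1e-6)
  expect_gt(as.numeric(approx), as.numeric(exact) - 20)
  expect_error(config_log_likelihood(part, geno, freqs, error_rate = 0.01,
                                     max_component_parents = 4,
                                     approx = FALSE),
               "exceeds")
})
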