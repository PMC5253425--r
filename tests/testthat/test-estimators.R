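test_that("alpha hits the heterozygote excess/deficit extremes", {
  # every individual heterozygous at p = 0.5: alpha = -1
  g_all_het <- matrix(1L, 20, 4)
  expect_equal(estimate_alpha(g_all_het), -1)
  # no heterozygotes at p = 0.5: alpha = +1
  g_no_het <- matrix(rep(c(0L, 2L), each = 10), 20, 4)
  expect_equal(estimate_alpha(g_no_het), 1)
  expect_error(estimate_alpha(matrix(integer(0), 0, 0)), "monomorphic")
})

test_that("alpha is near zero under Hardy-Weinberg", {
  set.seed(3)
  p <- runif(95, 0.1, 0.5)
  g <- matrix(rbinom(500 * 95, 2, rep(p, each = 500)), 500, 95)
  expect_lt(abs(estimate_alpha(g)), 0.02)
})

test_that("sibship frequencies match cluster combinatorics and the pair scan", {
  n <- 5
  singles <- sibship_partition(paste0("o", 1:n), paste0("s", 1:n),
                               paste0("d", 1:n), "monogamy")
  q0 <- sibship_frequencies(singles)
  expect_equal(c(q0$q1, q0$q2, q0$q3), c(0, 0, 0))
  # monogamy clusters {3, 2}: Q3 = (3 + 1) / 10
  part <- sibship_partition(paste0("o", 1:5), c("a", "a", "a", "b", "b"),
                            c("x", "x", "x", "y", "y"), "monogamy")
  q <- sibship_frequencies(part)
  expect_equal(q$q3, 0.4)
  expect_equal(q$q1 + q$q2, 0)
  set.seed(8)
  for (rep in 1:5) {
    sire <- sample(paste0("s", 1:4), 12, replace = TRUE)
    dam <- sample(paste0("d", 1:5), 12, replace = TRUE)
    p <- sibship_partition(paste0("o", 1:12), sire, dam, "polygamy")
    qq <- sibship_frequencies(p)
    oc <- oracle_dyad_counts(sire, dam)
    # oracle splits HS by which parent is shared
    fs <- 0L; q1 <- 0L; q2 <- 0L
    for (i in 1:11) for (j in (i + 1):12) {
      ss <- sire[i] == sire[j]; sd <- dam[i] == dam[j]
      if (ss && sd) fs <- fs + 1L
      else if (ss) q1 <- q1 + 1L
      else if (sd) q2 <- q2 + 1L
    }
    expect_equal(qq$q3, fs / 66)
    expect_equal(qq$q1, q1 / 66)
    expect_equal(qq$q2, q2 / 66)
    expect_identical(unname(oc["FS"]), fs)
  }
})

test_that("SA estimator closed forms and monotonicity", {
  expect_equal(as.numeric(sa_nb(list(q1 = 0, q2 = 0, q3 = 0.01))), 200)
  expect_equal(as.numeric(sa_nb(list(q1 = 0.01, q2 = 0.01, q3 = 0))), 200)
  expect_identical(as.numeric(sa_nb(list(q1 = 0, q2 = 0, q3 = 0))), Inf)
  # monotone decreasing in each Q at alpha = 0
  base <- as.numeric(sa_nb(list(q1 = 0.01, q2 = 0.01, q3 = 0.01)))
  for (which in 1:3) {
    q <- list(q1 = 0.01, q2 = 0.01, q3 = 0.01)
    q[[which]] <- 0.02
    expect_lt(as.numeric(sa_nb(q)), base)
  }
  expect_error(sa_nb(list(q1 = -0.1, q2 = 0, q3 = 0)), "invalid")
})

test_that("ki from partitions counts latent-parent offspring", {
  part <- sibship_partition(paste0("o", 1:4), c("s1", "s1", "s2", "s2"),
                            c("d1", "d1", "d2", "d2"), "monogamy")
  ki <- ki_from_partition(part)
  expect_identical(sort(as.integer(ki)), rep(2L, 4))
  expect_identical(sum(ki), 8L)
  # sire shared by two dams with 2 and 1 offspring
  p2 <- sibship_partition(paste0("o", 1:3), rep("s", 3), c("d1", "d1", "d2"),
                          "male_polygamy_female_monogamy")
  ki2 <- ki_from_partition(p2)
  expect_identical(unname(ki2[c("S\rs", "D\rd1", "D\rd2")]), c(3L, 2L, 1L))
  set.seed(14)
  for (rep in 1:4) {
    n <- sample(5:20, 1)
    part <- sibship_partition(paste0("o", 1:n),
                              sample(paste0("s", 1:4), n, replace = TRUE),
                              sample(paste0("d", 1:4), n, replace = TRUE),
                              "polygamy")
    expect_identical(sum(ki_from_partition(part)), 2L * n)
  }
})

test_that("PwoP from partitions matches closed forms and the true pedigree", {
  part <- sibship_partition(paste0("o", 1:4), c("s1", "s1", "s2", "s2"),
                            c("d1", "d1", "d2", "d2"), "monogamy")
  expect_equal(as.numeric(pwop_nb_from_partition(part)), 7)
  singles <- sibship_partition(paste0("o", 1:10), paste0("s", 1:10),
                               paste0("d", 1:10), "monogamy")
  expect_identical(as.numeric(pwop_nb_from_partition(singles)), Inf)
  # identity with the pedigree-truth code path
  cc <- quick_cohort(seed = 37, n = 40, n_loci = 5, reuse = 0.2,
                     contamination = 0.1, theta = 0.5, n_females = 22,
                     n_males = 14)
  expect_equal(as.numeric(pwop_nb_from_partition(truth_partition(cc$pedigree))),
               pwop_nb(ki_vector(cc$pedigree)))
})

test_that("monogamy SA/PwoP ratio identity holds exactly", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:120, 1)
    # random monogamous clustering
    k <- sample(1:6, n, replace = TRUE)
    cl <- rep(seq_along(k), k)[1:n]
    part <- sibship_partition(paste0("o", 1:n), paste0("s", cl),
                              paste0("d", cl), "monogamy")
    sa <- as.numeric(sa_nb(sibship_frequencies(part), alpha = 0))
    pw <- as.numeric(pwop_nb_from_partition(part))
    cs <- table(cl)
    denom <- sum(cs * (cs - 1))
    if (denom == 0) {
      expect_identical(sa, Inf)
      expect_identical(pw, Inf)
    } else {
      expect_equal(sa, 2 * n * (n - 1) / denom, tolerance = 1e-10)
      expect_equal(pw, n * (2 * n - 1) / denom, tolerance = 1e-10)
      expect_equal(sa / pw, 2 * (n - 1) / (2 * n - 1), tolerance = 1e-10)
      # consequence: within 7% whenever n >= 8
      expect_lt(100 * abs(sa - pw) / pw, 7)
    }
  }
})

test_that("BestCluster files round-trip and validate", {
  part <- sibship_partition(c("o1", "o2", "o3", "o4"),
                            c("F1", "F1", "F2", "F2"),
                            c("M1", "M1", "M2", "M2"), "monogamy")
  path <- withr::local_tempfile(fileext = ".BestCluster")
  write_best_cluster(part, path)
  back <- read_best_cluster(path)
  expect_identical(classify_dyads(back)$counts, classify_dyads(part)$counts)
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile()
  write_best_cluster(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # fixture with two clusters
  fix <- withr::local_tempfile()
  writeLines(c("ClusterIndex ClusterProbability OffspringID FatherID MotherID",
               "1 0.98 kidA  *1 #1",
               "1 0.98 kidB  *1 #1",
               "2 1.00 kidC  *2 #2",
               "2 1.00 kidD  *2 #2"), fix)
  p <- read_best_cluster(fix)
  expect_identical(unname(classify_dyads(p)$counts), c(2L, 0L, 4L))

  # shared FatherID across clusters implies half-sib dyads
  fix2 <- withr::local_tempfile()
  writeLines(c("1 1.0 a *1 #1", "1 1.0 b *1 #1", "2 1.0 c *1 #2"), fix2)
  p2 <- read_best_cluster(fix2)
  expect_gt(classify_dyads(p2)$counts["HS"], 0)

  # duplicate offspring and short rows are errors
  dup <- withr::local_tempfile()
  writeLines(c("1 1.0 a *1 #1", "2 1.0 a *2 #2"), dup)
  expect_error(read_best_cluster(dup), "duplicate")
  short <- withr::local_tempfile()
  writeLines(c("1 1.0 a *1 #1", "2 1.0 b"), short)
  expect_error(read_best_cluster(short), "line 2")
})
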