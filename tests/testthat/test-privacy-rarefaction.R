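test_that("presence matrix thresholds read counts correctly", {
  m <- matrix(c(0L, 5L, 3L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("i1", "i2")))
  pm <- build_presence_matrix(m)
  expect_equal(unname(pm), matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                                  byrow = TRUE), ignore_attr = TRUE)
  expect_equal(attr(pm, "min_reads"), 1L)

  one <- matrix(1L, 1, 1, dimnames = list("c", "i"))
  expect_true(build_presence_matrix(one, min_reads = 1)[1, 1])
  expect_false(build_presence_matrix(one, min_reads = 2)[1, 1])

  dup <- matrix(0L, 2, 2, dimnames = list(c("c", "c"), c("i1", "i2")))
  expect_error(build_presence_matrix(dup), "duplicate contig")
  neg <- matrix(-1L, 1, 1, dimnames = list("c", "i"))
  expect_error(build_presence_matrix(neg), "non-negative")
})

test_that("noiseless planted Y locus has support 1 at every level", {
  coh <- simulate_cohort(3, 3, 30, 1, dropout_prob = 0, seed = 4)
  pr <- privacy_rarefaction(build_presence_matrix(coh), coh$sexes,
                            n_boot = 50, seed = 1)
  y <- coh$truth$y_loci
  expect_equal(unname(pr$support_male[y, ]), rep(1, 3))
  for (s in pr$levels) {
    expect_true(all(pr$counts_male[[s]] == 1))
    expect_true(all(pr$counts_female[[s]] == 0))
  }
})

test_that("supports match exhaustive enumeration on the 2M+2F toy case", {
  # locus X present in both males and one of two females: at s = 1 it is
  # male-private in the 2 of 4 draws picking the absent female; at s = 2
  # never
  P <- matrix(c(1, 1, 1, 0,
                1, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("X", "auto"),
                              c("M01", "M02", "F01", "F02")))
  reg <- make_toy_registry(2, 2)
  ex <- privacy_rarefaction(build_presence_matrix(P), reg,
                            method = "exhaustive")
  expect_equal(ex$support_male["X", 1], 0.5)
  expect_equal(ex$support_male["X", 2], 0)
  expect_equal(ex$support_male["auto", 1], 0)

  orc <- oracle_privacy_support(P > 0, c("M01", "M02"), c("F01", "F02"), 1)
  expect_equal(ex$support_male[, 1], orc$male)
  expect_equal(ex$support_female[, 1], orc$female)
})

test_that("exhaustive mode equals the independent enumeration oracle", {
  coh <- simulate_cohort(4, 4, 60, 2, dropout_prob = 0.25, seed = 13)
  pm <- build_presence_matrix(coh)
  ex <- privacy_rarefaction(pm, coh$sexes, method = "exhaustive")
  ids_m <- coh$sexes$individual_id[coh$sexes$sex == "M"]
  ids_f <- coh$sexes$individual_id[coh$sexes$sex == "F"]
  for (s in 1:4) {
    orc <- oracle_privacy_support(unclass(pm), ids_m, ids_f, s)
    expect_equal(ex$support_male[, s], orc$male)
    expect_equal(ex$support_female[, s], orc$female)
  }
})

test_that("Monte-Carlo supports converge to exhaustive supports", {
  coh <- simulate_cohort(4, 4, 80, 2, dropout_prob = 0.2, seed = 3)
  pm <- build_presence_matrix(coh)
  ex <- privacy_rarefaction(pm, coh$sexes, method = "exhaustive")
  mc <- privacy_rarefaction(pm, coh$sexes, n_boot = 2000, seed = 17)
  for (s in 1:4) {
    p <- ex$support_male[, s]
    se <- sqrt(p * (1 - p) / 2000)
    expect_true(all(abs(mc$support_male[, s] - p) <= 3 * se + 1e-12))
  }
})

test_that("scan is deterministic, label-invariant and sex-swap symmetric", {
  coh <- simulate_cohort(5, 5, 100, 2, dropout_prob = 0.2, seed = 7)
  pm <- build_presence_matrix(coh)
  pr1 <- privacy_rarefaction(pm, coh$sexes, n_boot = 40, seed = 11)
  pr2 <- privacy_rarefaction(pm, coh$sexes, n_boot = 40, seed = 11)
  expect_identical(pr1$support_male, pr2$support_male)
  expect_identical(pr1$counts_female, pr2$counts_female)

  # permuting contigs and individuals (registry permuted identically)
  set.seed(1)
  cp <- sample(nrow(coh$counts)); ip <- sample(ncol(coh$counts))
  pm_p <- build_presence_matrix(coh$counts[cp, ip])
  pr_p <- privacy_rarefaction(pm_p, coh$sexes[order(ip), ],
                              n_boot = 40, seed = 11)
  expect_identical(pr_p$support_male[rownames(pm), ], pr1$support_male)
  expect_identical(pr_p$counts_male, pr1$counts_male)

  # swapping all sex labels swaps the outputs exactly
  swapped <- coh$sexes
  swapped$sex <- ifelse(swapped$sex == "M", "F", "M")
  pr_s <- privacy_rarefaction(pm, swapped, n_boot = 40, seed = 11)
  expect_identical(pr_s$support_male, pr1$support_female)
  expect_identical(pr_s$support_female, pr1$support_male)
  expect_identical(pr_s$counts_male, pr1$counts_female)
})

test_that("male- and female-private sets are disjoint within any draw", {
  # a contig private to both sexes at once is impossible by construction;
  # verified on a noisy scan by checking no contig has support > 0 for both
  # sexes at the same level with full-cohort stringency
  coh <- simulate_cohort(4, 4, 200, 0, dropout_prob = 0.3, seed = 19)
  pr <- privacy_rarefaction(build_presence_matrix(coh), coh$sexes,
                            method = "exhaustive")
  s <- max(pr$levels)
  expect_true(all(!(pr$support_male[, s] > 0 & pr$support_female[, s] > 0)))
  for (s in pr$levels) {
    expect_true(all(pr$counts_male[[s]] >= 0))
    expect_true(all(pr$support_male[, s] >= 0 & pr$support_male[, s] <= 1))
  }
})

test_that("null scans show symmetric, decreasing candidate curves", {
  # no sex-linked loci: male and female mean counts both shrink with
  # stringency and are statistically indistinguishable (paired sign test)
  diffs <- t(vapply(1:50, function(sd) {
    coh <- simulate_cohort(10, 10, 200, 0, dropout_prob = 0.2, seed = sd)
    pr <- privacy_rarefaction(build_presence_matrix(coh), coh$sexes,
                              n_boot = 30, seed = sd + 500,
                              max_stringency = 6)
    m <- pr$summary$mean_male; f <- pr$summary$mean_female
    c(mono_m = all(diff(m) <= 0), mono_f = all(diff(f) <= 0),
      d2 = m[2] - f[2], d3 = m[3] - f[3])
  }, numeric(4)))
  # monotone decrease in the large majority of individual scans
  expect_gte(mean(diffs[, "mono_m"]), 0.9)
  expect_gte(mean(diffs[, "mono_f"]), 0.9)
  for (col in c("d2", "d3")) {
    d <- diffs[, col]
    d <- d[d != 0]
    if (length(d) > 5) {
      p <- oracle_binom_p(sum(d > 0), length(d), 0.5)
      expect_gt(p, 0.01)
    }
  }
})

test_that("candidate retention applies the support and stringency rule", {
  coh <- simulate_cohort(5, 5, 50, 1, dropout_prob = 0, seed = 2)
  pr <- privacy_rarefaction(build_presence_matrix(coh), coh$sexes,
                            n_boot = 100, seed = 3)
  cand <- candidate_contigs(pr, min_support = 0.5, min_stringency = 3)
  expect_equal(cand$contig_id, coh$truth$y_loci)
  expect_equal(cand$sex, "M")
  expect_equal(cand$passed_levels[[1]], 3:5)

  # support just under the threshold, or only below min_stringency, is out
  fake <- pr
  fake$support_male[] <- 0
  fake$support_male[1, ] <- 0.49
  fake$support_female[] <- 0
  expect_equal(nrow(candidate_contigs(fake)), 0)
  fake$support_male[1, ] <- c(1, 0.6, 0, 0, 0)
  expect_equal(nrow(candidate_contigs(fake, min_stringency = 3)), 0)
  expect_equal(nrow(candidate_contigs(fake, min_stringency = 2)), 1)
})

test_that("heterogamety classification separates XY, ZW and null", {
  xy <- simulate_cohort(10, 10, 300, 4, dropout_prob = 0.1, seed = 8)
  pr_xy <- privacy_rarefaction(build_presence_matrix(xy), xy$sexes,
                               n_boot = 100, max_stringency = 5, seed = 1)
  expect_equal(classify_heterogamety(pr_xy)$label, "XY-like")

  zw <- simulate_cohort(10, 10, 300, 0, n_w_loci = 4, dropout_prob = 0.1,
                        seed = 8)
  pr_zw <- privacy_rarefaction(build_presence_matrix(zw), zw$sexes,
                               n_boot = 100, max_stringency = 5, seed = 1)
  expect_equal(classify_heterogamety(pr_zw)$label, "ZW-like")

  nul <- simulate_cohort(10, 10, 200, 0, dropout_prob = 0.2, seed = 8)
  pr_n <- privacy_rarefaction(build_presence_matrix(nul), nul$sexes,
                              n_boot = 100, seed = 1)
  expect_equal(classify_heterogamety(pr_n)$label, "none")

  short <- privacy_rarefaction(build_presence_matrix(nul), nul$sexes,
                               n_boot = 10, max_stringency = 2, seed = 1)
  expect_error(classify_heterogamety(short), "3 stringency")
})

test_that("incidence report reproduces published marker incidences", {
  expect_equal(attr(incidence_report(5.29, 94968), "formatted"), "0.0056%")
  expect_equal(attr(incidence_report(0.59, 38830), "formatted"), "0.0015%")
  expect_equal(as.numeric(incidence_report(0, 1000)), 0)

  coh <- simulate_cohort(3, 3, 40, 1, dropout_prob = 0, seed = 2)
  pr <- privacy_rarefaction(build_presence_matrix(coh), coh$sexes,
                            n_boot = 20, seed = 1)
  # exactly one male-private candidate among 40 contigs -> 2.5%
  expect_equal(as.numeric(incidence_report(pr, 40)), 2.5)
  expect_error(incidence_report(pr, 0), "positive")
})

test_that("scan rejects invalid stringency and registries", {
  coh <- simulate_cohort(3, 3, 20, 1, dropout_prob = 0, seed = 1)
  pm <- build_presence_matrix(coh)
  expect_error(privacy_rarefaction(pm, coh$sexes, max_stringency = 4),
               "exceeds")
  reg <- coh$sexes[-1, ]
  expect_error(privacy_rarefaction(pm, reg), "missing from the sex registry")
  allm <- coh$sexes; allm$sex <- "M"
  expect_error(privacy_rarefaction(pm, allm), "at least one male")
})
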