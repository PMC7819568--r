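test_that("allele frequencies count homozygotes twice and skip missing", {
  tbl <- table_from_genotypes(list(S1 = c("10/10", "10/12")), rl = 1L)
  fr <- allele_frequencies(tbl)
  expect_equal(fr$by_site$L01["S1", "10"], 0.75)
  expect_equal(fr$by_site$L01["S1", "12"], 0.25)
  expect_equal(unname(fr$n["S1", 1]), 2L)
})

test_that("pooled frequencies equal the n-weighted mean of site frequencies", {
  tbl <- random_table(n = 30, L = 3, sites = c("A", "B", "C"),
                      missing_frac = 0.1, seed = 9)
  fr <- allele_frequencies(tbl)
  for (l in seq_len(3)) {
    n_s <- fr$n[, l]
    pooled <- colSums(fr$by_site[[l]] * n_s) / sum(n_s)
    expect_equal(unname(pooled), unname(fr$pooled[[l]]), tolerance = 1e-12)
  }
})

test_that("all-missing site-locus cells are flagged with empty frequencies", {
  a1 <- matrix(c(20L, NA), 2, 1); a2 <- matrix(c(22L, NA), 2, 1)
  tbl <- genotype_table(c("x", "y"), dinuc_loci(1), a1, a2, c("S1", "S2"))
  fr <- allele_frequencies(tbl)
  expect_true("L01@S2" %in% fr$flags)
  expect_equal(unname(fr$n["S2", 1]), 0L)
})

test_that("diversity statistics match hand computation and limits", {
  # genotype counts AA=30, AB=40, BB=30 at one site
  genos <- c(rep("10/10", 30), rep("10/12", 40), rep("12/12", 30))
  tbl <- table_from_genotypes(list(S1 = genos), rl = 1L)
  d <- diversity_stats(tbl)
  expect_equal(d$per_cell$Ho, 0.4)
  expect_equal(d$per_cell$He, (200 / 199) * 0.5, tolerance = 1e-12)
  expect_equal(d$per_cell$F_IS, 1 - 0.4 / ((200 / 199) * 0.5),
               tolerance = 1e-12)

  # monomorphic locus: Ho = He = 0, F_IS undefined
  mono <- table_from_genotypes(list(S1 = rep("10/10", 5)), rl = 1L)
  dm <- diversity_stats(mono)
  expect_equal(dm$per_cell$Ho, 0)
  expect_equal(dm$per_cell$He, 0)
  expect_true(is.na(dm$per_cell$F_IS))

  # all heterozygous A/B at p = 0.5: Ho = 1, He -> 0.5, F_IS -> -1
  het <- table_from_genotypes(list(S1 = rep("10/12", 100)), rl = 1L)
  dh <- diversity_stats(het)
  expect_equal(dh$per_cell$Ho, 1)
  expect_equal(dh$per_cell$He, (200 / 199) * 0.5, tolerance = 1e-12)
  expect_lt(abs(dh$per_cell$F_IS - (1 - 1 / 0.5)), 0.02)
})

test_that("HWE exact enumeration matches the pairing-enumeration oracle", {
  cases <- list(
    # AB=3 is the modal table: every table is in the tail, p = 1
    c("1/1", "1/2", "1/2", "1/2", "2/2"),
    # heterozygote deficit: AA=2, AB=1, BB=2
    c("1/1", "1/1", "1/2", "2/2", "2/2"),
    # heterozygote excess
    c("1/2", "1/2", "1/2", "1/2", "1/1"),
    # three alleles, n = 6
    c("1/2", "1/3", "2/3", "1/1", "2/2", "3/3"),
    c("1/1", "1/1", "2/2", "3/3", "2/3", "1/2"))
  for (genos in cases) {
    tbl <- table_from_genotypes(list(S1 = genos), rl = 1L)
    res <- hwe_exact_test(tbl, "L01")
    expect_identical(res$method, "enumeration")
    p_or <- oracle_hwe_p(tbl$allele1[, 1], tbl$allele2[, 1])
    expect_equal(res$p, p_or, tolerance = 1e-10,
                 label = paste(genos, collapse = " "))
  }
  # the het-deficit case genuinely discriminates (p < 1)
  tbl_def <- table_from_genotypes(
    list(S1 = c("1/1", "1/1", "1/2", "2/2", "2/2")), rl = 1L)
  expect_lt(hwe_exact_test(tbl_def, "L01")$p, 1)
})

test_that("HWE Monte Carlo agrees with the pairing oracle within 3 MC SEs", {
  # four alleles forces the Monte Carlo path; oracle enumerates pairings
  tbl <- table_from_genotypes(list(S1 = c("1/1", "2/2", "3/4", "1/2",
                                          "3/3", "4/4")), rl = 1L)
  res <- hwe_exact_test(tbl, "L01", n_mc = 20000, seed = 5)
  expect_identical(res$method, "monte_carlo")
  p_or <- oracle_hwe_p(tbl$allele1[, 1], tbl$allele2[, 1])
  expect_gt(p_or, 0); expect_lt(p_or, 1)
  se <- sqrt(p_or * (1 - p_or) / 20000)
  expect_lt(abs(res$p - p_or), 3 * se + 1e-4)
})

test_that("HWE degenerate cases and Bonferroni helper", {
  mono <- table_from_genotypes(list(S1 = rep("10/10", 4)), rl = 1L)
  expect_equal(hwe_exact_test(mono, "L01")$p, 1)
  expect_equal(bonferroni(c(0.01, 0.4), 3), c(0.03, 1))
})

test_that("linkage test finds perfect association and respects the p grid", {
  set.seed(31)
  az <- sample(10:14, 60, TRUE); bz <- sample(10:14, 60, TRUE)
  a1 <- cbind(az, az); a2 <- cbind(bz, bz)   # locus 2 copies locus 1
  tbl <- genotype_table(sprintf("i%02d", 1:60), dinuc_loci(2), a1, a2,
                        rep("S1", 60))
  res <- ld_test(tbl, c("L01", "L02"), n_perm = 99, seed = 2)
  expect_equal(res$p, 1 / 100)              # minimal attainable on k/100 grid
  expect_true(all(abs(res$p * 100 - round(res$p * 100)) < 1e-9))

  # insufficient data path
  small <- random_table(n = 5, L = 2, seed = 3)
  expect_identical(ld_test(small, c("L01", "L02"))$method, "not_tested")
})

test_that("private alleles are counted only for single-site alleles", {
  tbl <- table_from_genotypes(list(
    S1 = c("10/12", "10/14"),                # 14 private to S1
    S2 = c("10/12", "12/16"),                # 16 private to S2
    S3 = c("10/18", "18/20")), rl = 1L)      # 18, 20 private to S3
  pa <- private_alleles(allele_frequencies(tbl))
  expect_equal(unname(pa), c(1L, 1L, 2L))
  expect_equal(sum(pa), 4L)
})

test_that("G_ST closed forms: fixed alternate alleles and identical sites", {
  fixed <- table_from_genotypes(list(S1 = rep("10/10", 10),
                                     S2 = rep("12/12", 10)), rl = 1L)
  for (corr in c(TRUE, FALSE)) {
    g <- global_differentiation(fixed, corrected = corr)
    expect_equal(g$Gst, 1, tolerance = 1e-12)
    expect_equal(g$Gst_prime, 1, tolerance = 1e-12)
  }
  same <- table_from_genotypes(list(
    S1 = c(rep("10/10", 4), rep("10/12", 2), rep("12/12", 4)),
    S2 = c(rep("10/10", 4), rep("10/12", 2), rep("12/12", 4))), rl = 1L)
  gu <- global_differentiation(same, corrected = FALSE)
  expect_equal(gu$Gst, 0, tolerance = 1e-12)
  expect_equal(gu$Gst_prime, 0, tolerance = 1e-12)
})

test_that("uncorrected two-site example: Hs=0.32, Ht=0.5, G'ST=0.6988...", {
  # frequencies (0.8, 0.2) and (0.2, 0.8), 10 individuals each
  tbl <- table_from_genotypes(list(
    S1 = c(rep("10/10", 6), rep("10/12", 4)),       # p(10) = 0.8
    S2 = c(rep("12/12", 6), rep("10/12", 4))), rl = 1L)
  g <- global_differentiation(tbl, corrected = FALSE)
  expect_equal(g$Hs, 0.32, tolerance = 1e-12)
  expect_equal(g$Ht, 0.5, tolerance = 1e-12)
  expect_equal(g$Gst, 0.36, tolerance = 1e-12)
  expect_equal(g$Gst_prime, 0.36 * (1 + 0.32) / (1 * (1 - 0.32)),
               tolerance = 1e-12)
})

test_that("G'ST >= G_ST for two sites and invariance under relabeling", {
  tbl <- random_table(n = 24, L = 4, sites = c("A", "B"), seed = 11)
  g <- global_differentiation(tbl, corrected = FALSE)
  expect_gte(g$Gst_prime, g$Gst - 1e-12)

  # relabel alleles (shift sizes) and sites: multilocus G_ST unchanged
  tbl2 <- tbl
  tbl2$allele1 <- tbl$allele1 + 100L
  tbl2$allele2 <- tbl$allele2 + 100L
  tbl2$site <- setNames(c(A = "zz", B = "aa")[tbl$site], names(tbl$site))
  g2 <- global_differentiation(tbl2, corrected = FALSE)
  expect_equal(g2$Gst, g$Gst, tolerance = 1e-12)
})

test_that("pairwise differentiation is consistent with the global code", {
  tbl <- random_table(n = 36, L = 4, sites = c("A", "B", "C"), seed = 13)
  pw <- pairwise_differentiation(tbl, n_boot = 49, seed = 1)
  expect_equal(unname(diag(pw$fst)), rep(0, 3))
  expect_equal(pw$fst, t(pw$fst))
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    keep <- tbl$site %in% pr
    sub <- genotype_table(tbl$ids[keep], tbl$loci,
                          tbl$allele1[keep, , drop = FALSE],
                          tbl$allele2[keep, , drop = FALSE],
                          tbl$site[keep])
    g <- global_differentiation(sub)
    expect_equal(pw$fst[pr[1], pr[2]], g$Fst, tolerance = 1e-12)
    expect_equal(pw$gst_prime[pr[1], pr[2]], g$Gst_prime, tolerance = 1e-12)
  }
})

test_that("a site split at random against itself is not significant", {
  set.seed(21)
  tbl <- random_table(n = 40, L = 6, sites = "X", seed = 17)
  tbl$site <- setNames(sample(rep(c("X1", "X2"), each = 20)), tbl$ids)
  pw <- pairwise_differentiation(tbl, n_boot = 499, seed = 3)
  expect_false(pw$pairs$gstp_sig_boot[1])
  expect_lt(abs(pw$pairs$Gst_prime[1]), 0.1)
})
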