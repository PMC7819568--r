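# random-mating genotype table with individuals placed at given sites
panmictic_table <- function(n, L, sites, seed, n_alleles = 5) {
  set.seed(seed)
  alleles <- seq(10, by = 1, length.out = n_alleles)
  a1 <- matrix(sample(alleles, n * L, TRUE), n, L)
  a2 <- matrix(sample(alleles, n * L, TRUE), n, L)
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  genotype_table(sprintf("i%03d", seq_len(n)), dinuc_loci(L, 1L), lo, hi,
                 rep_len(sites, n))
}

test_that("Loiselle kinship is symmetric and matches the formula oracle", {
  tbl <- table_from_genotypes(list(S = c("10/12", "10/10", "12/14",
                                         "10/14")), rl = 1L)
  k <- loiselle_kinship(tbl)
  expect_equal(k$F, t(k$F))
  for (pr in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    expect_equal(unname(k$F[pr[1], pr[2]]),
                 unname(oracle_loiselle(tbl, pr)), tolerance = 1e-12)
  }
  # multi-locus case with missing data
  tbl2 <- random_table(n = 6, L = 3, sites = "S", missing_frac = 0.2,
                       seed = 3)
  k2 <- loiselle_kinship(tbl2)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(unname(k2$F[i, j]),
                 unname(oracle_loiselle(tbl2, c(i, j))), tolerance = 1e-12)
  }
})

test_that("the pair-average kinship is near zero in a panmictic sample", {
  # self-referenced kinship has a known O(1/n) offset; the pair average
  # must sit at zero within that order plus Monte Carlo error
  n <- 100
  means <- vapply(1:20, function(r) {
    tbl <- panmictic_table(n, 5, "S", seed = 100 + r)
    k <- loiselle_kinship(tbl)
    mean(k$F[upper.tri(k$F)])
  }, numeric(1))
  expect_lt(abs(mean(means)), 1 / n + 3 * sd(means) / sqrt(20))
})

test_that("distance classes follow the (lo, hi] convention with a far class", {
  ids <- sprintf("i%03d", 1:8)
  sites <- c("A", "A", "B", "B", "C", "C", "D", "D")
  tbl <- panmictic_table(8, 3, sites, seed = 7)
  # A-B 300 m, A-C 900 m, A-D 25 km
  mperdeg <- pi / 180 * 6371008.8
  sdf <- data.frame(site_id = c("A", "B", "C", "D"),
                    longitude = c(0, 300, 900, 25000) / mperdeg,
                    latitude = 0)
  coords <- individual_coords(tbl, sdf)
  br <- bin_autocorrelation(loiselle_kinship(tbl), coords)
  tab <- br$table
  # same-site pairs (distance 0) are in the within-site row AND class 1
  expect_equal(tab$n_pairs[tab$bin == "within_site"], 4)
  expect_equal(tab$n_pairs[tab$bin == "0-250m"], 4)
  # 300 m pairs fall in (250, 500]
  expect_equal(tab$n_pairs[tab$bin == "250-500m"], 4)
  # 600 m pairs (B-C) in (500, 750]; 900 m pairs (A-C) in (750, 1000]
  expect_equal(tab$n_pairs[tab$bin == "500-750m"], 4)
  expect_equal(tab$n_pairs[tab$bin == "750-1000m"], 4)
  # beyond 1 km everything pools into the far class
  expect_equal(tab$n_pairs[tab$bin == "25km"], 12)
  # classes partition all eligible pairs
  expect_equal(sum(tab$n_pairs[tab$bin != "within_site"]), choose(8, 2))
})

test_that("bin means are invariant to individual ordering", {
  tbl <- panmictic_table(20, 4, c("A", "B"), seed = 9)
  sdf <- line_sites(c("A", "B"), dx = 400)
  br <- bin_autocorrelation(loiselle_kinship(tbl),
                            individual_coords(tbl, sdf))
  perm <- sample(20)
  tblp <- genotype_table(tbl$ids[perm], tbl$loci, tbl$allele1[perm, ],
                         tbl$allele2[perm, ], tbl$site[perm])
  brp <- bin_autocorrelation(loiselle_kinship(tblp),
                             individual_coords(tblp, sdf))
  expect_equal(brp$table$mean_Fij, br$table$mean_Fij, tolerance = 1e-12)
})

test_that("jackknife SE: zero for duplicated loci, closed form at L = 2", {
  base <- panmictic_table(15, 1, c("A", "B"), seed = 12)
  # four identical copies of one locus -> every leave-one-out is identical
  dup <- genotype_table(base$ids, dinuc_loci(4, 1L),
                        base$allele1[, c(1, 1, 1, 1)],
                        base$allele2[, c(1, 1, 1, 1)], base$site)
  sdf <- line_sites(c("A", "B"), dx = 400)
  br <- bin_autocorrelation(loiselle_kinship(dup),
                            individual_coords(dup, sdf))
  se <- jackknife_se(br)
  expect_true(all(abs(se[!is.na(se)]) < 1e-12))

  two <- panmictic_table(15, 2, c("A", "B"), seed = 13)
  br2 <- bin_autocorrelation(loiselle_kinship(two),
                             individual_coords(two, sdf))
  se2 <- jackknife_se(br2)
  # delete-one estimates by hand
  for (bcol in seq_along(se2)) {
    th <- vapply(1:2, function(drop) {
      keep <- setdiff(1:2, drop)
      sub <- genotype_table(two$ids, two$loci[keep, , drop = FALSE],
                            two$allele1[, keep, drop = FALSE],
                            two$allele2[, keep, drop = FALSE], two$site)
      bs <- bin_autocorrelation(loiselle_kinship(sub),
                                individual_coords(sub, sdf))
      bs$table$mean_Fij[bcol]
    }, numeric(1))
    if (!anyNA(th)) expect_equal(se2[bcol], abs(th[1] - th[2]) / 2,
                                 tolerance = 1e-10)
  }

  one <- panmictic_table(15, 1, c("A", "B"), seed = 14)
  br1 <- bin_autocorrelation(loiselle_kinship(one),
                             individual_coords(one, sdf))
  expect_warning(se1 <- jackknife_se(br1), "2 informative loci")
  expect_true(all(is.na(se1)))
})

test_that("permutation envelopes are reproducible and centered on the null", {
  tbl <- panmictic_table(30, 4, c("A", "B", "C"), seed = 16)
  sdf <- line_sites(c("A", "B", "C"), dx = 400)
  br <- bin_autocorrelation(loiselle_kinship(tbl),
                            individual_coords(tbl, sdf))
  e1 <- permutation_envelope(br, n_perm = 199, seed = 8)
  e2 <- permutation_envelope(br, n_perm = 199, seed = 8)
  expect_identical(e1$ci_lo, e2$ci_lo)
  expect_identical(e1$p, e2$p)
  # null bin means center on the global pair average
  k <- loiselle_kinship(tbl)
  overall <- mean(k$F[upper.tri(k$F)], na.rm = TRUE)
  ok <- !is.na(e1$ci_lo)
  expect_true(any(ok))
  expect_true(all(e1$ci_lo[ok] - 1e-9 <= overall &
                    overall <= e1$ci_hi[ok] + 1e-9))
})

test_that("strong simulated philopatry lifts short-distance kinship above the envelope", {
  fx_cfg <- sim_config(n_regions = 4, n_transect_regions = 2,
                       deme_size = 40, n_loci = 8, n_generations = 60,
                       philopatry = 1, n_sample_per_site = 10,
                       raster_rows = 30, raster_cols = 30,
                       cell_size_m = 210, block_cells = 5, seed = 99)
  raster <- generate_landscape(fx_cfg)
  surf <- reclassify(raster, default_class_groups(), hypothesis_set()$B)
  sim <- simulate_genotypes(fx_cfg, surf)
  res <- kinship_autocorrelation(sim$table,
                                 individual_coords(sim$table, sim$sites),
                                 n_perm = 499, seed = 3)
  b1 <- res[res$bin == "0-250m", ]
  far <- res[res$bin == "25km", ]
  expect_gt(b1$mean_Fij, far$mean_Fij)
  expect_gt(b1$mean_Fij, b1$ci_hi)
})
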