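#' Allele frequencies by site and pooled
#'
#' Counts each allele twice per homozygote and once per heterozygote;
#' missing genotypes do not contribute to the sample size `n`.
#'
#' @param table a `genotype_table`.
#' @return object of class `allele_freqs`: for every locus, a
#'   `sites x alleles` frequency matrix (`by_site`), the pooled frequency
#'   vector over all genotyped individuals (`pooled`), and the `sites x loci`
#'   matrix `n` of genotyped individuals. Site-locus cells with zero
#'   genotyped individuals are flagged in `$flags`.
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  sites <- unique(table$site)
  sf <- factor(table$site, levels = sites)
  L <- n_loci(table)
  by_site <- vector("list", L); pooled <- vector("list", L)
  nmat <- matrix(0L, length(sites), L, dimnames = list(sites, table$loci$name))
  flags <- character(0)
  for (l in seq_len(L)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    ok <- !is.na(a1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    af <- factor(c(a1[ok], a2[ok]), levels = alleles)
    gf <- rep(sf[ok], 2L)
    cnt <- table(gf, af)                     # sites x alleles gene counts
    n_s <- as.vector(table(sf[ok]))
    nmat[, l] <- n_s
    fr <- matrix(0, length(sites), length(alleles),
                 dimnames = list(sites, as.character(alleles)))
    nz <- n_s > 0
    fr[nz, ] <- unclass(cnt)[nz, , drop = FALSE] / (2 * n_s[nz])
    by_site[[l]] <- fr
    tot <- colSums(unclass(cnt))
    pooled[[l]] <- if (sum(tot) > 0) tot / sum(tot) else numeric(0)
    if (any(!nz)) {
      flags <- c(flags, paste0(table$loci$name[l], "@", sites[!nz]))
    }
  }
  names(by_site) <- names(pooled) <- table$loci$name
  structure(list(by_site = by_site, pooled = pooled, n = nmat,
                 sites = sites, flags = flags),
            class = "allele_freqs")
}

#' Per-site, per-locus diversity and inbreeding statistics
#'
#' Observed heterozygosity `Ho` is the fraction of heterozygotes among
#' genotyped individuals; expected heterozygosity `He` uses the unbiased
#' small-sample estimator `(2n/(2n-1)) (1 - sum p^2)`; the inbreeding
#' coefficient is `F_IS = 1 - Ho/He`, undefined (NA) at monomorphic cells.
#'
#' @param table a `genotype_table`.
#' @return list with `per_cell` (data frame site x locus: n, Ho, He, F_IS,
#'   n_alleles), `per_site` and `per_locus` means, and two labelled overall
#'   F_IS aggregates: `fis_mean_cells` (mean over all site-locus cells) and
#'   `fis_mean_site_means` (mean over loci within site, then over sites).
#' @export
diversity_stats <- function(table) {
  fr <- allele_frequencies(table)
  sites <- fr$sites
  rows <- list(); r <- 0L
  sf <- factor(table$site, levels = sites)
  for (l in seq_len(n_loci(table))) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    for (s in seq_along(sites)) {
      in_s <- sf == sites[s] & !is.na(a1)
      n <- sum(in_s)
      p <- fr$by_site[[l]][s, ]
      ho <- if (n > 0) mean(a1[in_s] != a2[in_s]) else NA_real_
      he <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
      fis <- if (!is.na(he) && he > 0) 1 - ho / he else NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(site = sites[s], locus = table$loci$name[l],
                              n = n, Ho = ho, He = he, F_IS = fis,
                              n_alleles = sum(p > 0), stringsAsFactors = FALSE)
    }
  }
  per_cell <- do.call(rbind, rows)
  agg <- function(f, by) {
    stats::aggregate(per_cell[c("Ho", "He", "F_IS")], by = per_cell[by],
                     FUN = function(x) mean(x, na.rm = TRUE))
  }
  per_site <- agg(mean, "site"); per_locus <- agg(mean, "locus")
  list(per_cell = per_cell, per_site = per_site, per_locus = per_locus,
       fis_mean_cells = mean(per_cell$F_IS, na.rm = TRUE),
       fis_mean_site_means = mean(per_site$F_IS, na.rm = TRUE))
}

#' Private alleles per site
#'
#' An allele is private to a site if it is observed there and at no other
#' site (over all genotyped individuals, any locus).
#'
#' @param freqs an `allele_freqs` object (needs >= 2 sites).
#' @return named integer vector: number of private alleles per site.
#' @export
private_alleles <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  if (length(freqs$sites) < 2) stop("private alleles need >= 2 sites")
  out <- stats::setNames(integer(length(freqs$sites)), freqs$sites)
  for (fr in freqs$by_site) {
    present <- fr > 0
    priv <- colSums(present) == 1L
    if (any(priv)) {
      carrier <- apply(present[, priv, drop = FALSE], 2, which)
      tab <- table(factor(freqs$sites[carrier], levels = freqs$sites))
      out <- out + as.integer(tab)
    }
  }
  out
}

## ---- Hardy-Weinberg exact test -------------------------------------------

# log conditional probability (Levene) of a genotype-count table given
# allele counts: P = n! 2^H prod(c_a!) / (prod n_ab! (2n)!)
hwe_log_prob <- function(het, hom, allele_counts) {
  n <- sum(het) + sum(hom)
  H <- sum(het)
  lgamma(n + 1) + H * log(2) + sum(lgamma(allele_counts + 1)) -
    (sum(lgamma(het + 1)) + sum(lgamma(hom + 1)) + lgamma(2 * n + 1))
}

# enumerate all genotype tables compatible with allele counts c (k <= 3)
hwe_enumerate <- function(counts) {
  k <- length(counts)
  stopifnot(k <= 3)
  out <- list(); r <- 0L
  if (k == 1) {
    return(list(list(het = integer(0), hom = counts / 2,
                     lp = 0)))
  }
  if (k == 2) {
    for (h12 in seq(counts[1] %% 2, min(counts), by = 2)) {
      hom <- (counts - h12) / 2
      r <- r + 1L
      out[[r]] <- list(het = h12, hom = hom,
                       lp = hwe_log_prob(h12, hom, counts))
    }
    return(out)
  }
  for (h12 in 0:min(counts[1], counts[2])) {
    for (h13 in 0:min(counts[1] - h12, counts[3])) {
      if ((counts[1] - h12 - h13) %% 2 != 0) next
      for (h23 in 0:min(counts[2] - h12, counts[3] - h13)) {
        if ((counts[2] - h12 - h23) %% 2 != 0) next
        if ((counts[3] - h13 - h23) %% 2 != 0) next
        het <- c(h12, h13, h23)
        hom <- (counts - c(h12 + h13, h12 + h23, h13 + h23)) / 2
        r <- r + 1L
        out[[r]] <- list(het = het, hom = hom,
                         lp = hwe_log_prob(het, hom, counts))
      }
    }
  }
  out
}

genotype_counts_at <- function(table, locus, site = NULL) {
  l <- match(locus, table$loci$name)
  if (is.na(l)) stop("unknown locus: ", locus)
  keep <- if (is.null(site)) rep(TRUE, n_individuals(table)) else table$site == site
  a1 <- table$allele1[keep, l]; a2 <- table$allele2[keep, l]
  ok <- !is.na(a1)
  list(a1 = a1[ok], a2 = a2[ok])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype array given the allele counts,
#' ordering tables by their conditional (Levene) probability: the p-value is
#' the total probability of tables no more probable than the observed one
#' (ties included in the tail). Full enumeration is used when the locus has
#' at most 3 alleles and at most 30 genotyped individuals; otherwise a Monte
#' Carlo version shuffles the gene array `n_mc` times and applies the
#' add-one correction `p = (1 + #(P_sim <= P_obs)) / (n_mc + 1)`.
#'
#' @param table a `genotype_table`.
#' @param locus locus name.
#' @param site optional site id to restrict to (default: all individuals).
#' @param n_mc Monte Carlo shuffles (>= 1000) when enumeration is not used.
#' @param seed integer seed for the Monte Carlo path.
#' @return list: `p`, `method` ("enumeration", "monte_carlo" or "none"),
#'   `n`, `n_alleles`.
#' @export
hwe_exact_test <- function(table, locus, site = NULL, n_mc = 10000, seed = 1) {
  g <- genotype_counts_at(table, locus, site)
  n <- length(g$a1)
  if (n < 2) stop("need >= 2 genotyped individuals for the HWE test")
  alleles <- sort(unique(c(g$a1, g$a2)))
  k <- length(alleles)
  if (k < 2) {
    return(list(p = 1, method = "none", n = n, n_alleles = k))
  }
  i1 <- match(g$a1, alleles); i2 <- match(g$a2, alleles)
  allele_counts <- tabulate(c(i1, i2), k)
  het_idx <- function(i, j) ifelse(i < j, paste(i, j), paste(j, i))
  obs_het <- integer(k * (k - 1) / 2); obs_hom <- integer(k)
  pair_id <- 0L
  het_map <- matrix(0L, k, k)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    pair_id <- pair_id + 1L
    het_map[a, b] <- het_map[b, a] <- pair_id
  }
  for (ind in seq_len(n)) {
    if (i1[ind] == i2[ind]) obs_hom[i1[ind]] <- obs_hom[i1[ind]] + 1L
    else {
      id <- het_map[i1[ind], i2[ind]]
      obs_het[id] <- obs_het[id] + 1L
    }
  }
  lp_obs <- hwe_log_prob(obs_het, obs_hom, allele_counts)
  tol <- 1e-9
  if (k <= 3 && n <= 30) {
    tabs <- hwe_enumerate(allele_counts)
    lps <- vapply(tabs, `[[`, numeric(1), "lp")
    p <- sum(exp(lps[lps <= lp_obs + tol]))
    p <- min(1, p)
    return(list(p = p, method = "enumeration", n = n, n_alleles = k))
  }
  stopifnot(n_mc >= 1000)
  genes <- c(i1, i2)
  hits <- 0L
  with_seed(seed, {
    for (m in seq_len(n_mc)) {
      sh <- sample(genes)
      s1 <- sh[seq_len(n)]; s2 <- sh[n + seq_len(n)]
      hom <- tabulate(s1[s1 == s2], k)
      het <- tabulate(het_map[cbind(s1[s1 != s2], s2[s1 != s2])],
                      k * (k - 1) / 2)
      if (hwe_log_prob(het, hom, allele_counts) <= lp_obs + tol) {
        hits <- hits + 1L
      }
    }
  })
  list(p = (1 + hits) / (n_mc + 1), method = "monte_carlo",
       n = n, n_alleles = k)
}

#' Bonferroni correction
#' @param p raw p-values. @param m number of tests (default `length(p)`).
#' @return corrected p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

## ---- Linkage disequilibrium ----------------------------------------------

allele_dosage <- function(a1, a2) {
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  d <- matrix(NA_real_, length(a1), length(alleles),
              dimnames = list(NULL, as.character(alleles)))
  d[ok, ] <- (outer(a1[ok], alleles, "==") + outer(a2[ok], alleles, "=="))
  d
}

ld_statistic <- function(X, Y) {
  # composite genotypic association: sum of squared covariances between
  # allele dosages at the two loci
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sum((crossprod(Xc, Yc) / (nrow(X) - 1))^2)
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Statistic: the sum over allele pairs of the squared covariance between
#' allele dosages at the two loci (a composite genotypic association
#' measure that needs no phase information). The null distribution is built
#' by permuting one locus's genotype column across individuals.
#'
#' @param table a `genotype_table`.
#' @param locus_pair character vector of two locus names.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `p`, `statistic`, `n` (individuals complete at both loci),
#'   or `method = "not_tested"` when fewer than 10 complete pairs or a
#'   monomorphic locus.
#' @export
ld_test <- function(table, locus_pair, n_perm = 999, seed = 1) {
  stopifnot(length(locus_pair) == 2)
  l1 <- match(locus_pair[1], table$loci$name)
  l2 <- match(locus_pair[2], table$loci$name)
  if (anyNA(c(l1, l2))) stop("unknown locus in pair")
  ok <- !is.na(table$allele1[, l1]) & !is.na(table$allele1[, l2])
  if (sum(ok) < 10) {
    return(list(p = NA_real_, statistic = NA_real_, n = sum(ok),
                method = "not_tested", reason = "fewer than 10 complete pairs"))
  }
  X <- allele_dosage(table$allele1[ok, l1], table$allele2[ok, l1])
  Y <- allele_dosage(table$allele1[ok, l2], table$allele2[ok, l2])
  if (ncol(X) < 2 || ncol(Y) < 2) {
    return(list(p = NA_real_, statistic = NA_real_, n = sum(ok),
                method = "not_tested", reason = "monomorphic locus"))
  }
  obs <- ld_statistic(X, Y)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (ld_statistic(X, Y[sample(nrow(Y)), , drop = FALSE]) >= obs) {
        hits <- hits + 1L
      }
    }
  })
  list(p = (1 + hits) / (n_perm + 1), statistic = obs, n = sum(ok),
       method = "permutation")
}

## ---- Differentiation (G_ST family) ---------------------------------------

# Per-locus H_S, H_T and sample sizes for a site factor.
# corrected = TRUE applies the Nei & Chesser (1983) small-sample estimators
# (harmonic-mean sample size; the dialect used by GenAlEx/mmod):
#   Hs_est = Hs * 2ñ/(2ñ-1);  Ht_est = Ht + Hs_est/(2 ñ k)
# with Hs the unweighted mean over sites of 1 - sum p^2 and Ht computed from
# the unweighted mean allele frequencies.
locus_hs_ht <- function(a1, a2, sf, corrected = TRUE) {
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  cnt <- table(rep(sf[ok], 2L), factor(c(a1[ok], a2[ok]), levels = alleles))
  n_s <- as.vector(table(sf[ok]))
  use <- n_s > 0
  k <- sum(use)
  if (k < 2 || length(alleles) < 1) {
    return(list(Hs = NA_real_, Ht = NA_real_, k = k))
  }
  p <- unclass(cnt)[use, , drop = FALSE] / (2 * n_s[use])
  Hs <- mean(1 - rowSums(p^2))
  pbar <- colMeans(p)
  Ht <- 1 - sum(pbar^2)
  if (corrected) {
    n_harm <- k / sum(1 / n_s[use])
    Hs <- Hs * (2 * n_harm) / (2 * n_harm - 1)
    Ht <- Ht + Hs / (2 * n_harm * k)
  }
  list(Hs = Hs, Ht = Ht, k = k)
}

gst_from_components <- function(Hs, Ht, k) {
  keep <- !is.na(Hs) & !is.na(Ht) & Ht > 0
  if (!any(keep)) stop("no locus with H_T > 0")
  Hs <- Hs[keep]; Ht <- Ht[keep]
  per_gst <- (Ht - Hs) / Ht
  hedrick <- function(gst, hs, kk) {
    gst * (kk - 1 + hs) / ((kk - 1) * (1 - hs))
  }
  per_gstp <- hedrick(per_gst, Hs, k)
  Hs_ml <- mean(Hs); Ht_ml <- mean(Ht)
  gst_ml <- (Ht_ml - Hs_ml) / Ht_ml           # ratio of sums == ratio of means
  list(per_locus = data.frame(Hs = Hs, Ht = Ht, Gst = per_gst,
                              Gst_prime = per_gstp),
       Hs = Hs_ml, Ht = Ht_ml, Gst = gst_ml,
       Gst_prime = hedrick(gst_ml, Hs_ml, k),
       skipped = sum(!keep))
}

#' Global differentiation: F_ST (Nei G_ST) and Hedrick's G'ST
#'
#' Per locus, `H_S` is the mean within-site expected heterozygosity and
#' `H_T` the expected heterozygosity of the mean allele frequencies;
#' `G_ST = (H_T - H_S)/H_T` and the standardized
#' `G'ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))` for `k` sites. The
#' multilocus value is the ratio of sums over loci, then standardized. By
#' default the Nei & Chesser (1983) small-sample corrections are applied
#' (matching GenAlEx); `corrected = FALSE` gives the textbook Nei (1973)
#' estimators.
#'
#' @param table a `genotype_table` with >= 2 sites.
#' @param corrected apply small-sample corrections (default TRUE).
#' @return list of class `fst_result`: multilocus `Fst` (= G_ST), `Gst`,
#'   `Gst_prime`, component `Hs`, `Ht`, `k`, and a per-locus data frame.
#' @export
global_differentiation <- function(table, corrected = TRUE) {
  sites <- unique(table$site)
  if (length(sites) < 2) stop("differentiation needs >= 2 sites")
  sf <- factor(table$site, levels = sites)
  L <- n_loci(table)
  Hs <- Ht <- numeric(L)
  for (l in seq_len(L)) {
    comp <- locus_hs_ht(table$allele1[, l], table$allele2[, l], sf, corrected)
    Hs[l] <- comp$Hs; Ht[l] <- comp$Ht
  }
  res <- gst_from_components(Hs, Ht, length(sites))
  res$per_locus <- cbind(locus = table$loci$name[!is.na(Hs) & !is.na(Ht) & Ht > 0],
                         res$per_locus)
  res$Fst <- res$Gst
  res$k <- length(sites)
  res$corrected <- corrected
  class(res) <- "fst_result"
  res
}

#' Pairwise differentiation between sites with resampling significance
#'
#' For every pair of sites, multilocus F_ST (Nei G_ST) and Hedrick's G'ST
#' are computed as in [global_differentiation()] with `k = 2`. Two
#' significance measures are reported, because "bootstrapping over loci"
#' and "permutation" are different procedures: (i) a percentile 95% CI from
#' resampling loci with replacement `n_boot` times (significant when the CI
#' excludes 0), and (ii) when `n_perm > 0`, a permutation p-value from
#' shuffling individuals between the two sites. Negative G'ST estimates are
#' reported as computed (interpret as 0); they are never truncated.
#'
#' @param table a `genotype_table`.
#' @param n_boot locus bootstrap replicates (>= 999 recommended).
#' @param n_perm individual-permutation replicates (0 disables).
#' @param seed integer seed.
#' @param corrected small-sample corrections as in [global_differentiation()].
#' @return list of class `pairwise_fst`: matrices `fst` and `gst_prime`
#'   (symmetric, zero diagonal), and data frame `pairs` with CI bounds,
#'   permutation p, and a `low_n` flag for pairs where a site has < 2
#'   individuals.
#' @export
pairwise_differentiation <- function(table, n_boot = 999, n_perm = 0,
                                     seed = 1, corrected = TRUE) {
  sites <- unique(table$site)
  s <- length(sites)
  if (s < 2) stop("need >= 2 sites")
  stopifnot(n_boot >= 1)
  L <- n_loci(table)
  fst <- gstp <- matrix(0, s, s, dimnames = list(sites, sites))
  rows <- list(); r <- 0L
  with_seed(seed, {
    for (i in 1:(s - 1)) for (j in (i + 1):s) {
      keep <- table$site %in% sites[c(i, j)]
      sf <- factor(table$site[keep], levels = sites[c(i, j)])
      a1 <- table$allele1[keep, , drop = FALSE]
      a2 <- table$allele2[keep, , drop = FALSE]
      Hs <- Ht <- numeric(L)
      for (l in seq_len(L)) {
        comp <- locus_hs_ht(a1[, l], a2[, l], sf, corrected)
        Hs[l] <- comp$Hs; Ht[l] <- comp$Ht
      }
      est <- gst_from_components(Hs, Ht, 2)
      fst[i, j] <- fst[j, i] <- est$Gst
      gstp[i, j] <- gstp[j, i] <- est$Gst_prime
      usable <- which(!is.na(Hs) & !is.na(Ht) & Ht > 0)
      boot <- matrix(NA_real_, n_boot, 2)
      for (b in seq_len(n_boot)) {
        bl <- sample(usable, length(usable), replace = TRUE)
        be <- gst_from_components(Hs[bl], Ht[bl], 2)
        boot[b, ] <- c(be$Gst, be$Gst_prime)
      }
      ci_f <- stats::quantile(boot[, 1], c(0.025, 0.975), names = FALSE)
      ci_g <- stats::quantile(boot[, 2], c(0.025, 0.975), names = FALSE)
      p_f <- p_g <- NA_real_
      if (n_perm > 0) {
        hits_f <- hits_g <- 0L
        for (b in seq_len(n_perm)) {
          psf <- sample(sf)
          pHs <- pHt <- numeric(L)
          for (l in seq_len(L)) {
            comp <- locus_hs_ht(a1[, l], a2[, l], psf, corrected)
            pHs[l] <- comp$Hs; pHt[l] <- comp$Ht
          }
          pe <- gst_from_components(pHs, pHt, 2)
          if (pe$Gst >= est$Gst) hits_f <- hits_f + 1L
          if (pe$Gst_prime >= est$Gst_prime) hits_g <- hits_g + 1L
        }
        p_f <- (1 + hits_f) / (n_perm + 1)
        p_g <- (1 + hits_g) / (n_perm + 1)
      }
      n_i <- sum(table$site == sites[i]); n_j <- sum(table$site == sites[j])
      r <- r + 1L
      rows[[r]] <- data.frame(
        site1 = sites[i], site2 = sites[j], n1 = n_i, n2 = n_j,
        Fst = est$Gst, Gst_prime = est$Gst_prime,
        fst_ci_lo = ci_f[1], fst_ci_hi = ci_f[2],
        gstp_ci_lo = ci_g[1], gstp_ci_hi = ci_g[2],
        fst_sig_boot = ci_f[1] > 0, gstp_sig_boot = ci_g[1] > 0,
        p_fst_perm = p_f, p_gstp_perm = p_g,
        low_n = n_i < 2 || n_j < 2,
        gstp_note = ifelse(est$Gst_prime < 0, "interpret as 0", ""),
        stringsAsFactors = FALSE)
    }
  })
  structure(list(fst = fst, gst_prime = gstp, pairs = do.call(rbind, rows),
                 n_boot = n_boot, n_perm = n_perm, seed = seed),
            class = "pairwise_fst")
}
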