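#' Pairwise Loiselle kinship coefficients
#'
#' For individuals i, j:
#' `F_ij = sum_l sum_a [ (p_ila - pbar_la)(p_jla - pbar_la) + c_la ] /
#'         sum_l sum_a pbar_la (1 - pbar_la)`
#' where `p_ila` in \{0, 1/2, 1\} is i's allelic state, `pbar_la` the allele
#' frequency pooled over all genotyped individuals at locus l (the whole
#' filtered dataset is the reference), and
#' `c_la = pbar_la (1 - pbar_la) / (n_l - 1)` the small-sample bias term
#' with `n_l` genotyped individuals at locus l. Loci missing in either
#' individual are excluded from both sums for that pair.
#'
#' @param table a `genotype_table` with >= 2 individuals.
#' @param bias_n_minus_1 use `1/(n_l - 1)` for the bias term (default); the
#'   literature also has a `1/(2 n_l - 1)` dialect, available with FALSE.
#' @return object of class `kinship_matrix`: `F` (symmetric matrix, NA
#'   diagonal, NA for pairs with no shared polymorphic locus), plus the
#'   per-locus numerator array and denominators needed for jackknifing.
#' @export
loiselle_kinship <- function(table, bias_n_minus_1 = TRUE) {
  n <- n_individuals(table); L <- n_loci(table)
  if (n < 2) stop("kinship needs >= 2 individuals")
  num <- array(0, c(n, n, L))
  shared <- array(FALSE, c(n, n, L))
  den <- numeric(L)
  for (l in seq_len(L)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    ok <- !is.na(a1)
    n_l <- sum(ok)
    if (n_l < 2) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2) next             # monomorphic: contributes 0
    pbar <- (colSums(outer(a1[ok], alleles, "==")) +
             colSums(outer(a2[ok], alleles, "=="))) / (2 * n_l)
    P <- (outer(a1, alleles, "==") + outer(a2, alleles, "==")) / 2
    P[!ok, ] <- 0
    C <- sweep(P, 2, pbar)
    C[!ok, ] <- 0
    m <- tcrossprod(C)
    denom_bias <- if (bias_n_minus_1) n_l - 1 else 2 * n_l - 1
    c_l <- sum(pbar * (1 - pbar)) / denom_bias
    sh <- outer(ok, ok, "&")
    num[, , l] <- (m + c_l) * sh
    shared[, , l] <- sh
    den[l] <- sum(pbar * (1 - pbar))
  }
  den_pair <- matrix(0, n, n)
  num_pair <- matrix(0, n, n)
  for (l in seq_len(L)) {
    den_pair <- den_pair + shared[, , l] * den[l]
    num_pair <- num_pair + num[, , l]
  }
  F_ij <- ifelse(den_pair > 0, num_pair / den_pair, NA_real_)
  diag(F_ij) <- NA
  dimnames(F_ij) <- list(table$ids, table$ids)
  structure(list(F = F_ij, num = num, shared = shared, den = den,
                 ids = table$ids),
            class = "kinship_matrix")
}

# meter-scale distance matrix between individuals from lon/lat coordinates
individual_distances_m <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  if (n > 1) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    d <- geosphere::distHaversine(
      cbind(coords$longitude, coords$latitude)[idx[, 1], , drop = FALSE],
      cbind(coords$longitude, coords$latitude)[idx[, 2], , drop = FALSE],
      r = 6371008.8)
    m[idx] <- d
    m[idx[, c(2, 1), drop = FALSE]] <- d
  }
  m
}

#' Coordinates of individuals from site metadata
#'
#' Individuals sampled at a site inherit that site's coordinates (their
#' pairs fall at geographic distance 0).
#'
#' @param table a `genotype_table`. @param sites site metadata data frame.
#' @return data frame `id`, `longitude`, `latitude` in table order.
#' @export
individual_coords <- function(table, sites) {
  i <- match(table$site, sites$site_id)
  if (anyNA(i)) {
    stop("individuals at sites missing from metadata: ",
         paste(unique(table$site[is.na(i)]), collapse = ", "))
  }
  data.frame(id = table$ids, longitude = sites$longitude[i],
             latitude = sites$latitude[i], stringsAsFactors = FALSE)
}

# pair -> distance class: 0 and (0, e1] in class 1, (e_{k-1}, e_k] in class
# k, beyond the last edge in the far class (length(edges)+1)
assign_bins <- function(dist_m, edges) {
  b <- matrix(findInterval(dist_m, c(0, edges), left.open = TRUE) ,
              nrow(dist_m))
  b[dist_m == 0] <- 1L
  b
}

bin_labels <- function(edges, far_class_km) {
  c(paste0(c(0, edges[-length(edges)]), "-", edges, "m"),
    paste0(far_class_km, "km"))
}

#' Bin pairwise kinship by geographic distance class
#'
#' Pairs are assigned to the first class whose interval `(lo, hi]` contains
#' their great-circle distance; distance 0 (same plot) falls in the first
#' class; pairs beyond the last edge are pooled into a single far class
#' reported at a nominal distance (default 25 km). A separate
#' `within_site` row (distance exactly 0; also contained in class 1)
#' is reported first.
#'
#' @param kinship a `kinship_matrix` (or a `genotype_table`, in which case
#'   kinship is computed first).
#' @param coords data frame `id`, `longitude`, `latitude` per individual.
#' @param edges increasing bin edges in meters (default 250/500/750/1000).
#' @param far_class_km nominal distance of the pooled far class.
#' @return object of class `kinship_bins`: data frame `table` with bin
#'   label, n_pairs, mean F_ij; plus internals reused by
#'   [jackknife_se()] and [permutation_envelope()].
#' @export
bin_autocorrelation <- function(kinship, coords,
                                edges = c(250, 500, 750, 1000),
                                far_class_km = 25) {
  if (inherits(kinship, "genotype_table")) kinship <- loiselle_kinship(kinship)
  stopifnot(all(diff(edges) > 0))
  ids <- kinship$ids
  if (!identical(coords$id, ids)) {
    coords <- coords[match(ids, coords$id), ]
    if (anyNA(coords$id)) stop("coords missing for some individuals")
  }
  dm <- individual_distances_m(coords)
  bins <- assign_bins(dm, edges)
  nb <- length(edges) + 1L
  labels <- bin_labels(edges, far_class_km)
  ut <- upper.tri(dm)
  eligible <- ut & !is.na(kinship$F)
  bin_mean <- function(Fm) {
    vapply(seq_len(nb), function(b) {
      sel <- eligible & bins == b
      if (any(sel)) mean(Fm[sel]) else NA_real_
    }, numeric(1))
  }
  means <- bin_mean(kinship$F)
  npairs <- vapply(seq_len(nb), function(b) sum(eligible & bins == b),
                   integer(1))
  ws_sel <- eligible & dm == 0
  tab <- data.frame(
    bin = c("within_site", labels),
    n_pairs = c(sum(ws_sel), npairs),
    mean_Fij = c(if (any(ws_sel)) mean(kinship$F[ws_sel]) else NA_real_,
                 means),
    stringsAsFactors = FALSE)
  structure(list(table = tab, kinship = kinship, bins = bins,
                 eligible = eligible, ws_sel = ws_sel, edges = edges,
                 far_class_km = far_class_km, n_bins = nb),
            class = "kinship_bins")
}

#' Jackknife-over-loci standard errors of bin means
#'
#' Each locus is deleted in turn, kinship and the per-class mean recomputed,
#' and `SE = sqrt((L-1)/L * sum_l (theta_(-l) - mean(theta_(-l)))^2)` per
#' class (within-site row included).
#'
#' @param binres a `kinship_bins` result.
#' @return numeric vector of SEs aligned with `binres$table` rows (NA with
#'   a warning when only one locus is available).
#' @export
jackknife_se <- function(binres) {
  stopifnot(inherits(binres, "kinship_bins"))
  k <- binres$kinship
  L <- dim(k$num)[3]
  active <- which(k$den > 0)
  if (length(active) < 2) {
    warning("jackknife needs >= 2 informative loci; SE undefined")
    return(rep(NA_real_, nrow(binres$table)))
  }
  nb <- binres$n_bins
  theta <- matrix(NA_real_, length(active), nb + 1L)
  for (t in seq_along(active)) {
    drop_l <- active[t]
    keep <- setdiff(seq_len(L), drop_l)
    num_p <- apply(k$num[, , keep, drop = FALSE], c(1, 2), sum)
    den_p <- matrix(0, nrow(num_p), ncol(num_p))
    for (l in keep) den_p <- den_p + k$shared[, , l] * k$den[l]
    Fm <- ifelse(den_p > 0, num_p / den_p, NA_real_)
    sel0 <- binres$ws_sel & !is.na(Fm)
    theta[t, 1] <- if (any(sel0)) mean(Fm[sel0]) else NA_real_
    for (b in seq_len(nb)) {
      sel <- binres$eligible & binres$bins == b & !is.na(Fm)
      theta[t, b + 1L] <- if (any(sel)) mean(Fm[sel]) else NA_real_
    }
  }
  Lj <- length(active)
  apply(theta, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sqrt((Lj - 1) / Lj * sum((x - mean(x))^2))
  })
}

#' Permutation confidence envelope and p-values for bin means
#'
#' The genotype-to-location assignment is shuffled `n_perm` times (kinship
#' values are fixed; only which pair lands in which distance class
#' changes), the per-class means recomputed, and the 2.5th/97.5th
#' percentiles reported as the null envelope. The two-tailed p-value is
#' the rank-based position of the observed mean among the permuted ones,
#' with the add-one correction.
#'
#' @param binres a `kinship_bins` result.
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed integer seed.
#' @return data frame: the `binres$table` columns plus `jackknife_se`,
#'   `ci_lo`, `ci_hi`, `p`.
#' @export
permutation_envelope <- function(binres, n_perm = 10000, seed = 1) {
  stopifnot(inherits(binres, "kinship_bins"), n_perm >= 1)
  Fm <- binres$kinship$F
  n <- nrow(Fm)
  nb <- binres$n_bins
  obs <- binres$table$mean_Fij
  perm_means <- matrix(NA_real_, n_perm, nb + 1L)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pi <- sample(n)
      Fp <- Fm[pi, pi]
      sel0 <- binres$ws_sel & !is.na(Fp)
      perm_means[b, 1] <- if (any(sel0)) mean(Fp[sel0]) else NA_real_
      for (k in seq_len(nb)) {
        sel <- binres$eligible & binres$bins == k & !is.na(Fp)
        perm_means[b, k + 1L] <- if (any(sel)) mean(Fp[sel]) else NA_real_
      }
    }
  })
  ci <- apply(perm_means, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  pvals <- vapply(seq_len(nb + 1L), function(k) {
    x <- perm_means[, k]; x <- x[!is.na(x)]
    if (!length(x) || is.na(obs[k])) return(NA_real_)
    up <- (1 + sum(x >= obs[k])) / (length(x) + 1)
    lo <- (1 + sum(x <= obs[k])) / (length(x) + 1)
    min(1, 2 * min(up, lo))
  }, numeric(1))
  out <- binres$table
  out$jackknife_se <- jackknife_se(binres)
  out$ci_lo <- ci[1, ]
  out$ci_hi <- ci[2, ]
  out$p <- pvals
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Full fine-scale kinship autocorrelation analysis
#'
#' Convenience wrapper: Loiselle kinship, distance-class binning,
#' jackknife SEs, and the permutation envelope in one call.
#'
#' @inheritParams bin_autocorrelation
#' @inheritParams permutation_envelope
#' @param table a `genotype_table`.
#' @return the annotated bin table of [permutation_envelope()].
#' @export
kinship_autocorrelation <- function(table, coords,
                                    edges = c(250, 500, 750, 1000),
                                    far_class_km = 25, n_perm = 10000,
                                    seed = 1) {
  binres <- bin_autocorrelation(loiselle_kinship(table), coords, edges,
                                far_class_km)
  permutation_envelope(binres, n_perm = n_perm, seed = seed)
}
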