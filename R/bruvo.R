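#' Bruvo's distance between two diploid genotypes at one locus
#'
#' Allele sizes are converted to repeat units `x = size / repeat_length`
#' (kept as real numbers, so sub-repeat size variants are preserved); the
#' per-allele distance under the stepwise mutation model is
#' `d(x, y) = 1 - 2^(-|x - y|)`, and the diploid locus distance is the
#' minimum over the two perfect matchings of the mean of the two allele
#' distances. The result lies in `[0, 1)`.
#'
#' @param genotype_a,genotype_b numeric vectors of two allele sizes (bp).
#' @param repeat_length repeat-unit length in bp.
#' @return the locus distance, or `NA` if either genotype is missing.
#' @export
bruvo_pair <- function(genotype_a, genotype_b, repeat_length) {
  if (anyNA(genotype_a) || anyNA(genotype_b)) return(NA_real_)
  x <- genotype_a / repeat_length
  y <- genotype_b / repeat_length
  da <- function(u, v) 1 - 2^(-abs(u - v))
  m1 <- (da(x[1], y[1]) + da(x[2], y[2])) / 2
  m2 <- (da(x[1], y[2]) + da(x[2], y[1])) / 2
  min(m1, m2)
}

#' Bruvo distance matrix between all individuals
#'
#' The distance between two individuals is the mean of per-locus Bruvo
#' distances over the loci where both are genotyped (whole-locus pairwise
#' deletion with per-pair renormalization). Pairs with zero shared loci get
#' `NA` and are listed in the `"no_shared_loci"` attribute.
#'
#' @param table a `genotype_table`; every locus must carry a repeat length.
#' @return a `dist_matrix` (units `"bruvo"`) over individuals.
#' @export
bruvo_matrix <- function(table) {
  n <- n_individuals(table); L <- n_loci(table)
  num <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    rl <- table$loci$repeat_length[l]
    x1 <- table$allele1[, l] / rl
    x2 <- table$allele2[, l] / rl
    ok <- !is.na(x1)
    d11 <- 1 - 2^(-abs(outer(x1, x1, "-")))
    d22 <- 1 - 2^(-abs(outer(x2, x2, "-")))
    d12 <- 1 - 2^(-abs(outer(x1, x2, "-")))
    dl <- pmin((d11 + d22) / 2, (d12 + t(d12)) / 2)
    share <- outer(ok, ok, "&")
    dl[!share] <- 0
    num <- num + dl
    cnt <- cnt + share
  }
  d <- ifelse(cnt > 0, num / cnt, NA_real_)
  diag(d) <- 0
  no_shared <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)
  if (nrow(no_shared) > 0) {
    warning("bruvo_matrix: ", nrow(no_shared),
            " pair(s) share zero genotyped loci; entries set NA")
  }
  out <- dist_matrix(d, table$ids, "bruvo")
  attr(out, "no_shared_loci") <-
    if (nrow(no_shared)) cbind(table$ids[no_shared[, 1]],
                               table$ids[no_shared[, 2]]) else NULL
  out
}

#' Mean between-site genetic distance from an individual distance matrix
#'
#' Entry (s, t) is the mean over all cross-site individual pairs; the
#' diagonal is 0. Sites with no individuals are dropped with a warning.
#'
#' @param ind_matrix individual-level `dist_matrix`.
#' @param site_of named character vector mapping individual id to site id
#'   (e.g. the `site` component of a `genotype_table`).
#' @return a site-level `dist_matrix` with the same units.
#' @export
site_mean_distance <- function(ind_matrix, site_of) {
  ids <- rownames(ind_matrix)
  if (!all(ids %in% names(site_of))) {
    stop("site_mean_distance: unmapped individuals")
  }
  site <- site_of[ids]
  sites <- unique(unname(site))
  empty <- setdiff(unique(unname(site_of)), sites)
  if (length(empty)) {
    warning("sites with no individuals dropped: ", paste(empty, collapse = ", "))
  }
  s <- length(sites)
  out <- matrix(0, s, s, dimnames = list(sites, sites))
  for (i in seq_len(s - 1)) for (j in (i + 1):s) {
    block <- ind_matrix[site == sites[i], site == sites[j], drop = FALSE]
    out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
  }
  dist_matrix(out, sites, attr(ind_matrix, "units"))
}
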