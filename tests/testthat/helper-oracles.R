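# Independent brute-force oracles. These deliberately share no code with
# the package implementations: plain loops, direct formula transcription.

# Bruvo distance: explicit per-allele stepwise formula and enumeration of
# both diploid matchings, then pairwise-deletion averaging over loci.
oracle_bruvo_matrix <- function(table) {
  n <- length(table$ids)
  L <- nrow(table$loci)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ds <- c()
    for (l in seq_len(L)) {
      rl <- table$loci$repeat_length[l]
      ga <- c(table$allele1[i, l], table$allele2[i, l]) / rl
      gb <- c(table$allele1[j, l], table$allele2[j, l]) / rl
      if (anyNA(ga) || anyNA(gb)) next
      m1 <- ((1 - 2^(-abs(ga[1] - gb[1]))) + (1 - 2^(-abs(ga[2] - gb[2])))) / 2
      m2 <- ((1 - 2^(-abs(ga[1] - gb[2]))) + (1 - 2^(-abs(ga[2] - gb[1])))) / 2
      ds <- c(ds, min(m1, m2))
    }
    out[i, j] <- if (length(ds)) mean(ds) else NA_real_
  }
  dimnames(out) <- list(table$ids, table$ids)
  out
}

# Loiselle kinship: direct transcription of the covariance formula with
# explicit loops over pairs, loci, alleles.
oracle_loiselle <- function(table, pair) {
  i <- pair[1]; j <- pair[2]
  num <- 0; den <- 0
  for (l in seq_len(nrow(table$loci))) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    if (is.na(a1[i]) || is.na(a1[j])) next
    ok <- !is.na(a1)
    n_l <- sum(ok)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2) next
    for (a in alleles) {
      pbar <- (sum(a1[ok] == a) + sum(a2[ok] == a)) / (2 * n_l)
      p_i <- ((a1[i] == a) + (a2[i] == a)) / 2
      p_j <- ((a1[j] == a) + (a2[j] == a)) / 2
      num <- num + (p_i - pbar) * (p_j - pbar) +
        pbar * (1 - pbar) / (n_l - 1)
      den <- den + pbar * (1 - pbar)
    }
  }
  if (den > 0) num / den else NA_real_
}

# Effective resistance via the dense pseudoinverse of the Laplacian:
# R_ij = L+_ii + L+_jj - 2 L+_ij, with L+ from the rank-correction trick.
oracle_effective_resistance <- function(edges, n_nodes) {
  L <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$conductance[k]
    L[i, j] <- L[i, j] - w
    L[j, i] <- L[j, i] - w
    L[i, i] <- L[i, i] + w
    L[j, j] <- L[j, j] + w
  }
  Lp <- solve(L + 1 / n_nodes) - 1 / n_nodes
  R <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    R[i, j] <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  }
  R
}

# HWE: exhaustive enumeration of all perfect pairings of the gene array
# into unordered genotypes; the p-value is the pairing-probability mass of
# tables no more likely than the observed one.
oracle_hwe_p <- function(a1, a2) {
  genes <- c(a1, a2)
  n <- length(a1)
  sig <- function(s1, s2) {
    g <- paste(pmin(s1, s2), pmax(s1, s2), sep = "/")
    paste(sort(g), collapse = ";")
  }
  counts <- new.env(parent = emptyenv())
  recurse <- function(remaining, acc1, acc2) {
    if (!length(remaining)) {
      key <- sig(acc1, acc2)
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
      return(invisible())
    }
    first <- remaining[1]
    rest <- remaining[-1]
    for (k in seq_along(rest)) {
      recurse(rest[-k], c(acc1, first), c(acc2, rest[k]))
    }
  }
  recurse(genes, integer(0), integer(0))
  tot <- 0; tab <- list()
  for (key in ls(counts)) tot <- tot + counts[[key]]
  p_obs <- counts[[sig(a1, a2)]] / tot
  p <- 0
  for (key in ls(counts)) {
    pk <- counts[[key]] / tot
    if (pk <= p_obs * (1 + 1e-9)) p <- p + pk
  }
  p
}

# OLS via explicit normal equations on unfolded lower triangles
oracle_ols <- function(response, predictors) {
  y <- response[lower.tri(response)]
  X <- cbind(1, vapply(predictors, function(m) m[lower.tri(m)],
                       numeric(length(y))))
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# simple Mantel test: correlation statistic, permute one matrix's labels
oracle_mantel_p <- function(a, b, n_perm, seed) {
  obs <- cor(a[lower.tri(a)], b[lower.tri(b)])
  n <- nrow(a)
  hits <- 0
  set.seed(seed)
  for (k in seq_len(n_perm)) {
    pi <- sample(n)
    if (cor(a[pi, pi][lower.tri(a)], b[lower.tri(b)]) >= obs) hits <- hits + 1
  }
  (1 + hits) / (n_perm + 1)
}
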