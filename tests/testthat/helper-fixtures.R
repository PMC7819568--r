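# Small genotype tables built in code.

dinuc_loci <- function(n, rl = 2L) {
  data.frame(name = sprintf("L%02d", seq_len(n)),
             repeat_length = rep(rl, length.out = n),
             stringsAsFactors = FALSE)
}

# random complete-or-missing diploid table
random_table <- function(n = 10, L = 4, sites = c("S1", "S2"),
                         missing_frac = 0, seed = 1, allele_range = 8:20,
                         rl = 2L) {
  set.seed(seed)
  a1 <- matrix(sample(allele_range, n * L, TRUE) * rl, n, L)
  a2 <- matrix(sample(allele_range, n * L, TRUE) * rl, n, L)
  if (missing_frac > 0) {
    miss <- matrix(runif(n * L) < missing_frac, n, L)
    # keep at least one genotyped locus per individual
    miss[cbind(seq_len(n), max.col(-miss))] <- FALSE
    a1[miss] <- NA; a2[miss] <- NA
  }
  genotype_table(sprintf("ind%02d", seq_len(n)), dinuc_loci(L, rl), a1, a2,
                 rep_len(sites, n))
}

# table from explicit genotype strings: list(site = list(c("10/12", ...)))
# one string per locus; "NA" = missing; sizes in repeat units times rl
table_from_genotypes <- function(genos, rl = 2L) {
  ids <- character(0); site <- character(0)
  rows1 <- list(); rows2 <- list()
  k <- 0
  for (s in names(genos)) {
    for (ind in genos[[s]]) {
      k <- k + 1
      ids <- c(ids, sprintf("i%02d", k)); site <- c(site, s)
      parts <- strsplit(ind, ",")[[1]]
      g <- lapply(parts, function(p) {
        if (p == "NA") c(NA_integer_, NA_integer_)
        else as.integer(strsplit(p, "/")[[1]]) * rl
      })
      rows1[[k]] <- vapply(g, `[`, integer(1), 1)
      rows2[[k]] <- vapply(g, `[`, integer(1), 2)
    }
  }
  L <- length(rows1[[1]])
  genotype_table(ids, dinuc_loci(L, rl), do.call(rbind, rows1),
                 do.call(rbind, rows2), site)
}

# site metadata for a set of site ids laid out on a line, dx meters apart
line_sites <- function(ids, dx = 5000, lat0 = 30.5, lon0 = -97.7) {
  mperdeg <- pi / 180 * 6371008.8
  data.frame(site_id = ids, region_id = ids,
             longitude = lon0 + (seq_along(ids) - 1) * dx /
               (mperdeg * cos(lat0 * pi / 180)),
             latitude = lat0, transect_offset_m = NA_real_,
             stringsAsFactors = FALSE)
}
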