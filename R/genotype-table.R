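#' Construct a diploid microsatellite genotype table
#'
#' The central container of the package: `n` individuals typed at `L`
#' codominant microsatellite loci, with two allele-size calls (base pairs)
#' per individual and locus, plus the sampling site of every individual.
#' Missing data are all-or-nothing per individual-locus pair: either both
#' allele slots carry a positive size, or both are `NA`.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci data frame with columns `name` (unique locus labels) and
#'   `repeat_length` (integer >= 1, base pairs per repeat unit; e.g. 2 for a
#'   dinucleotide motif). The repeat length is carried here but only used
#'   when converting to repeat units in [bruvo_matrix()].
#' @param allele1,allele2 integer matrices (`n x L`) of allele sizes in base
#'   pairs; `NA` marks a missing genotype and must occur in both matrices at
#'   the same cells.
#' @param site character vector of length `n`: site id of each individual.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, loci, allele1, allele2, site) {
  ids <- as.character(ids)
  site <- as.character(site)
  if (anyDuplicated(ids)) {
    stop("duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.data.frame(loci) || !all(c("name", "repeat_length") %in% names(loci))) {
    stop("'loci' must be a data frame with columns 'name' and 'repeat_length'")
  }
  loci$name <- as.character(loci$name)
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  if (any(loci$repeat_length < 1)) stop("repeat_length must be >= 1")
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  n <- length(ids); L <- nrow(loci)
  if (!all(dim(allele1) == c(n, L)) || !all(dim(allele2) == c(n, L))) {
    stop("allele matrices must be n individuals x L loci")
  }
  if (length(site) != n) stop("'site' must have one entry per individual")
  if (any(is.na(site))) stop("every individual needs a site id")
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop("partial (single-allele) genotype at individual '", ids[bad[1]],
         "', locus '", loci$name[bad[2]], "': missing must be all-or-nothing")
  }
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE)) {
    stop("allele sizes must be strictly positive")
  }
  dimnames(allele1) <- dimnames(allele2) <- list(ids, loci$name)
  structure(
    list(ids = ids, loci = loci, allele1 = allele1, allele2 = allele2,
         site = stats::setNames(site, ids)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", nrow(x$loci),
      "loci,", length(unique(x$site)), "sites\n")
  mf <- mean(is.na(x$allele1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mf))
  invisible(x)
}

#' Number of individuals / loci
#' @param table a `genotype_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$ids)

#' @rdname n_individuals
#' @export
n_loci <- function(table) nrow(table$loci)

#' Per-individual fraction of missing loci
#' @param table a `genotype_table`.
#' @return named numeric vector in \[0, 1\].
#' @export
missing_fraction <- function(table) {
  rowMeans(is.na(table$allele1))
}

subset_individuals <- function(table, keep) {
  genotype_table(table$ids[keep], table$loci,
                 table$allele1[keep, , drop = FALSE],
                 table$allele2[keep, , drop = FALSE],
                 table$site[keep])
}

#' Remove individuals with too much missing data
#'
#' Drops every individual whose fraction of missing loci is strictly greater
#' than `max_missing_frac` (an individual exactly at the threshold is kept:
#' the rule is "over", not "at or over"). Order of the retained individuals
#' is preserved.
#'
#' @param table a `genotype_table`.
#' @param max_missing_frac maximum tolerated missing fraction, default 0.2.
#' @param quiet suppress the removal message.
#' @return filtered `genotype_table`; removed IDs in attribute `"removed"`.
#' @export
filter_missing <- function(table, max_missing_frac = 0.2, quiet = FALSE) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  mf <- missing_fraction(table)
  drop <- mf > max_missing_frac
  if (all(drop)) {
    stop("filter_missing would remove every individual; review the threshold")
  }
  if (any(drop) && !quiet) {
    message("filter_missing: removed ", sum(drop), " of ", length(drop),
            " individuals (> ", 100 * max_missing_frac, "% missing)")
  }
  out <- subset_individuals(table, !drop)
  attr(out, "removed") <- table$ids[drop]
  out
}

#' Exclude listed individuals (e.g. identified full siblings)
#'
#' @param table a `genotype_table`.
#' @param ids character vector of individual IDs to drop; unknown IDs raise
#'   a warning, not an error.
#' @param quiet suppress the removal message.
#' @return `genotype_table` without the listed individuals.
#' @export
exclude_individuals <- function(table, ids, quiet = FALSE) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, table$ids)
  if (length(unknown)) {
    warning("exclude_individuals: unknown IDs ignored: ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(table$ids %in% ids)
  if (!any(keep)) stop("exclusion list removes every individual")
  if (!quiet && any(!keep)) {
    message("exclude_individuals: removed ", sum(!keep), " individuals")
  }
  subset_individuals(table, keep)
}

#' Read a GenAlEx codominant genotype CSV
#'
#' Expects the GenAlEx layout for codominant data: three header rows (counts
#' row; title row; locus-name row with two columns per locus), then one row
#' per individual: ID, population (mapped to site id), and an allele-size
#' pair per locus. `0`, an empty cell, or `NA` denote a missing allele;
#' missingness must cover both alleles of a locus.
#'
#' @param path CSV file path.
#' @param repeat_lengths optional named integer vector of repeat lengths per
#'   locus (names matching the locus-name row); defaults to 2 (dinucleotide)
#'   with a message.
#' @return a `genotype_table`.
#' @export
read_genalex <- function(path, repeat_lengths = NULL) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", blank.lines.skip = FALSE)
  if (nrow(raw) < 4) stop("GenAlEx file too short: ", path)
  locus_row <- as.character(unlist(raw[3, ]))
  locus_names <- locus_row[seq(3, length(locus_row), by = 2)]
  locus_names <- locus_names[!is.na(locus_names) & nzchar(locus_names)]
  L <- length(locus_names)
  if (L == 0) stop("no locus names found on header row 3 of ", path)
  if (ncol(raw) < 2 + 2 * L) {
    stop("odd allele-column count in ", path, ": expected ", 2 + 2 * L,
         " columns for ", L, " loci")
  }
  body <- raw[-(1:3), , drop = FALSE]
  body <- body[rowSums(body != "" & !is.na(body)) > 0, , drop = FALSE]
  ids <- as.character(body[[1]])
  site <- as.character(body[[2]])
  parse_allele <- function(x, col) {
    x <- trimws(x)
    x[x %in% c("", "0", "NA", "na")] <- NA
    bad <- !is.na(x) & is.na(suppressWarnings(as.integer(x)))
    if (any(bad)) {
      stop("non-numeric allele value '", x[which(bad)[1]], "' at row ",
           which(bad)[1] + 3, ", column ", col, " of the GenAlEx file")
    }
    as.integer(x)
  }
  a1 <- matrix(NA_integer_, nrow(body), L)
  a2 <- matrix(NA_integer_, nrow(body), L)
  for (l in seq_len(L)) {
    a1[, l] <- parse_allele(body[[2 * l + 1]], 2 * l + 1)
    a2[, l] <- parse_allele(body[[2 * l + 2]], 2 * l + 2)
  }
  # GenAlEx writes a whole missing genotype as 0,0; a lone 0 is a half-call
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop("partial genotype (one allele missing) at individual '",
         ids[bad[1]], "', locus '", locus_names[bad[2]], "'")
  }
  if (is.null(repeat_lengths)) {
    message("read_genalex: no repeat lengths supplied; defaulting to 2 bp ",
            "(dinucleotide) for all loci")
    repeat_lengths <- stats::setNames(rep(2L, L), locus_names)
  }
  if (!all(locus_names %in% names(repeat_lengths))) {
    stop("repeat_lengths missing for loci: ",
         paste(setdiff(locus_names, names(repeat_lengths)), collapse = ", "))
  }
  loci <- data.frame(name = locus_names,
                     repeat_length = as.integer(repeat_lengths[locus_names]),
                     stringsAsFactors = FALSE)
  genotype_table(ids, loci, a1, a2, site)
}

#' Write a genotype table as GenAlEx codominant CSV
#'
#' Missing genotypes are written back as `0,0` (the GenAlEx dialect), so
#' `read_genalex(write_genalex(x))` round-trips.
#'
#' @param table a `genotype_table`.
#' @param path output CSV path.
#' @param title free-text title placed on header row 2.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(table, path, title = "msatland export") {
  n <- n_individuals(table); L <- n_loci(table)
  sites <- unique(table$site)
  # header row 1 (counts + per-site sizes) may be wider than the data block
  ncols <- max(2 + 2 * L, 3 + length(sites))
  pad <- function(x) c(x, rep("", ncols - length(x)))
  h1 <- pad(c(L, n, length(sites), as.vector(table(factor(table$site, sites)))))
  h2 <- pad(title)
  h3 <- character(ncols); h3[1:2] <- c("Ind", "Pop")
  h3[seq(3, by = 2, length.out = L)] <- table$loci$name
  a1 <- table$allele1; a2 <- table$allele2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  body <- matrix("", n, ncols)
  body[, 1] <- table$ids; body[, 2] <- table$site
  body[, seq(3, by = 2, length.out = L)] <- as.character(a1)
  body[, seq(4, by = 2, length.out = L)] <- as.character(a2)
  out <- rbind(h1, h2, h3, body)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site metadata
#'
#' @param path CSV with header
#'   `site_id,region_id,longitude,latitude,transect_offset_m` (the offset
#'   column is optional and may be empty).
#' @return data frame of validated site records, one row per site.
#' @export
read_sites <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "region_id", "longitude", "latitude")
  if (!all(req %in% names(s))) {
    stop("site metadata must have columns ", paste(req, collapse = ", "))
  }
  if (!"transect_offset_m" %in% names(s)) s$transect_offset_m <- NA_real_
  validate_sites(s)
  s
}

validate_sites <- function(s) {
  if (anyDuplicated(s$site_id)) stop("duplicate site_id in site metadata")
  if (any(s$latitude < -90 | s$latitude > 90, na.rm = TRUE) ||
      any(s$longitude < -180 | s$longitude > 180, na.rm = TRUE)) {
    stop("coordinates out of range: latitude in [-90,90], longitude in [-180,180]")
  }
  invisible(s)
}

#' Read an exclusion list (one individual ID per line)
#' @param path text file path; blank lines and `#` comments ignored.
#' @return character vector of IDs.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
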