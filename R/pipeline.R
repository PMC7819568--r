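#' Pipeline configuration
#'
#' Defaults are the study settings: 20% missing-data threshold for the
#' pairwise analysis, 10,000 MRDM permutations, 9,999 locus-bootstrap
#' replicates for pairwise differentiation, 10,000 autocorrelation
#' permutations, distance classes at 250/500/750/1000 m with a 25 km far
#' class, and 210 m aggregation (factor 7 at 30 m input resolution).
#'
#' @param genotypes path to the GenAlEx genotype CSV.
#' @param sites path to the site metadata CSV.
#' @param raster path to the land-cover .asc raster (NULL disables IBR).
#' @param exclusion_list optional path to an ID-per-line exclusion file.
#' @param repeat_lengths named integer vector of per-locus repeat lengths,
#'   or a single integer recycled over loci.
#' @param missing_threshold max missing fraction for the pairwise subset.
#' @param n_perm_mrdm,n_boot_pairwise,n_perm_autocorr resampling sizes.
#' @param bin_edges autocorrelation class edges (m).
#' @param far_class_km nominal distance of the pooled far class.
#' @param aggregate_factor raster block-aggregation factor.
#' @param value_pairs list of (low, high) resistance value pairs.
#' @param seed master seed; stages derive child seeds from it.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, sites, raster = NULL,
                            exclusion_list = NULL, repeat_lengths = 2L,
                            missing_threshold = 0.2, n_perm_mrdm = 10000,
                            n_boot_pairwise = 9999, n_perm_autocorr = 10000,
                            bin_edges = c(250, 500, 750, 1000),
                            far_class_km = 25, aggregate_factor = 7,
                            value_pairs = list(c(0.1, 0.9), c(0.1, 0.5),
                                               c(0.3, 0.9), c(0.3, 0.5)),
                            seed = 1, out_dir = "msatland_out") {
  structure(as.list(environment()), class = "pipeline_config")
}

PIPELINE_KEYS <- c("genotypes", "sites", "raster", "exclusion_list",
                   "repeat_lengths", "missing_threshold", "n_perm_mrdm",
                   "n_boot_pairwise", "n_perm_autocorr", "bin_edges",
                   "far_class_km", "aggregate_factor", "seed", "out_dir")

#' Read a flat key=value pipeline config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' unknown keys are errors. List-valued keys (`bin_edges`,
#' `repeat_lengths`) take comma-separated values; `repeat_lengths` entries
#' may be `locus:length` pairs.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  unknown <- setdiff(keys, PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      genotypes = , sites = , raster = , exclusion_list = , out_dir = v,
      missing_threshold = , far_class_km = as.numeric(v),
      n_perm_mrdm = , n_boot_pairwise = , n_perm_autocorr = ,
      aggregate_factor = , seed = as.integer(v),
      bin_edges = as.numeric(strsplit(v, ",")[[1]]),
      repeat_lengths = {
        parts <- strsplit(v, ",")[[1]]
        if (all(grepl(":", parts))) {
          sp <- strsplit(parts, ":")
          stats::setNames(as.integer(vapply(sp, `[`, "", 2)),
                          vapply(sp, `[`, "", 1))
        } else as.integer(v)
      })
  }
  do.call(pipeline_config, args)
}

lonlat_to_metric <- function(lon, lat) {
  data.frame(
    x = (lon - LL_REF["lon"]) * M_PER_DEG * cos(LL_REF["lat"] * pi / 180),
    y = (lat - LL_REF["lat"]) * M_PER_DEG)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

provenance_header <- function(cfg, inputs) {
  hashes <- vapply(inputs, function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else ""
  }, "")
  c(paste0("# msatland ",
           as.character(utils::packageVersion("msatland")),
           "; seed=", cfg$seed),
    paste0("# input ", names(hashes), "=", hashes))
}

write_out <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run the full multi-scale analysis pipeline
#'
#' Stages, in order: load and validate inputs; exclude listed individuals;
#' diversity, private-allele and global differentiation statistics; the
#' >missing-threshold filter and pairwise differentiation; Bruvo distances
#' and site means; geographic distances; the resistance-surface suite and
#' the 22-model IBD/IBR MRDM suite (skipped without a raster);
#' fine-scale kinship autocorrelation. Any stage failure aborts with a
#' stage-named error. All outputs carry a provenance header (package
#' version, master seed, input MD5 hashes) and a resolved-config copy is
#' written alongside them.
#'
#' @param cfg a `pipeline_config`.
#' @return (invisibly) list with every stage result and the output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(cfg, list(genotypes = cfg$genotypes,
                                     sites = cfg$sites, raster = cfg$raster))
  paths <- new.env(parent = emptyenv())

  inp <- stage("load", {
    tbl <- read_genalex(cfg$genotypes, repeat_lengths =
      if (length(cfg$repeat_lengths) == 1 && is.null(names(cfg$repeat_lengths)))
        NULL else cfg$repeat_lengths)
    if (length(cfg$repeat_lengths) == 1 && is.null(names(cfg$repeat_lengths))) {
      tbl$loci$repeat_length <- rep(as.integer(cfg$repeat_lengths),
                                    nrow(tbl$loci))
    }
    sites <- read_sites(cfg$sites)
    missing_sites <- setdiff(unique(tbl$site), sites$site_id)
    if (length(missing_sites)) {
      stop("genotype sites missing from metadata: ",
           paste(missing_sites, collapse = ", "))
    }
    excl <- if (!is.null(cfg$exclusion_list)) {
      read_exclusion_list(cfg$exclusion_list)
    } else character(0)
    list(table = tbl, sites = sites, excl = excl)
  })
  tbl <- stage("exclude", {
    if (length(inp$excl)) exclude_individuals(inp$table, inp$excl,
                                              quiet = TRUE)
    else inp$table
  })

  stats_res <- stage("stats", {
    freqs <- allele_frequencies(tbl)
    div <- diversity_stats(tbl)
    priv <- private_alleles(freqs)
    glob <- global_differentiation(tbl)
    paths$diversity <- write_out(div$per_cell,
                                  file.path(cfg$out_dir, "diversity.csv"), hdr)
    paths$global <- write_out(
      data.frame(statistic = c("Fst", "Gst_prime", "Hs", "Ht", "k"),
                 value = c(glob$Fst, glob$Gst_prime, glob$Hs, glob$Ht,
                           glob$k)),
      file.path(cfg$out_dir, "global_differentiation.csv"), hdr)
    paths$private <- write_out(
      data.frame(site = names(priv), private_alleles = unname(priv)),
      file.path(cfg$out_dir, "private_alleles.csv"), hdr)
    list(freqs = freqs, diversity = div, private = priv, global = glob)
  })

  pw <- stage("pairwise", {
    tbl_pw <- filter_missing(tbl, cfg$missing_threshold, quiet = TRUE)
    res <- pairwise_differentiation(tbl_pw, n_boot = cfg$n_boot_pairwise,
                                    seed = child_seed(cfg$seed, "pairwise"))
    paths$pairwise <- write_out(res$pairs,
                                 file.path(cfg$out_dir, "pairwise_fst.csv"),
                                 hdr)
    res
  })

  dists <- stage("distances", {
    bm <- bruvo_matrix(tbl)
    sm <- site_mean_distance(bm, tbl$site)
    paths$bruvo_sites <- file.path(cfg$out_dir, "bruvo_site_means.csv")
    write_dist_csv(sm, paths$bruvo_sites)
    site_sub <- inp$sites[inp$sites$site_id %in% rownames(sm), ]
    geo <- great_circle_matrix(site_sub)
    paths$geo <- file.path(cfg$out_dir, "geographic_km.csv")
    write_dist_csv(geo, paths$geo)
    list(ind = bm, site = sm, geo = geo, site_sub = site_sub)
  })

  suite <- NULL
  if (!is.null(cfg$raster)) {
    suite <- stage("ibr", {
      if (!file.exists(cfg$raster)) {
        stop("raster input not found: ", cfg$raster)
      }
      raster <- read_asc(cfg$raster)
      surfaces <- build_surface_suite(raster,
                                      value_pairs = cfg$value_pairs,
                                      aggregate_factor = cfg$aggregate_factor)
      ss <- dists$site_sub
      pts <- if (all(c("x", "y") %in% names(ss))) {
        data.frame(site_id = ss$site_id, x = ss$x, y = ss$y)
      } else {
        cbind(site_id = ss$site_id,
              lonlat_to_metric(ss$longitude, ss$latitude))
      }
      res <- run_model_suite(dists$site, dists$geo, surfaces, pts, ss,
                             n_perm = cfg$n_perm_mrdm,
                             seed = child_seed(cfg$seed, "mrdm"))
      paths$mrdm <- write_out(res, file.path(cfg$out_dir, "mrdm_suite.csv"),
                               hdr)
      res
    })
  }

  autoc <- stage("autocorr", {
    coords <- individual_coords(tbl, inp$sites)
    res <- kinship_autocorrelation(tbl, coords, edges = cfg$bin_edges,
                                   far_class_km = cfg$far_class_km,
                                   n_perm = cfg$n_perm_autocorr,
                                   seed = child_seed(cfg$seed, "autocorr"))
    paths$autocorr <- write_out(res,
                                 file.path(cfg$out_dir, "autocorrelation.csv"),
                                 hdr)
    res
  })

  cfg_lines <- vapply(PIPELINE_KEYS, function(k) {
    paste0(k, " = ", paste(unlist(cfg[[k]]), collapse = ","))
  }, "")
  writeLines(c(hdr, cfg_lines), file.path(cfg$out_dir, "resolved_config.txt"))
  writeLines(c(hdr, paste0("stages completed: load, exclude, stats, ",
                           "pairwise, distances",
                           if (!is.null(suite)) ", ibr" else "",
                           ", autocorr")),
             file.path(cfg$out_dir, "log.txt"))
  invisible(list(table = tbl, sites = inp$sites, stats = stats_res,
                 pairwise = pw, distances = dists, mrdm_suite = suite,
                 autocorrelation = autoc, paths = as.list(paths)))
}
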