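#' Configuration for the forward-time genotype simulator
#'
#' Defines a spatial sampling design (regions, optionally with 5-point
#' transects at 300 m spacing), a landscape raster spec, and the
#' population-genetic parameters of a forward-time stepwise-mutation model
#' with resistance-dependent migration and within-region philopatry.
#'
#' @param n_regions number of regions (one breeding deme each).
#' @param n_transect_regions how many regions get a transect of
#'   `sites_per_transect` collection points.
#' @param sites_per_transect points per transect (default 5: offsets 0,
#'   300, 600, 900, 1200 m).
#' @param transect_spacing_m spacing between transect points (default 300).
#' @param deme_size individuals per region per generation (default 40).
#' @param n_loci microsatellite loci (default 10).
#' @param repeat_length bp per repeat unit, recycled over loci (default 2).
#' @param mu stepwise mutation rate per allele per generation (default
#'   0.005; each event adds or removes one repeat, reflecting at 5 and 40
#'   repeat units).
#' @param n_generations forward generations (default 60).
#' @param migration_total total per-generation emigration probability out
#'   of a region (default 0.05); destination weights are
#'   `exp(-lambda * R_ij)` row-normalized, self-probability the remainder.
#' @param lambda decay of migration with effective resistance (default 5:
#'   on landscapes with cell resistances in (0,1\] the pairwise effective
#'   resistances span roughly 0.1-1.5 units, so migration e-folds per 0.2
#'   resistance units).
#' @param founder_pool optional list(`repeats`, `weights`) overriding the
#'   triangular 8-20 repeat founder allele pool (a single repeat with
#'   weight 1 gives the no-variation limit).
#' @param philopatry probability an offspring keeps its parent's natal
#'   subsite rather than redrawing uniformly within the region (default 0.5).
#' @param n_sample_per_site individuals sampled per collection point from
#'   the final generation (default 15, capped by availability).
#' @param raster_rows,raster_cols,cell_size_m landscape grid spec.
#' @param cover_proportions named proportions of the five cover groups in
#'   the block mosaic.
#' @param block_cells edge length (cells) of the mosaic blocks.
#' @param seed master seed; every simulator draw is governed by it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 8, n_transect_regions = 2,
                       sites_per_transect = 5, transect_spacing_m = 300,
                       deme_size = 40, n_loci = 10, repeat_length = 2,
                       mu = 0.005, n_generations = 60,
                       migration_total = 0.05, lambda = 5,
                       philopatry = 0.5, founder_pool = NULL,
                       n_sample_per_site = 15,
                       raster_rows = 60, raster_cols = 60, cell_size_m = 210,
                       cover_proportions = c(developed = 0.2,
                                             cultivated = 0.2,
                                             forest_shrub = 0.2,
                                             grassland = 0.3, other = 0.1),
                       block_cells = 6, seed = 1) {
  stopifnot(mu >= 0, mu <= 1, migration_total >= 0, migration_total < 1,
            philopatry >= 0, philopatry <= 1, deme_size >= 2,
            n_generations >= 1, n_transect_regions <= n_regions)
  cover_proportions <- cover_proportions / sum(cover_proportions)
  structure(as.list(environment()), class = "sim_config")
}

# representative NLCD codes for the five cover groups
GROUP_CODES <- c(developed = 22L, cultivated = 81L, forest_shrub = 41L,
                 grassland = 71L, other = 11L)

#' Generate a blocky land-cover mosaic
#'
#' Seeded mosaic of square blocks, each assigned one of the five cover
#' groups with the configured proportions; optional corridors overwrite a
#' straight band of cells between two points with a chosen group.
#'
#' @param cfg a `sim_config`.
#' @param corridors optional data frame `x1, y1, x2, y2, group, width_m`.
#' @return a `land_raster` of NLCD-style class codes.
#' @export
generate_landscape <- function(cfg, corridors = NULL) {
  nr <- cfg$raster_rows; nc <- cfg$raster_cols
  stopifnot(nr >= 1, nc >= 1, cfg$cell_size_m > 0)
  codes <- GROUP_CODES[names(cfg$cover_proportions)]
  with_seed(child_seed(cfg$seed, "landscape"), {
    br <- ceiling(nr / cfg$block_cells); bc <- ceiling(nc / cfg$block_cells)
    blocks <- matrix(sample(codes, br * bc, replace = TRUE,
                            prob = cfg$cover_proportions), br, bc)
    v <- blocks[(seq_len(nr) - 1) %/% cfg$block_cells + 1,
                (seq_len(nc) - 1) %/% cfg$block_cells + 1, drop = FALSE]
  })
  if (!is.null(corridors)) {
    cs <- cfg$cell_size_m
    xc <- (seq_len(nc) - 0.5) * cs
    yc <- rev((seq_len(nr) - 0.5) * cs)       # row 1 = top
    for (k in seq_len(nrow(corridors))) {
      co <- corridors[k, ]
      a <- c(co$x1, co$y1); b <- c(co$x2, co$y2)
      ab <- b - a; len2 <- sum(ab^2)
      for (r in seq_len(nr)) for (cl in seq_len(nc)) {
        p <- c(xc[cl], yc[r])
        t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
        d <- sqrt(sum((p - (a + t * ab))^2))
        if (d <= co$width_m / 2) v[r, cl] <- GROUP_CODES[[co$group]]
      }
    }
  }
  land_raster(v, cfg$cell_size_m)
}

# reference point for the metric -> lon/lat local projection (study-area
# scale; any fixed anchor works)
LL_REF <- c(lon = -97.7, lat = 30.5)
M_PER_DEG <- pi / 180 * 6371008.8

metric_to_lonlat <- function(x, y) {
  lat <- LL_REF["lat"] + y / M_PER_DEG
  lon <- LL_REF["lon"] + x / (M_PER_DEG * cos(LL_REF["lat"] * pi / 180))
  data.frame(longitude = unname(lon), latitude = unname(lat))
}

# place region anchors inside the raster with a margin, transects running
# east; returns the collection-point table (one row per subsite)
layout_sites <- function(cfg) {
  ext_x <- cfg$raster_cols * cfg$cell_size_m
  ext_y <- cfg$raster_rows * cfg$cell_size_m
  tr_len <- (cfg$sites_per_transect - 1) * cfg$transect_spacing_m
  margin <- 0.07 * min(ext_x, ext_y)
  with_seed(child_seed(cfg$seed, "sites"), {
    ax <- runif(cfg$n_regions, margin, ext_x - margin - tr_len)
    ay <- runif(cfg$n_regions, margin, ext_y - margin)
  })
  rows <- list(); r <- 0L
  for (g in seq_len(cfg$n_regions)) {
    region <- sprintf("R%02d", g)
    offs <- if (g <= cfg$n_transect_regions) {
      (seq_len(cfg$sites_per_transect) - 1) * cfg$transect_spacing_m
    } else 0
    for (o in offs) {
      r <- r + 1L
      rows[[r]] <- data.frame(
        site_id = if (length(offs) > 1) paste0(region, "_", o) else region,
        region_id = region, x = ax[g] + o, y = ay[g],
        transect_offset_m = if (length(offs) > 1) o else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, rows)
  cbind(pts, metric_to_lonlat(pts$x, pts$y))
}

triangular_founder_pool <- function() {
  r <- 8:20
  w <- pmin(r - 7, 21 - r)
  list(repeats = r, weights = w / sum(w))
}

reflect_repeats <- function(x, lo = 5, hi = 40) {
  x[x < lo] <- 2 * lo - x[x < lo]
  x[x > hi] <- 2 * hi - x[x > hi]
  x
}

#' Simulate spatially structured microsatellite genotypes
#'
#' Forward-time model: one deme of `deme_size` diploids per region;
#' founders draw alleles from a shared triangular pool over 8-20 repeat
#' units. Each generation, every offspring slot in a region picks a source
#' region (backward migration with probability `migration_total`, spread
#' over regions as `exp(-lambda * R_ij)` row-normalized), two distinct
#' parents from that deme (no selfing), one allele per parent with
#' stepwise mutation at rate `mu` (reflecting at 5/40 repeats). Offspring
#' of non-migrants keep the first parent's natal subsite with probability
#' `philopatry`, otherwise (and for migrants) a uniform subsite of their
#' region. The final generation is sampled without replacement per
#' collection point.
#'
#' @param cfg a `sim_config`.
#' @param surface a `resistance_surface` over which migration decays (the
#'   generating hypothesis); its extent must contain the site layout.
#' @param points optional precomputed site table from `layout_sites`
#'   (internal reuse).
#' @param resist optional precomputed region-anchor resistance
#'   `dist_matrix` (skips the Laplacian solve when simulating many
#'   replicates on one landscape).
#' @return list: `table` (a `genotype_table`), `sites` (collection-point
#'   metadata incl. metric x/y and lon/lat), and `truth` (generating
#'   hypothesis, lambda, philopatry, realized migration matrix, founder
#'   pool).
#' @export
simulate_genotypes <- function(cfg, surface, points = NULL, resist = NULL) {
  pts <- if (is.null(points)) layout_sites(cfg) else points
  anchors <- pts[!duplicated(pts$region_id), ]
  K <- nrow(anchors)
  if (is.null(resist)) {
    resist <- resistance_distance(surface,
                                  data.frame(site_id = anchors$region_id,
                                             x = anchors$x, y = anchors$y))
  }
  R <- unclass(resist)[anchors$region_id, anchors$region_id, drop = FALSE]
  M <- diag(1, K)
  if (K > 1 && cfg$migration_total > 0) {
    W <- exp(-cfg$lambda * R)
    diag(W) <- 0
    M <- cfg$migration_total * W / rowSums(W)
    diag(M) <- 1 - cfg$migration_total
  }
  N <- cfg$deme_size; L <- cfg$n_loci; G <- cfg$n_generations
  rl <- rep(cfg$repeat_length, length.out = L)
  subsites <- split(pts$site_id, pts$region_id)[unique(pts$region_id)]
  pool <- if (is.null(cfg$founder_pool)) triangular_founder_pool() else
    cfg$founder_pool
  with_seed(child_seed(cfg$seed, "genotypes"), {
    # state: per region, repeat-unit array [individual, locus, chromosome]
    A <- lapply(seq_len(K), function(g) {
      draw <- pool$repeats[sample.int(length(pool$repeats), N * L * 2,
                                      replace = TRUE, prob = pool$weights)]
      array(draw, c(N, L, 2))
    })
    sub <- lapply(seq_len(K), function(g) {
      sample(subsites[[g]], N, replace = TRUE)
    })
    for (gen in seq_len(G)) {
      Anew <- vector("list", K); subnew <- vector("list", K)
      for (j in seq_len(K)) {
        src <- sample.int(K, N, replace = TRUE, prob = M[j, ])
        child <- array(0L, c(N, L, 2))
        csub <- character(N)
        for (s in unique(src)) {
          idx <- which(src == s)
          p1 <- sample.int(N, length(idx), replace = TRUE)
          p2 <- 1 + (p1 - 1 + sample.int(N - 1, length(idx),
                                         replace = TRUE)) %% N
          for (l in seq_len(L)) {
            pick1 <- sample.int(2, length(idx), replace = TRUE)
            pick2 <- sample.int(2, length(idx), replace = TRUE)
            g1 <- A[[s]][cbind(p1, l, pick1)]
            g2 <- A[[s]][cbind(p2, l, pick2)]
            if (cfg$mu > 0) {
              mut1 <- stats::runif(length(idx)) < cfg$mu
              mut2 <- stats::runif(length(idx)) < cfg$mu
              g1[mut1] <- g1[mut1] + sample(c(-1L, 1L), sum(mut1), TRUE)
              g2[mut2] <- g2[mut2] + sample(c(-1L, 1L), sum(mut2), TRUE)
              g1 <- reflect_repeats(g1); g2 <- reflect_repeats(g2)
            }
            child[cbind(idx, l, 1L)] <- g1
            child[cbind(idx, l, 2L)] <- g2
          }
          if (s == j) {
            stay <- stats::runif(length(idx)) < cfg$philopatry
            cs <- character(length(idx))
            cs[stay] <- sub[[s]][p1[stay]]
            cs[!stay] <- sample(subsites[[j]], sum(!stay), replace = TRUE)
            csub[idx] <- cs
          } else {
            csub[idx] <- sample(subsites[[j]], length(idx), replace = TRUE)
          }
        }
        Anew[[j]] <- child; subnew[[j]] <- csub
      }
      A <- Anew; sub <- subnew
    }
    # sample the final generation per collection point
    ids <- character(0); site <- character(0)
    a1 <- NULL; a2 <- NULL
    for (j in seq_len(K)) {
      for (ss in subsites[[j]]) {
        avail <- which(sub[[j]] == ss)
        take <- avail[sample.int(length(avail),
                                 min(cfg$n_sample_per_site, length(avail)))]
        if (!length(take)) next
        ids <- c(ids, paste0(ss, "_i", seq_along(take)))
        site <- c(site, rep(ss, length(take)))
        m1 <- A[[j]][take, , 1, drop = FALSE][, , 1, drop = TRUE]
        m2 <- A[[j]][take, , 2, drop = FALSE][, , 1, drop = TRUE]
        if (length(take) == 1) { m1 <- matrix(m1, 1); m2 <- matrix(m2, 1) }
        a1 <- rbind(a1, m1); a2 <- rbind(a2, m2)
      }
    }
  })
  # order alleles within genotype and convert repeat units -> base pairs
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  bp1 <- sweep(lo, 2, rl, "*"); bp2 <- sweep(hi, 2, rl, "*")
  loci <- data.frame(name = sprintf("L%02d", seq_len(L)), repeat_length = rl,
                     stringsAsFactors = FALSE)
  tbl <- genotype_table(ids, loci, bp1, bp2, site)
  truth <- list(hypothesis = surface$provenance$hypothesis,
                lambda = cfg$lambda, philopatry = cfg$philopatry,
                migration = M, founder_pool = pool,
                resistance = R, seed = cfg$seed)
  list(table = tbl, sites = pts, truth = truth)
}

#' Corridor-cluster study design for isolation-by-resistance recovery
#'
#' Builds the synthetic study used for validating the 22-model suite.
#' Twelve regions sit in three spatially interleaved rows on a
#' grassland-dominated mosaic; each row's neighboring anchors are linked
#' by narrow corridors of a single woody-substrate cover (row 1
#' cultivated, row 2 developed, row 3 forest/shrub), with no corridors
#' between rows. Gene flow is simulated over the hypothesis-B (developed +
#' cultivated + forest permeable) surface of this landscape, so every row
#' is internally well connected while rows are mutually isolated. Each
#' single-cover hypothesis then mispredicts two of the three rows, and
#' plain geographic distance cannot reproduce the row-block structure
#' (between-row and within-row separations overlap), which makes the
#' generating hypothesis identifiable from the model ranking. Migration
#' decay is steep (`lambda = 50`) because two-level effective resistances
#' on a permeable background span only ~0.15 units: migration must e-fold
#' well inside that span for the corridor network, rather than raw
#' proximity, to govern gene flow.
#'
#' @param seed master seed.
#' @param deme_size,n_generations,philopatry,n_sample_per_site forwarded
#'   to [sim_config()] (defaults: 50, 150, 0.5, 12).
#' @return list: `cfg`, `raster` (corridor landscape), `surface_true`
#'   (hypothesis B at 0.1/0.9), `points` (collection-point table), and
#'   `resist_true` (precomputed anchor resistance matrix, so replicated
#'   simulations skip the Laplacian solve).
#' @export
make_ibr_scenario <- function(seed = 1, deme_size = 50,
                              n_generations = 150, philopatry = 0.5,
                              n_sample_per_site = 12) {
  cfg <- sim_config(n_regions = 12, n_transect_regions = 0,
                    deme_size = deme_size, n_generations = n_generations,
                    philopatry = philopatry, lambda = 50,
                    migration_total = 0.25,
                    n_sample_per_site = n_sample_per_site,
                    raster_rows = 40, raster_cols = 40, cell_size_m = 210,
                    block_cells = 5,
                    cover_proportions = c(developed = 0, cultivated = 0,
                                          forest_shrub = 0,
                                          grassland = 0.85, other = 0.15),
                    seed = seed)
  xs <- c(1.2, 3.2, 5.2, 7.2) * 1000
  ys <- c(1.7, 4.2, 6.7) * 1000
  pts <- do.call(rbind, lapply(1:3, function(r) data.frame(
    site_id = sprintf("R%02d", (r - 1) * 4 + 1:4),
    region_id = sprintf("R%02d", (r - 1) * 4 + 1:4),
    x = xs, y = ys[r], transect_offset_m = NA_real_,
    stringsAsFactors = FALSE)))
  pts <- cbind(pts, metric_to_lonlat(pts$x, pts$y))
  row_cover <- c("cultivated", "developed", "forest_shrub")
  legs <- do.call(rbind, lapply(1:3, function(r) data.frame(
    x1 = xs[-4], y1 = ys[r], x2 = xs[-1], y2 = ys[r],
    group = row_cover[r], width_m = 2 * cfg$cell_size_m,
    stringsAsFactors = FALSE)))
  raster <- generate_landscape(cfg, corridors = legs)
  surface_true <- reclassify(raster, default_class_groups(),
                             hypothesis_set(0.1, 0.9)$B)
  resist_true <- resistance_distance(
    surface_true, data.frame(site_id = pts$region_id, x = pts$x, y = pts$y))
  list(cfg = cfg, raster = raster, surface_true = surface_true,
       points = pts, resist_true = resist_true)
}

#' Build and write a small end-to-end fixture bundle
#'
#' Four regions (one with a 5-point transect at 300 m spacing), 4 loci, a
#' 40 x 40 block-mosaic raster: small enough that the whole pipeline runs
#' in well under a minute, written in the same plain-text formats the
#' pipeline reads (GenAlEx CSV, site CSV, .asc raster, truth sidecar).
#' Regenerating with the same seed is byte-identical.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed); NULL skips writing.
#' @return list: `table`, `sites`, `truth`, `raster`, `cfg`, and (when
#'   written) `paths`.
#' @export
make_fixture_small <- function(seed = 1, dir = NULL) {
  cfg <- sim_config(n_regions = 4, n_transect_regions = 1,
                    deme_size = 30, n_loci = 4, n_generations = 30,
                    n_sample_per_site = 7, raster_rows = 40,
                    raster_cols = 40, cell_size_m = 210, block_cells = 5,
                    seed = seed)
  raster <- generate_landscape(cfg)
  surface <- reclassify(raster, default_class_groups(),
                        hypothesis_set()$B)
  sim <- simulate_genotypes(cfg, surface)
  out <- c(sim, list(raster = raster, cfg = cfg))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genotypes = file.path(dir, "genotypes.csv"),
      sites = file.path(dir, "sites.csv"),
      raster = file.path(dir, "landcover.asc"),
      truth = file.path(dir, "truth.txt"))
    write_genalex(sim$table, paths$genotypes, title = "synthetic fixture")
    utils::write.csv(sim$sites, paths$sites, row.names = FALSE)
    write_asc(raster, paths$raster)
    tr <- sim$truth
    writeLines(c(paste0("hypothesis=", tr$hypothesis),
                 paste0("lambda=", tr$lambda),
                 paste0("philopatry=", tr$philopatry),
                 paste0("seed=", tr$seed),
                 paste0("migration=",
                        paste(signif(tr$migration, 8), collapse = ","))),
               paths$truth)
    out$paths <- paths
  }
  out
}
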