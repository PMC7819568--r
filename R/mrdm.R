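#' Multiple regression on distance matrices (MRDM)
#'
#' Unfolds the strict lower triangles of the response and predictor
#' matrices, fits OLS with an intercept, and assesses significance by
#' permuting rows and columns of the response matrix simultaneously
#' `n_perm` times (the Mantel-style null preserving the predictor
#' structure): `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`, with ties
#' counting toward the tail; per-coefficient p-values use |t| analogously.
#' Predictors are z-standardized over the unfolded vector by default so
#' coefficients are comparable across units (km vs resistance); set
#' `standardize = FALSE` for raw coefficients.
#'
#' @param response a `dist_matrix`.
#' @param predictors named list of `dist_matrix` objects sharing the
#'   response's labels and order.
#' @param n_perm number of response permutations (0 skips the test).
#' @param seed integer seed.
#' @param standardize z-standardize unfolded predictors (default TRUE).
#' @param label model label carried into the result.
#' @return object of class `mrdm_result`: `coefficients` (with per-coef
#'   permutation p), `r_squared`, `f_statistic`, `p_value`, `n_pairs`,
#'   `n_perm`, `seed`, `label`.
#' @export
mrdm <- function(response, predictors, n_perm = 10000, seed = 1,
                 standardize = TRUE, label = "mrdm") {
  if (!is.list(predictors)) predictors <- list(predictor = predictors)
  labs <- rownames(response)
  s <- length(labs)
  if (s < 4) stop("MRDM needs >= 4 sites")
  for (pm in predictors) {
    if (!identical(rownames(pm), labs)) {
      stop("predictor labels do not match response labels")
    }
  }
  y <- unfold_lower(unclass(response))
  if (stats::var(y) == 0) {
    stop("zero-variance response matrix; nothing to test")
  }
  Xp <- vapply(predictors, function(m) unfold_lower(unclass(m)),
               numeric(length(y)))
  if (is.null(dim(Xp))) Xp <- matrix(Xp, ncol = 1)
  if (standardize) Xp <- scale(Xp)
  q <- ncol(Xp)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, Xp)
  XtXi <- solve(crossprod(X))
  A <- XtXi %*% t(X)                          # coef = A y
  H <- X %*% A                                # hat matrix (n small)
  fit_stats <- function(yv) {
    coefs <- drop(A %*% yv)
    res <- yv - drop(H %*% yv)
    rss <- sum(res^2)
    tss <- sum((yv - mean(yv))^2)
    r2 <- 1 - rss / tss
    f <- (r2 / q) / ((1 - r2) / (n - q - 1))
    sigma2 <- rss / (n - q - 1)
    tvals <- coefs / sqrt(sigma2 * diag(XtXi))
    list(coefs = coefs, r2 = r2, f = f, t = tvals)
  }
  obs <- fit_stats(y)
  p_f <- NA_real_
  p_t <- rep(NA_real_, q + 1)
  if (n_perm > 0) {
    hits_f <- 0L
    hits_t <- integer(q + 1)
    ym <- unclass(response)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        pi <- sample(s)
        yp <- unfold_lower(ym[pi, pi])
        st <- fit_stats(yp)
        if (st$f >= obs$f) hits_f <- hits_f + 1L
        hits_t <- hits_t + (abs(st$t) >= abs(obs$t))
      }
    })
    p_f <- (1 + hits_f) / (n_perm + 1)
    p_t <- (1 + hits_t) / (n_perm + 1)
  }
  coef_tab <- data.frame(term = colnames(X), estimate = obs$coefs,
                         t = obs$t, p_perm = p_t, row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(label = label, coefficients = coef_tab,
                 r_squared = obs$r2, f_statistic = obs$f, p_value = p_f,
                 n_pairs = n, n_perm = n_perm, seed = seed,
                 standardized = standardize),
            class = "mrdm_result")
}

#' @export
print.mrdm_result <- function(x, ...) {
  cat("MRDM [", x$label, "]: F = ", signif(x$f_statistic, 5),
      ", R^2 = ", signif(x$r_squared, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_pairs, " pairs, ", x$n_perm, " permutations)\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Run the isolation-by-distance / isolation-by-resistance model suite
#'
#' Fits 22 single-predictor MRDM models of mean between-site genetic
#' distance: two isolation-by-distance models (geographic distance over all
#' sites; geographic distance over the subset of sites > 1 km apart, i.e.
#' dropping interior transect points and keeping the two transect-end
#' sites) and one isolation-by-resistance model per resistance surface
#' (normally the 20-surface suite of [build_surface_suite()]).
#'
#' @param genetic_site_matrix site-level genetic `dist_matrix` (bruvo).
#' @param geo_matrix site-level geographic `dist_matrix` (km).
#' @param surfaces named list of `resistance_surface` objects.
#' @param points data frame `site_id`, `x`, `y` (meters in raster
#'   coordinates) for [resistance_distance()].
#' @param sites site metadata (`site_id`, `region_id`,
#'   `transect_offset_m`) used to pick the transect-end subset.
#' @param n_perm permutations per model.
#' @param seed integer seed (one child seed per model).
#' @return data frame sorted by decreasing F: model, hypothesis, low, high,
#'   F, R^2, p, coefficient, n_sites; full `mrdm_result` objects in
#'   attribute `"models"`.
#' @export
run_model_suite <- function(genetic_site_matrix, geo_matrix, surfaces,
                            points, sites, n_perm = 10000, seed = 1) {
  labs <- rownames(genetic_site_matrix)
  if (!identical(sort(labs), sort(rownames(geo_matrix)))) {
    stop("genetic and geographic matrices must cover the same sites")
  }
  geo_matrix <- dist_matrix(unclass(geo_matrix)[labs, labs], labs, "km")
  models <- list()
  rows <- list()
  add <- function(name, fit, hyp = NA, low = NA, high = NA) {
    models[[name]] <<- fit
    rows[[name]] <<- data.frame(
      model = name, hypothesis = hyp, low = low, high = high,
      F = fit$f_statistic, R2 = fit$r_squared, p = fit$p_value,
      coefficient = fit$coefficients$estimate[2],
      n_sites = (1 + sqrt(1 + 8 * fit$n_pairs)) / 2,
      stringsAsFactors = FALSE)
  }
  add("IBD_all",
      mrdm(genetic_site_matrix, list(geographic = geo_matrix),
           n_perm = n_perm, seed = child_seed(seed, "IBD_all"),
           label = "IBD_all"))
  far <- transect_end_sites(sites)
  far <- intersect(labs, far)
  if (length(far) >= 4) {
    gsub_ <- dist_matrix(unclass(genetic_site_matrix)[far, far], far, "bruvo")
    geos <- dist_matrix(unclass(geo_matrix)[far, far], far, "km")
    add("IBD_far",
        mrdm(gsub_, list(geographic = geos), n_perm = n_perm,
             seed = child_seed(seed, "IBD_far"), label = "IBD_far"))
  }
  for (nm in names(surfaces)) {
    rd <- resistance_distance(surfaces[[nm]], points)
    rd <- dist_matrix(unclass(rd)[labs, labs], labs, "resistance")
    fit <- mrdm(genetic_site_matrix, list(resistance = rd),
                n_perm = n_perm, seed = child_seed(seed, nm), label = nm)
    pr <- surfaces[[nm]]$provenance
    add(nm, fit, hyp = pr$hypothesis, low = pr$low, high = pr$high)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$F), ]
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

# sites > 1 km apart: per region, drop interior transect points, keeping
# the transect ends (min and max offset); non-transect sites kept as-is
transect_end_sites <- function(sites) {
  keep <- logical(nrow(sites))
  for (rg in unique(sites$region_id)) {
    idx <- which(sites$region_id == rg)
    off <- sites$transect_offset_m[idx]
    if (length(idx) == 1 || all(is.na(off))) {
      keep[idx] <- TRUE
    } else {
      off[is.na(off)] <- 0
      keep[idx[which.min(off)]] <- TRUE
      keep[idx[which.max(off)]] <- TRUE
    }
  }
  sites$site_id[keep]
}
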