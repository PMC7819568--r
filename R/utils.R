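# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic per-stage child seeds below 2^31 (Lehmer-style mix kept in
# double range < 2^53 so the arithmetic is exact)
child_seed <- function(master, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer(((as.numeric(master) %% 2147483647) * 16807 + h * 131) %%
               2147483647)
}

#' Labelled symmetric distance matrix with a units tag
#'
#' The currency passed between pipeline stages. Enforces symmetry (within
#' 1e-12 of the magnitude), an exactly-zero diagonal, and a units tag from
#' `bruvo` (genetic, in \[0,1\]), `km` (great-circle geographic), or
#' `resistance` (effective resistance).
#'
#' @param values square numeric matrix.
#' @param labels ordered ids (default: rownames of `values`).
#' @param units one of `"bruvo"`, `"km"`, `"resistance"`.
#' @return a `dist_matrix`: the matrix with `units` attribute.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        units = c("bruvo", "km", "resistance")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) stop("distance matrix needs labels")
  scale <- max(abs(values), 1, na.rm = TRUE)
  asym <- abs(values - t(values))
  if (any(asym > 1e-12 * scale, na.rm = TRUE) ||
      any(is.na(values) != t(is.na(values)))) {
    stop("distance matrix not symmetric")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, units = units, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", attr(x, "units"), "): ", nrow(x), " x ", ncol(x),
      "\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

dist_units <- function(x) attr(x, "units")

# strict lower triangle of a labelled square matrix, unfolded column-major
unfold_lower <- function(m) m[lower.tri(m)]

#' Write / read a labelled distance matrix as CSV
#'
#' The units tag travels in a `# units:` comment line above the header.
#'
#' @param x a `dist_matrix`. @param path file path.
#' @return `path` (write) or a `dist_matrix` (read).
#' @export
write_dist_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", attr(x, "units")), con)
  utils::write.csv(as.data.frame(unclass(x)), con, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  first <- readLines(path, n = 1)
  units <- sub("^# units: *", "", first)
  m <- as.matrix(utils::read.csv(path, comment.char = "#", row.names = 1,
                                 check.names = FALSE))
  dist_matrix(m, rownames(m), units)
}
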