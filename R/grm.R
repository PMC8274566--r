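#' Filter dominant markers by minor allele frequency
#'
#' For dominant presence/absence markers the only observable allele frequency
#' is the presence frequency `p`; the minor allele frequency is
#' `min(p, 1 - p)`. Markers with MAF below `maf_min` are removed (the
#' boundary is inclusive: a marker with MAF exactly `maf_min` is kept), so
#' monomorphic markers are always dropped for any positive threshold.
#' Marker order is preserved.
#'
#' @param markers lines x markers matrix with entries in \{0, 1\}.
#' @param maf_min minimum minor allele frequency to retain (default 0.05).
#' @param quiet suppress the before/after count message.
#' @return the filtered marker matrix (same class, columns subset).
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 1,   0, 1, 0, 1,   1, 1, 1, 0), ncol = 3)
#' colnames(m) <- c("mono", "p50", "p75")
#' colnames(filter_markers(m, 0.05))
filter_markers <- function(markers, maf_min = 0.05, quiet = FALSE) {
  stopifnot(is.matrix(markers))
  if (any(!markers %in% c(0, 1)))
    stopf("filter_markers: marker matrix must be strictly 0/1")
  p <- colMeans(markers)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  if (!any(keep))
    stopf("filter_markers: no markers pass MAF >= %g; lower the threshold",
          maf_min)
  if (!quiet)
    gs_log("INFO", sprintf("MAF filter (>= %g): %d of %d markers retained",
                           maf_min, sum(keep), ncol(markers)))
  markers[, keep, drop = FALSE]
}

#' Genomic relationship matrix from centered, standardized markers
#'
#' Computes `G = W W' / m` where `W` is the marker matrix with each column
#' centered and scaled to unit variance, and `m` is the number of (non
#' zero-variance) columns used. Scaling uses the population standard
#' deviation (denominator `n`), which makes `trace(G)/n = 1` an exact
#' algebraic identity. Zero-variance columns are excluded with a warning.
#' The construction is invariant to flipping the 0/1 orientation of any
#' marker, so the dominant coding direction does not matter.
#'
#' @param markers lines x markers numeric matrix (typically 0/1 after
#'   [filter_markers()]); rownames are line ids.
#' @return object of class `grm`: the n x n relationship matrix with
#'   attributes `m` (markers used), `center` and `scale` (the per-column
#'   statistics of the retained markers).
#' @export
#' @examples
#' G <- build_grm(matrix(c(1, 0, 0, 1), 2, 2,
#'                dimnames = list(c("A", "B"), NULL)))
#' G
build_grm <- function(markers) {
  stopifnot(is.matrix(markers))
  if (nrow(markers) < 2L) stopf("build_grm: need >= 2 lines")
  n <- nrow(markers)
  ctr <- colMeans(markers)
  sdv <- sqrt(colMeans(markers^2) - ctr^2)  # population sd
  poly <- sdv > 0
  if (!any(poly)) stopf("build_grm: no polymorphic markers")
  if (!all(poly))
    warning(sprintf("build_grm: %d zero-variance markers excluded",
                    sum(!poly)), call. = FALSE)
  W <- sweep(sweep(markers[, poly, drop = FALSE], 2, ctr[poly]), 2,
             sdv[poly], "/")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(markers), rownames(markers))
  structure(G, m = ncol(W), center = ctr[poly], scale = sdv[poly],
            class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d lines, %d markers\n",
              nrow(x), attr(x, "m")))
  cat(sprintf("  mean diagonal %.4f, off-diagonal range [%.3f, %.3f]\n",
              mean(diag(x)), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

## ridge-stabilized copy used before any solve involving G
stabilize_grm <- function(G, ridge = 1e-6) {
  G2 <- unclass(G)
  diag(G2) <- diag(G2) + ridge
  G2
}
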