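#' Signed Mann-Whitney z-score between two groups
#'
#' Normal approximation to the Mann-Whitney U statistic with mid-ranks and
#' tie-corrected variance, no continuity correction. The sign is positive
#' when group `b` is stochastically larger than group `a`. Zero-variance
#' comparisons (all values identical) return z = 0.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @return signed z-score.
#' @export
mann_whitney_z <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    .stopf("mann_whitney_z: each group needs >= 2 values")
  .mw_z(c(a, b), length(a), length(b))
}

# core on the concatenated vector; nA values first
.mw_z <- function(x, nA, nB) {
  N <- nA + nB
  r <- rank(x)
  U <- sum(r[(nA + 1L):N]) - nB * (nB + 1) / 2
  mu <- nA * nB / 2
  t <- tabulate(match(x, unique(x)))
  sigma2 <- (nA * nB / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(0)
  (U - mu) / sqrt(sigma2)
}

#' Voxelwise Mann-Whitney group-difference map
#'
#' Applies [mann_whitney_z()] independently at every voxel of two groups of
#' registered ratio volumes, producing a signed z volume and a two-sided
#' p-value volume (normal approximation). Positive z means group B (mutant /
#' treated) has higher values at that voxel.
#'
#' @param group_a,group_b lists of 3D numeric arrays of identical dimensions
#'   (>= 3 per group).
#' @return object of class `zmap`: list with 3D arrays `z` and `p`, group
#'   sizes, and `sig_mask`/`fdr_q` slots filled by [apply_fdr()].
#' @export
voxelwise_map <- function(group_a, group_b) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    .stopf("voxelwise_map: need >= 3 stacks per group")
  dims <- dim(group_a[[1]])
  for (v in c(group_a, group_b))
    if (!identical(dim(v), dims))
      .stopf("voxelwise_map: stack dimensions differ")
  nA <- length(group_a); nB <- length(group_b)
  X <- cbind(vapply(group_a, as.vector, numeric(prod(dims))),
             vapply(group_b, as.vector, numeric(prod(dims))))
  z <- apply(X, 1L, .mw_z, nA = nA, nB = nB)
  p <- 2 * pnorm(-abs(z))
  p[z == 0] <- 1
  structure(list(z = array(z, dims), p = array(p, dims),
                 n_a = nA, n_b = nB, fdr_q = NULL, sig_mask = NULL),
            class = "zmap")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up BH procedure over all p-values: with `m` voxels and sorted
#' p-values, the largest `k` with `p_(k) <= k * q / m` fixes the rejection
#' set (the `k` smallest p-values).
#'
#' @param p numeric vector or array of p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return logical vector/array of the same shape, `TRUE` for rejected
#'   (significant) entries.
#' @export
fdr_mask <- function(p, q) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("fdr_mask: p-values outside [0, 1]")
  if (q <= 0 || q >= 1) .stopf("fdr_mask: q must lie in (0, 1)")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  if (!is.null(dim(p))) dim(rej) <- dim(p)
  rej
}

#' Attach an FDR significance mask to a z-map
#'
#' @param zmap a [voxelwise_map()] result.
#' @param q FDR level (the mapping analysis uses q = 0.00005).
#' @return the `zmap` with `sig_mask` and `fdr_q` filled in.
#' @export
apply_fdr <- function(zmap, q = 5e-5) {
  stopifnot(inherits(zmap, "zmap"))
  zmap$sig_mask <- fdr_mask(zmap$p, q)
  zmap$fdr_q <- q
  zmap
}

#' @export
print.zmap <- function(x, ...) {
  nsig <- if (is.null(x$sig_mask)) NA_integer_ else sum(x$sig_mask)
  cat(sprintf("<zmap %s: n=%d vs %d, fdr_q=%s, %s significant voxels>\n",
              paste(dim(x$z), collapse = "x"), x$n_a, x$n_b,
              ifelse(is.null(x$fdr_q), "unset", format(x$fdr_q)),
              ifelse(is.na(nsig), "?", nsig)))
  invisible(x)
}

#' ROI signal summary from a masked z-map
#'
#' The headline `signal` is the sum of |z| over significant voxels of the
#' dominant sign inside the ROI (the sign carrying the larger total |z|);
#' the literal mean z over significant ROI voxels and the significant-voxel
#' count are reported alongside.
#'
#' @param zmap a `zmap` with a significance mask (see [apply_fdr()]).
#' @param roi logical 3D array, same dimensions as the map, with >= 1 `TRUE`
#'   voxel.
#' @return list with `signal`, `mean_z`, `n_sig`, `dominant_sign`.
#' @export
roi_signal <- function(zmap, roi) {
  stopifnot(inherits(zmap, "zmap"))
  if (is.null(zmap$sig_mask)) .stopf("roi_signal: run apply_fdr() first")
  if (!identical(dim(roi), dim(zmap$z))) .stopf("roi_signal: ROI shape mismatch")
  if (!any(roi)) .stopf("roi_signal: empty ROI")
  sig <- zmap$sig_mask & roi
  if (!any(sig))
    return(list(signal = 0, mean_z = NA_real_, n_sig = 0L, dominant_sign = NA_integer_))
  zs <- zmap$z[sig]
  pos <- sum(abs(zs[zs > 0])); neg <- sum(abs(zs[zs < 0]))
  list(signal = max(pos, neg),
       mean_z = mean(zs),
       n_sig = sum(sig),
       dominant_sign = if (pos >= neg) 1L else -1L)
}

#' Relative enrichment of significant signal in an anatomical label
#'
#' Ratio of significant-|z| density (sum of |z| over significant voxels per
#' voxel of the mask) within the label to that within the whole brain mask;
#' values > 1 indicate relative enrichment of the group difference in the
#' label.
#'
#' @param zmap a masked `zmap`.
#' @param label logical 3D array, subset of `brain`.
#' @param brain logical 3D array covering the brain.
#' @return numeric enrichment ratio, or `NA` if there is no significant
#'   signal brain-wide.
#' @export
label_enrichment <- function(zmap, label, brain) {
  stopifnot(inherits(zmap, "zmap"))
  if (is.null(zmap$sig_mask)) .stopf("label_enrichment: run apply_fdr() first")
  if (!identical(dim(label), dim(zmap$z)) || !identical(dim(brain), dim(zmap$z)))
    .stopf("label_enrichment: mask shape mismatch")
  if (any(label & !brain)) .stopf("label_enrichment: label must lie within brain")
  if (!any(label) || !any(brain)) .stopf("label_enrichment: empty mask")
  dens <- function(mask) sum(abs(zmap$z[zmap$sig_mask & mask])) / sum(mask)
  db <- dens(brain)
  if (db == 0) return(NA_real_)
  dens(label) / db
}
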