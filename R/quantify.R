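#' Background-corrected fluorescence
#'
#' Total corrected fluorescence is
#' `integrated_density - roi_area * background_mean`; it is reported both as
#' a total and normalized per unit brain area.
#'
#' @param integrated_density ROI integrated density (AU).
#' @param roi_area ROI area (pixel^2, > 0).
#' @param background_mean mean background fluorescence (AU per pixel).
#' @param brain_area total brain area (pixel^2, > 0).
#' @return list with `total` (AU) and `per_area` (AU / pixel^2); vectorized.
#' @export
corrected_fluorescence <- function(integrated_density, roi_area,
                                   background_mean, brain_area) {
  if (any(roi_area <= 0) || any(brain_area <= 0))
    .stopf("corrected_fluorescence: areas must be > 0")
  if (any(integrated_density < 0))
    .stopf("corrected_fluorescence: integrated density must be >= 0")
  total <- integrated_density - roi_area * background_mean
  list(total = total, per_area = total / brain_area)
}

#' Average technical replicates
#'
#' Arithmetic mean of back-calculated concentrations; the assay protocol
#' averages three technical replicates per sample, so other counts trigger a
#' warning.
#'
#' @param values numeric vector of replicate concentrations (>= 1).
#' @return the mean.
#' @export
average_replicates <- function(values) {
  if (length(values) == 0L) .stopf("average_replicates: no values")
  if (length(values) != 3L)
    warning(sprintf("average_replicates: expected 3 technical replicates, got %d",
                    length(values)), call. = FALSE)
  mean(values)
}

# "+/-;-/-" -> list(a = c("+","-"), b = c("-","-"))
.parse_genotype2 <- function(g) {
  parts <- strsplit(g, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    .stopf("genotype '%s' must have two loci separated by ';'", g)
  loci <- lapply(parts, function(p) {
    al <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (length(al) != 2L || !all(al %in% c("+", "-")))
      .stopf("malformed locus genotype '%s' (expected e.g. '+/-')", p)
    al
  })
  names(loci) <- c("a", "b")
  loci
}

# canonical locus form by mutant-allele count (locale-independent)
.canon_locus <- function(al) c("+/+", "+/-", "-/-")[sum(al == "-") + 1L]

#' Expected offspring genotype ratios for a two-locus cross
#'
#' Enumerates gametes per parent assuming independent loci and Mendelian
#' segregation, combines them, and returns offspring two-locus genotype
#' probabilities. The screening cross `+/-;-/-  x  -/-;+/-` yields four
#' mutant genotype classes at 25% each.
#'
#' @param parent1,parent2 two-locus genotype strings like `"+/-;-/-"`
#'   (alleles `+` or `-` at each locus, loci separated by `;`).
#' @return named numeric vector of offspring genotype probabilities (names
#'   like `"+/-;-/-"`), summing to 1.
#' @export
punnett_expected <- function(parent1, parent2) {
  p1 <- .parse_genotype2(parent1)
  p2 <- .parse_genotype2(parent2)
  gametes <- function(p) {
    g <- expand.grid(a = p$a, b = p$b, stringsAsFactors = FALSE)
    g$prob <- 1 / nrow(g)
    g
  }
  g1 <- gametes(p1); g2 <- gametes(p2)
  out <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2))) {
    lab <- paste(.canon_locus(c(g1$a[i], g2$a[j])),
                 .canon_locus(c(g1$b[i], g2$b[j])), sep = ";")
    prev <- if (is.null(out[[lab]])) 0 else out[[lab]]
    out[[lab]] <- prev + g1$prob[i] * g2$prob[j]
  }
  res <- unlist(as.list(out))
  res[order(names(res))]
}

#' Classifier positive and negative predictive value
#'
#' PPV = 100 * tp / (tp + fp); NPV = 100 * tn / (tn + fn). Used to validate
#' phenotype-based genotype classification (e.g. hyperpigmentation calling of
#' double-homozygous mutants) against post hoc genotyping. A metric whose
#' denominator is zero is reported as `NA`.
#'
#' @param tp,fp,fn,tn non-negative integer confusion counts (total > 0).
#' @return named numeric `c(ppv, npv)` in percent.
#' @export
classifier_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    .stopf("classifier_metrics: counts must be non-negative integers")
  if (sum(counts) == 0) .stopf("classifier_metrics: all counts are zero")
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  c(ppv = ppv, npv = npv)
}
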