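#' Control distribution for a screen readout
#'
#' Pools the non-treated control group averages across experimental days into
#' one distribution per readout; its sample mean and sample standard
#' deviation (denominator n - 1) drive all z-scores.
#'
#' @param group_means numeric vector of per-group control averages (>= 2).
#' @param readout readout label, e.g. `"habituation_41_50"`.
#' @return object of class `control_distribution` with fields `readout`,
#'   `group_means`, `mean`, `sd`, `n_groups`.
#' @export
control_distribution <- function(group_means, readout = "readout") {
  group_means <- as.numeric(group_means)
  group_means <- group_means[!is.na(group_means)]
  if (length(group_means) < 2L)
    .stopf("control_distribution: need >= 2 control group averages")
  s <- sd(group_means)
  if (!is.finite(s) || s == 0)
    .stopf("control_distribution: degenerate controls (sd = 0)")
  structure(list(readout = readout, group_means = group_means,
                 mean = mean(group_means), sd = s,
                 n_groups = length(group_means)),
            class = "control_distribution")
}

#' @export
print.control_distribution <- function(x, ...) {
  cat(sprintf("<control_distribution '%s': n_groups=%d mean=%.3f sd=%.3f>\n",
              x$readout, x$n_groups, x$mean, x$sd))
  invisible(x)
}

#' Fit a Gaussian to a control histogram (display only)
#'
#' Nonlinear least-squares fit of `a * exp(-(x - mu)^2 / (2 * sigma^2))` to
#' the histogram of control group means, for plotting alongside the
#' distribution. The fit never feeds into z-scores, which always use the
#' sample mean/SD of [control_distribution()].
#'
#' @param control a `control_distribution`.
#' @param bins histogram bin count.
#' @return named numeric `c(a, mu, sigma)`, or `NULL` if the fit fails.
#' @export
fit_control_gaussian <- function(control, bins = 15) {
  stopifnot(inherits(control, "control_distribution"))
  h <- graphics::hist(control$group_means, breaks = bins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- try(stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
                        start = list(a = max(df$y), mu = control$mean,
                                     sigma = control$sd)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  co <- stats::coef(fit)
  c(a = unname(co["a"]), mu = unname(co["mu"]), sigma = abs(unname(co["sigma"])))
}

#' Compound z-score against the control distribution
#'
#' `z = (mean treated value - mean control value) / (control SD)`.
#'
#' @param treated_mean treated group mean(s) for the readout.
#' @param control a [control_distribution()].
#' @return numeric z-score(s).
#' @export
zscore <- function(treated_mean, control) {
  stopifnot(inherits(control, "control_distribution"))
  (treated_mean - control$mean) / control$sd
}

#' One-sided standard-normal critical value
#'
#' The screening threshold is the upper standard-normal quantile at
#' `1 - alpha`; at `alpha = 0.01` this is 2.326, the one-tailed 99% cut-off.
#'
#' @param alpha_one_sided one-sided tail probability in (0, 1).
#' @return the threshold.
#' @export
critical_value <- function(alpha_one_sided) {
  if (!is.numeric(alpha_one_sided) || length(alpha_one_sided) != 1L ||
      is.na(alpha_one_sided) || alpha_one_sided <= 0 || alpha_one_sided >= 1)
    .stopf("critical_value: alpha must lie strictly in (0, 1)")
  qnorm(1 - alpha_one_sided)
}

#' Call compound hits from z-scores
#'
#' Flags compounds whose z-score exceeds the one-sided critical value in the
#' beneficial direction. The comparison is inclusive (`z >= threshold` is a
#' hit) because the printed threshold is itself the rounded quantile.
#'
#' @param results `data.frame`/`data.table` with columns `compound_id` and
#'   `z`, or a bare numeric z vector.
#' @param direction `"increase"` (hit when `z >= threshold`) or `"decrease"`
#'   (hit when `z <= -threshold`).
#' @param alpha one-sided significance level (default 0.01).
#' @return The input table with a logical `hit` column added (for numeric
#'   input, a logical vector).
#' @export
call_hits <- function(results, direction = c("increase", "decrease"), alpha = 0.01) {
  direction <- match.arg(direction)
  thr <- critical_value(alpha)
  if (is.numeric(results)) {
    return(if (direction == "increase") results >= thr else results <= -thr)
  }
  dt <- as.data.table(results)
  if (!all(c("compound_id", "z") %in% names(dt)))
    .stopf("call_hits: results must have columns compound_id and z")
  dt[, hit := if (direction == "increase") z >= thr else z <= -thr]
  dt[]
}

#' One-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Upper-tail hypergeometric probability `P(X >= a)` with margins fixed, for
#' the table `rbind(c(a, b), c(c, d))` = (hits in class, hits outside class;
#' non-hits in class, non-hits outside class).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return one-sided p-value for enrichment of hits in the class.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    .stopf("fisher_exact_2x2: counts must be non-negative integers")
  m <- a + c            # class size (white balls)
  n <- b + d            # outside class (black balls)
  k <- a + b            # hits drawn
  hi <- min(k, m)
  if (a > hi) return(0)
  p <- sum(dhyper(a:hi, m, n, k))
  min(p, 1)
}

#' Target-class enrichment among screen hits
#'
#' For every target class in the library, builds the 2x2 table of hit/non-hit
#' by in/out of class and computes the one-sided Fisher exact p-value for
#' enrichment. Raw p-values are compared to `alpha` (no multiple-testing
#' correction by default; `p_adjust = "BH"` is available).
#'
#' @param hits character vector of hit compound ids (subset of the library).
#' @param library `data.frame` with columns `compound_id`, `target_class`.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return `data.table` with columns `target_class`, `hits_in_class`,
#'   `hits_out`, `nonhits_in_class`, `nonhits_out`, `p_value`, `significant`.
#' @export
enrich_targets <- function(hits, library, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  lib <- as.data.table(library)
  if (!all(c("compound_id", "target_class") %in% names(lib)))
    .stopf("enrich_targets: library must have compound_id and target_class")
  unknown <- setdiff(hits, lib$compound_id)
  if (length(unknown))
    .stopf("enrich_targets: hit compound(s) not in library: %s",
           paste(head(unknown, 5), collapse = ", "))
  lib[, is_hit := compound_id %in% hits]
  classes <- sort(unique(lib$target_class))
  res <- rbindlist(lapply(classes, function(cl) {
    a <- lib[target_class == cl & is_hit == TRUE, .N]
    b <- lib[target_class != cl & is_hit == TRUE, .N]
    cc <- lib[target_class == cl & is_hit == FALSE, .N]
    d <- lib[target_class != cl & is_hit == FALSE, .N]
    data.table(target_class = cl, hits_in_class = a, hits_out = b,
               nonhits_in_class = cc, nonhits_out = d,
               p_value = fisher_exact_2x2(a, b, cc, d))
  }))
  if (p_adjust == "BH") res[, p_value := stats::p.adjust(p_value, "BH")]
  res[, significant := p_value < alpha]
  lib[, is_hit := NULL]
  res[]
}
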