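library(data.table)

# one larva's event table with SLCs / LLCs at the given stimulus indices,
# deterministic latencies and kinematics
make_larva_events <- function(schedule, slc_idx = integer(0), llc_idx = integer(0),
                              larva_id = "L1") {
  stopifnot(length(intersect(slc_idx, llc_idx)) == 0L)
  idx <- schedule$events$index
  cls <- rep("none", length(idx))
  cls[idx %in% slc_idx] <- "SLC"
  cls[idx %in% llc_idx] <- "LLC"
  responded <- cls != "none"
  data.table(
    larva_id = larva_id,
    stimulus_index = idx,
    responded = responded,
    response_class = cls,
    latency_ms = ifelse(!responded, NA_real_, ifelse(cls == "SLC", 8, 28)),
    turn_angle_deg = ifelse(responded, 120, NA_real_),
    max_ang_vel_deg_per_ms = ifelse(responded, 25, NA_real_),
    distance_mm = ifelse(responded, 1.5, NA_real_)
  )
}

# metadata for n untreated larvae of a single genotype
make_metas <- function(n, genotype_a = "+/-", genotype_b = "-/-",
                       prefix = "L") {
  data.frame(larva_id = sprintf("%s%04d", prefix, seq_len(n)),
             genotype_a = genotype_a, genotype_b = genotype_b)
}

## ---- independent oracles ---------------------------------------------------

# exact permutation-distribution z for the Mann-Whitney U statistic
mw_perm_oracle <- function(a, b) {
  x <- c(a, b)
  N <- length(x); nB <- length(b)
  r <- rank(x)
  combos <- utils::combn(N, nB)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - nB * (nB + 1) / 2)
  U_obs <- sum(r[(length(a) + 1L):N]) - nB * (nB + 1) / 2
  sd_pop <- sqrt(mean((Us - mean(Us))^2))
  if (sd_pop == 0) return(0)
  (U_obs - mean(Us)) / sd_pop
}

# one-sided Fisher p by direct log-binomial-coefficient enumeration
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(0)
  sum(exp(lchoose(m, a:hi) + lchoose(n, k - (a:hi)) - lchoose(m + n, k)))
}

# BH rejections straight from the step-up definition via p.adjust
bh_oracle <- function(p, q) stats::p.adjust(p, "BH") <= q

# Poisson-binomial pmf by iterative convolution (index i = P(Y = i - 1))
pb_pmf <- function(ps) {
  d <- 1
  for (p in ps) d <- c(d * (1 - p), 0) + c(0, d * p)
  d
}

# exact expectation of the habituation ratio statistic
# 100 * (1 - (Y/n_late)/(X/n_first)) over X ~ Bin(n_first, p_first) (X >= 1)
# and Y ~ Poisson-binomial(p_late), independent
hab_expectation_oracle <- function(p_first, p_late, n_first = 10) {
  n_late <- length(p_late)
  px <- stats::dbinom(0:n_first, n_first, p_first)
  py <- pb_pmf(p_late)
  e <- 0
  for (x in 1:n_first) {
    ey_stat <- sum(py * (100 * (1 - ((0:n_late) / n_late) / (x / n_first))))
    e <- e + px[x + 1] * ey_stat
  }
  e / (1 - px[1])
}

# two-locus Punnett oracle: per-locus offspring distributions, combined by
# locus independence (implementation enumerates whole gametes instead)
punnett_locus_oracle <- function(parent1, parent2) {
  split2 <- function(g) strsplit(strsplit(g, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
  canon <- function(al) c("+/+", "+/-", "-/-")[sum(al == "-") + 1L]
  p1 <- split2(parent1); p2 <- split2(parent2)
  locus_dist <- function(a1, a2) {
    labs <- c(outer(a1, a2, Vectorize(function(x, y) canon(c(x, y)))))
    tab <- table(labs) / length(labs)
    stats::setNames(as.numeric(tab), names(tab))
  }
  la <- locus_dist(p1[[1]], p2[[1]])
  lb <- locus_dist(p1[[2]], p2[[2]])
  out <- c(outer(la, lb))
  names(out) <- c(outer(names(la), names(lb), paste, sep = ";"))
  out <- tapply(out, names(out), sum)
  stats::setNames(as.numeric(out), names(out))[order(names(out))]
}
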