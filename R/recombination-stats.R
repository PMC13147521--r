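# Comparative statistics: crossover-class fractions with the MII detection
# adjustment, arm association, the two significance tests, coefficient of
# exchange, and the cross-chromosome crossover-count comparison.
#
# The z and Mann-Whitney statistics are implemented here (they are part of
# the reproduced analysis); stats::prop.test and stats::wilcox.test serve
# only as independent cross-checks in the test suite.

new_ndj_test <- function(statistic, p.value, estimate, n, method, alternative) {
  structure(list(statistic = statistic, p.value = p.value, estimate = estimate,
                 n = n, method = method, alternative = alternative),
            class = "ndj_test")
}

#' @export
print.ndj_test <- function(x, ...) {
  cat(sprintf("<ndj_test> %s (%s)\n  statistic = %.4g, p = %.4g, n = %s\n",
              x$method, x$alternative, x$statistic, x$p.value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for comparing `x1/n1` against `x2/n2`, with
#' an optional Yates continuity correction of `(1/n1 + 1/n2)/2` (capped at
#' the observed difference). With the correction on, the two-sided p-value
#' coincides with the Yates-corrected chi-square test on the 2x2 table; the
#' one-tailed p-value is the corresponding normal tail. The tail direction
#' must be supplied explicitly.
#'
#' @param x1,n1,x2,n2 Successes and trials per group.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param correct Apply the continuity correction (default TRUE, matching
#'   the conventional default of the R `prop.test` interface).
#' @return An `ndj_test` object with `statistic` (z), `p.value`, `estimate`
#'   (the two proportions) and group sizes.
#' @examples
#' two_proportion_z_test(14, 63, 6, 103, alternative = "greater")
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2,
                                  alternative = c("two.sided", "less", "greater"),
                                  correct = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  cc <- if (correct) min(abs(d), (1 / n1 + 1 / n2) / 2) else 0
  z <- if (se == 0) 0 else sign(d) * (abs(d) - cc) / se
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  p <- min(p, 1)
  new_ndj_test(z, p, c(p1 = p1, p2 = p2), c(n1, n2),
               sprintf("two-proportion z-test (%s continuity correction)",
                       if (correct) "with" else "without"),
               alternative)
}

#' Mann-Whitney rank-sum test
#'
#' The U statistic for `x` versus `y`. For small samples
#' (`length(x) + length(y) <= 12` by default) the p-value is exact, from
#' full enumeration of the permutation distribution of U over all
#' assignments of the pooled observations to the two groups (valid with
#' ties, since it conditions on the observed values); otherwise a normal
#' approximation with tie correction and continuity correction is used. The
#' two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x shifted below y) or
#'   `"greater"`.
#' @param exact Force exact enumeration on/off; `NULL` decides by total n.
#' @return An `ndj_test` object (`statistic` = U for `x`).
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # p = 0.05
#' @export
mann_whitney_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  m <- length(x); n <- length(y); N <- m + n
  if (is.null(exact)) exact <- N <= 12
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (exact) {
    idx_sets <- combn(N, m)
    offset <- m * (m + 1) / 2
    U_perm <- colSums(matrix(r[idx_sets], nrow = m)) - offset
    eps <- 1e-9
    p_less <- mean(U_perm <= U + eps)
    p_greater <- mean(U_perm >= U - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less, greater = p_greater)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    cc <- 0.5 * sign(U - mu)
    z <- if (sigma == 0) 0 else switch(alternative,
      two.sided = (U - mu - cc) / sigma,
      less = (U - mu + 0.5) / sigma,
      greater = (U - mu - 0.5) / sigma)
    p <- switch(alternative,
                two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
                less = pnorm(z),
                greater = pnorm(z, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "Mann-Whitney U (normal approximation, tie + continuity corrected)"
  }
  new_ndj_test(U, p, NULL, c(m, n), method, alternative)
}

#' Per-class crossover-count fractions with the MII detection adjustment
#'
#' Tabulates, per event class, the fraction of chromosome arms carrying 0, 1
#' or 2+ observable crossovers. Because a normal meiosis transmits one
#' chromatid of four and MI NDJ one chromatid per homolog, only half of
#' single crossovers are observable in those classes, whereas MII NDJ
#' progeny carry both sisters of one chromosome and reveal every
#' inter-homolog crossover. `adjust_mii` therefore halves the MII single-CO
#' fraction for equitable comparison; double-crossover fractions are not
#' adjusted, and the adjusted column is reported alongside the raw fractions
#' without renormalization.
#'
#' @param arm_counts data.frame with columns `class` (e.g. `"NORMAL"`,
#'   `"MI"`, `"MII"`) and `n_co` (observable crossovers on one arm of one
#'   event).
#' @param adjust_mii Apply the MII halving adjustment.
#' @return data.frame: `class`, `co_class` (`"0"`, `"1"`, `"2"` for 2+),
#'   `n_arms`, `fraction`, `fraction_adjusted`.
#' @export
co_class_fractions <- function(arm_counts, adjust_mii = TRUE) {
  stopifnot(all(c("class", "n_co") %in% names(arm_counts)))
  if (nrow(arm_counts) == 0) stop("empty class table")
  out <- list()
  for (cl in unique(arm_counts$class)) {
    sub <- arm_counts[arm_counts$class == cl, ]
    co <- pmin(sub$n_co, 2)
    tab <- table(factor(co, levels = 0:2))
    frac <- as.numeric(tab) / sum(tab)
    adj <- frac
    if (adjust_mii && cl == "MII") adj[2] <- adj[2] / 2
    out[[cl]] <- data.frame(class = cl, co_class = names(tab),
                            n_arms = as.integer(tab), fraction = frac,
                            fraction_adjusted = adj)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of events with zero observable crossovers chromosome-wide
#'
#' @param events data.frame with an `n_calls` column (chromosome-wide
#'   observable crossover calls per event).
#' @return Fraction in `[0, 1]`.
#' @export
zero_co_chromosome_fraction <- function(events) {
  if (nrow(events) == 0) stop("empty cohort")
  mean(events$n_calls == 0)
}

#' Association between left-arm and right-arm crossovers
#'
#' For each event class, tabulates the probability of at least one right-arm
#' crossover conditional on the left arm carrying zero versus one-or-more
#' crossovers.
#'
#' @param events data.frame with columns `class`, `left_co`, `right_co`
#'   (per-event arm crossover counts).
#' @return data.frame per class: `p_right_given_left0`, `n_left0`,
#'   `p_right_given_left1plus`, `n_left1plus`.
#' @export
arm_association <- function(events) {
  stopifnot(all(c("class", "left_co", "right_co") %in% names(events)))
  out <- lapply(unique(events$class), function(cl) {
    sub <- events[events$class == cl, ]
    g0 <- sub$right_co[sub$left_co == 0]
    g1 <- sub$right_co[sub$left_co >= 1]
    data.frame(class = cl,
               p_right_given_left0 = if (length(g0)) mean(g0 >= 1) else NA_real_,
               n_left0 = length(g0),
               p_right_given_left1plus = if (length(g1)) mean(g1 >= 1) else NA_real_,
               n_left1plus = length(g1))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binned coefficient of exchange
#'
#' Exchange (crossover) frequency per meiosis in fixed-width bins along each
#' arm, corrected for the fraction of chromatids sampled by the event class:
#' the correction factor is `1 / detection_probability(mode, 1)` — 2 for
#' single-chromatid (normal) and MI sampling, 1 for MII.
#'
#' @param calls Crossover calls with `arm` and `pos` (arm-local midpoints).
#' @param map A [chromosome_map()].
#' @param n_events Number of events assayed.
#' @param mode Segregation mode of the class (sets the detection correction).
#' @param bin_bp Bin width, bp.
#' @param detection_correction Apply the chromatid-sampling correction.
#' @return data.frame: `arm`, `bin_start`, `bin_end` (arm-local bp), `n_co`,
#'   `exchange` (crossovers per meiosis per bin).
#' @export
coefficient_of_exchange <- function(calls, map, n_events,
                                    mode = c("NORMAL", "MI_NDJ", "MII_NDJ"),
                                    bin_bp = 1e6, detection_correction = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_events > 0)
  factor_ <- if (detection_correction) 1 / detection_probability(mode, 1) else 1
  out <- lapply(arm_names(map), function(nm) {
    a <- get_arm(map, nm)
    breaks <- seq(0, ceiling(a$length / bin_bp) * bin_bp, by = bin_bp)
    mids <- calls$pos[calls$arm == nm & !is.na(calls$arm)]
    counts <- if (length(mids)) {
      tabulate(findInterval(mids, breaks, rightmost.closed = TRUE),
               nbins = length(breaks) - 1)
    } else {
      integer(length(breaks) - 1)
    }
    data.frame(arm = nm, bin_start = head(breaks, -1), bin_end = tail(breaks, -1),
               n_co = counts, exchange = counts / n_events * factor_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Crossover counts on the nondisjoined chromosome versus the rest of the genome
#'
#' Mann-Whitney comparisons of the mean crossover count on the other assayed
#' chromosomes between strata defined by the focal-chromosome crossover
#' count (0 vs 1, 1 vs 2, 0 vs 2). Restricted to MI events by default,
#' because the probability of observing a crossover on the focal chromosome
#' differs between MI and MII.
#'
#' @param events data.frame with columns `division`, `chr2_co` (focal-
#'   chromosome observable crossovers) and `other_mean_co` (mean crossover
#'   count over the other assayed chromosomes).
#' @param divisions Event classes retained (default `"MI"`).
#' @param tails Named tails per comparison; the one-tailed direction is that
#'   the higher focal-count stratum has more crossovers elsewhere.
#' @return Named list of `ndj_test` objects (comparisons with an empty
#'   stratum are reported as a character notice instead).
#' @export
cross_chromosome_co_comparison <- function(events, divisions = "MI",
                                           tails = c("0v1" = "two.sided",
                                                     "1v2" = "greater",
                                                     "0v2" = "greater")) {
  stopifnot(all(c("division", "chr2_co", "other_mean_co") %in% names(events)))
  sub <- events[events$division %in% divisions, ]
  strata <- list("0" = sub$other_mean_co[sub$chr2_co == 0],
                 "1" = sub$other_mean_co[sub$chr2_co == 1],
                 "2" = sub$other_mean_co[sub$chr2_co >= 2])
  pairs <- list("0v1" = c("0", "1"), "1v2" = c("1", "2"), "0v2" = c("0", "2"))
  out <- list()
  for (nm in names(pairs)) {
    lo <- strata[[pairs[[nm]][1]]]
    hi <- strata[[pairs[[nm]][2]]]
    if (length(lo) == 0 || length(hi) == 0) {
      out[[nm]] <- sprintf("skipped: empty stratum (n=%d vs n=%d)",
                           length(lo), length(hi))
      next
    }
    out[[nm]] <- mann_whitney_test(hi, lo, alternative = tails[[nm]])
  }
  out
}

#' Published comparison constants for normal meioses and X-chromosome NDJ
#'
#' Cohort-level summary values from the published comparison datasets, used
#' for display next to recomputed quantities (they are inputs, never
#' recomputed here): the zero-crossover chromosome fraction and arm
#' association of normal chromosome 2 meioses, and the MI/MII composition of
#' X-chromosome NDJ.
#'
#' @return Named list of reference constants.
#' @export
normal_meiosis_reference <- function() {
  list(
    zero_co_chromosome_fraction = 0.134,
    p_right_given_left1plus = 0.527, n_left1plus = 66,
    p_right_given_left0 = 0.667, n_left0 = 97,
    x_ndj = list(n = 103, mii = 6),
    chr2_ndj = list(n = 63, mii = 14)
  )
}
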