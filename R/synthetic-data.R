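# Forward simulation of female meiosis on a four-chromatid bivalent, the
# segregation classes observable in the compound-chromosome backcross, and
# pooled offspring sequencing.
#
# Chromatid representation: parental origin is anchored at the CENTROMERE.
# A crossover at axis position x exchanges the telomere-distal material, so
# the origin of a point p on a chromatid is the host homolog's origin XOR the
# parity of the chromatid's breakpoints lying strictly between p and the
# centromere. This is the frame in which "MI NDJ progeny are heterozygous
# across the centromere" and "MII NDJ progeny are homozygous across the
# centromere" hold by construction.

SEGREGATION_MODES <- c("NORMAL", "MI_NDJ", "MII_NDJ", "MONOSOMY_RESCUE")

#' Create a chromatid mosaic
#'
#' @param origin Parental origin at the centromere: `"P1"` (Oregon R-like) or
#'   `"P2"` (w1118-like).
#' @param breakpoints Sorted axis positions (bp) of parental-origin switches
#'   (crossover positions involving this chromatid).
#' @return An object of class `chromatid`.
#' @export
chromatid <- function(origin = c("P1", "P2"), breakpoints = numeric(0)) {
  origin <- match.arg(origin)
  breakpoints <- sort(as.numeric(breakpoints))
  if (anyDuplicated(breakpoints)) stop("duplicate breakpoint positions")
  structure(list(origin = origin, breakpoints = breakpoints), class = "chromatid")
}

#' Parental origin of a chromatid at given axis positions
#'
#' @param ch A [chromatid()].
#' @param pos Axis position(s), bp.
#' @param cen Centromere axis position (see [centromere_axis()]).
#' @return Character vector of `"P1"`/`"P2"`.
#' @export
origin_at <- function(ch, pos, cen) {
  br <- ch$breakpoints
  if (length(br) == 0) return(rep(ch$origin, length(pos)))
  # breakpoints strictly between pos and cen
  n_between <- abs(findInterval(cen, br) - findInterval(pos, br))
  flipped <- n_between %% 2 == 1
  other <- if (ch$origin == "P1") "P2" else "P1"
  ifelse(flipped, other, ch$origin)
}

is_recombinant <- function(ch) length(ch$breakpoints) > 0

#' Draw crossover count and positions for one meiosis
#'
#' Per-arm crossover counts are drawn independently from `co_count_dist`;
#' positions are drawn from the configured density over the arm (by default
#' uniform over the euchromatin, reflecting pericentric crossover
#' suppression) and never fall in the unassembled centromeric gap.
#'
#' @param map A [chromosome_map()].
#' @param co_count_dist Probabilities for 0, 1 and 2 crossovers per arm
#'   (numeric length 3, summing to 1).
#' @param density `"uniform_euchromatin"` (default) or `"uniform_arm"`; or
#'   supply `sampler`.
#' @param sampler Optional function `(map, arm, n)` returning `n` positions as
#'   distances from the telomere, overriding `density`.
#' @return data.frame with columns `arm`, `pos` (arm-local, assembly
#'   orientation), `axis` (chromosome-axis bp), sorted by `axis`.
#' @export
draw_crossovers <- function(map, co_count_dist = c(0.37, 0.53, 0.10),
                            density = c("uniform_euchromatin", "uniform_arm"),
                            sampler = NULL) {
  stopifnot(length(co_count_dist) == 3, all(co_count_dist >= 0),
            abs(sum(co_count_dist) - 1) < 1e-8)
  if (is.null(sampler)) {
    density <- match.arg(density)
    sampler <- function(map, arm, n) {
      a <- get_arm(map, arm)
      upper <- if (density == "uniform_euchromatin") a$het_boundary else a$length
      runif(n, 0, upper)
    }
  }
  rows <- lapply(arm_names(map), function(nm) {
    a <- get_arm(map, nm)
    k <- sample(0:2, 1, prob = co_count_dist)
    if (k == 0) return(NULL)
    d <- sampler(map, nm, k)  # distance from telomere
    pos <- if (a$orientation == "telomere_to_centromere") d else a$length - d
    data.frame(arm = nm, pos = pos, axis = arm_to_axis(map, nm, pos))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(arm = character(), pos = numeric(), axis = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$axis), , drop = FALSE]
}

#' Assemble a four-chromatid bivalent from a crossover list
#'
#' Each crossover is assigned to one of the four non-sister chromatid pairs,
#' uniformly and independently (no chromatid interference) unless `pairs` is
#' supplied; the reciprocal breakpoints are installed on both participating
#' chromatids.
#'
#' @param cos data.frame of crossovers with a column `axis` (axis positions,
#'   strictly distinct), e.g. from [draw_crossovers()].
#' @param pairs Optional integer matrix with one row per crossover and columns
#'   `s1`, `s2` in `{1, 2}`: which sister of homolog 1 and of homolog 2 takes
#'   part. Drawn uniformly when `NULL`.
#' @return An object of class `bivalent`: homolog 1 sisters (origin `"P1"`),
#'   homolog 2 sisters (origin `"P2"`), and the crossover table.
#' @export
build_bivalent <- function(cos, pairs = NULL) {
  n <- nrow(cos)
  if (n > 0 && anyDuplicated(cos$axis)) stop("duplicate crossover positions")
  if (is.null(pairs)) {
    pairs <- cbind(s1 = sample(1:2, n, replace = TRUE),
                   s2 = sample(1:2, n, replace = TRUE))
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(nrow(pairs) == n, all(pairs %in% 1:2))
    colnames(pairs) <- c("s1", "s2")
  }
  bp1 <- list(numeric(0), numeric(0))  # per sister of homolog 1
  bp2 <- list(numeric(0), numeric(0))
  if (n > 0) {
    for (i in seq_len(n)) {
      bp1[[pairs[i, "s1"]]] <- c(bp1[[pairs[i, "s1"]]], cos$axis[i])
      bp2[[pairs[i, "s2"]]] <- c(bp2[[pairs[i, "s2"]]], cos$axis[i])
    }
  }
  co_table <- if (n > 0) {
    data.frame(axis = cos$axis, s1 = pairs[, "s1"], s2 = pairs[, "s2"])
  } else {
    data.frame(axis = numeric(), s1 = integer(), s2 = integer())
  }
  structure(
    list(h1 = list(chromatid("P1", bp1[[1]]), chromatid("P1", bp1[[2]])),
         h2 = list(chromatid("P2", bp2[[1]]), chromatid("P2", bp2[[2]])),
         crossovers = co_table),
    class = "bivalent"
  )
}

#' Segregate a bivalent under one of the observable modes
#'
#' * `NORMAL`: one of the four chromatids, uniformly (the gamete of a normal
#'   meiosis).
#' * `MI_NDJ`: one chromatid from each homolog, chosen uniformly and
#'   independently (homologs fail to separate at meiosis I).
#' * `MII_NDJ`: both sister chromatids of one uniformly chosen homolog
#'   (sisters fail to separate at meiosis II).
#' * `MONOSOMY_RESCUE`: one uniformly chosen chromatid, duplicated by an early
#'   embryonic mitotic event.
#'
#' @param biv A [bivalent()][build_bivalent()].
#' @param mode One of `r paste0('"', SEGREGATION_MODES, '"', collapse = ", ")`.
#' @return List with `chromatids` (list of 1 or 2 [chromatid()]s), `mode`, and
#'   `n_chromatids` (1 for `NORMAL`, 2 otherwise; the monosomy-rescue
#'   duplicate counts as two identical copies).
#' @export
segregate <- function(biv, mode = SEGREGATION_MODES) {
  mode <- match.arg(mode)
  all4 <- c(biv$h1, biv$h2)
  inherited <- switch(
    mode,
    NORMAL = all4[sample(4, 1)],
    MI_NDJ = list(biv$h1[[sample(2, 1)]], biv$h2[[sample(2, 1)]]),
    MII_NDJ = if (sample(2, 1) == 1) biv$h1 else biv$h2,
    MONOSOMY_RESCUE = rep(all4[sample(4, 1)], 2)
  )
  list(chromatids = inherited, mode = mode, n_chromatids = length(inherited))
}

#' Copies of the P1 allele carried by the inherited chromatids at positions
#'
#' @param inherited List of [chromatid()]s (1 or 2).
#' @param pos Axis positions, bp.
#' @param cen Centromere axis position.
#' @return Integer vector: 0..length(inherited) P1 copies per position.
#' @export
p1_copies <- function(inherited, pos, cen) {
  counts <- integer(length(pos))
  for (ch in inherited) counts <- counts + (origin_at(ch, pos, cen) == "P1")
  counts
}

# Breakpoints of the inherited chromatids at which the noiseless state track
# actually changes (a breakpoint shared by reciprocal recombinants cancels).
visible_breakpoints <- function(inherited, cen) {
  br <- sort(unique(unlist(lapply(inherited, `[[`, "breakpoints"))))
  if (length(br) == 0) return(numeric(0))
  eps <- pmax(1e-9, abs(br) * 1e-12)
  lo <- p1_copies(inherited, br - eps, cen)
  hi <- p1_copies(inherited, br + eps, cen)
  br[lo != hi]
}

#' Noiseless genotype-state track of an inherited chromatid set
#'
#' @inheritParams p1_copies
#' @return Integer P1-copy counts at `pos` (the state track: for two
#'   chromatids 0 = HOM_P2, 1 = HET, 2 = HOM_P1).
#' @export
noiseless_states <- function(inherited, pos, cen) p1_copies(inherited, pos, cen)

#' Expected pooled alt-allele frequency per SNP
#'
#' In the backcross, every offspring carries one P2 (w1118) homolog from the
#' mother, and the father transmits each of his chromosome copies to half the
#' pool in expectation; the pool-level frequency of the P1 allele is therefore
#' `copies/4` per site for a two-chromatid father (0, 0.25 or 0.5) and
#' `carrier_fraction * copies/2` for a single-chromatid track.
#'
#' @param p1 Integer P1-copy counts per SNP (from [noiseless_states()]).
#' @param n_chromatids 1 or 2.
#' @return Expected frequencies in `[0, 0.5]`.
#' @export
expected_freq <- function(p1, n_chromatids) {
  stopifnot(n_chromatids %in% 1:2)
  # two chromatids: copies/(2 * 2) per offspring genome; one chromatid:
  # carried by half the pool, so (1/2) * copies/2 -- both reduce to copies/4
  p1 / 4
}

#' Simulate pooled offspring read counts for one sample
#'
#' Models the backcross of one NDJ (or control) male to homozygous P2 females
#' and pooled sequencing of the offspring. Sperm are split once per sample
#' between the father's two chromosome copies as `Binomial(pool_size, 1/2)`
#' (meiotic recombination does not occur in males, so the transmitted
#' chromatids are unaltered); each offspring additionally carries a P2
#' homolog from the mother. Per-SNP depth is Poisson; alt (P1-allele) reads
#' are binomial at the error-adjusted pool frequency.
#'
#' @param inherited List of 1 or 2 [chromatid()]s (the father's maternal
#'   chromosome copies).
#' @param panel_axis Axis positions of the SNP panel, bp.
#' @param cen Centromere axis position.
#' @param pool_size Offspring per pooled library.
#' @param mean_depth Mean reads per SNP.
#' @param seq_error Per-read flip probability.
#' @return data.frame with columns `axis`, `ref_count`, `alt_count` (alt =
#'   the P1 / Oregon R-like allele).
#' @export
pooled_read_counts <- function(inherited, panel_axis, cen, pool_size = 50,
                               mean_depth = 30, seq_error = 0.005) {
  if (pool_size <= 0) stop("pool_size must be positive")
  n <- length(panel_axis)
  k <- length(inherited)
  stopifnot(k %in% 1:2)
  if (k == 2) {
    i1 <- origin_at(inherited[[1]], panel_axis, cen) == "P1"
    i2 <- origin_at(inherited[[2]], panel_axis, cen) == "P1"
    n1 <- rbinom(1, pool_size, 0.5)  # offspring receiving chromatid 1
    f <- (n1 * i1 + (pool_size - n1) * i2) / (2 * pool_size)
  } else {
    i1 <- origin_at(inherited[[1]], panel_axis, cen) == "P1"
    carriers <- rbinom(1, pool_size, 0.5)  # offspring receiving this copy
    f <- carriers * i1 / (2 * pool_size)
  }
  depth <- rpois(n, mean_depth)
  p <- f * (1 - seq_error) + (1 - f) * seq_error
  alt <- rbinom(n, depth, p)
  data.frame(axis = panel_axis, ref_count = depth - alt, alt_count = alt)
}

# --- exhaustive detection-probability model --------------------------------

enumerate_inheritances <- function(biv, mode) {
  switch(
    mode,
    NORMAL = lapply(c(biv$h1, biv$h2), list),
    MI_NDJ = {
      out <- vector("list", 4); n <- 0
      for (i in 1:2) for (j in 1:2) {
        n <- n + 1; out[[n]] <- list(biv$h1[[i]], biv$h2[[j]])
      }
      out
    },
    MII_NDJ = list(biv$h1, biv$h2),
    MONOSOMY_RESCUE = lapply(c(biv$h1, biv$h2), function(ch) list(ch, ch))
  )
}

#' Chromatid-inheritance detection probability, by exhaustive enumeration
#'
#' Enumerates all equally likely inheritance outcomes for a segregation mode
#' given a crossover configuration, and reports the fraction whose noiseless
#' expected-frequency track is non-constant (i.e. in which at least one
#' crossover is detectable via a change in allele frequency). When the
#' chromatid pair taking part in each crossover is not fixed, the enumeration
#' marginalizes uniformly over all `4^k` pair assignments.
#'
#' For a single crossover this reproduces the chromatid-sampling argument:
#' 50% detection for a normal meiosis (one chromatid of four), 50% for MI NDJ
#' (one chromatid per homolog; the reciprocal-recombinant and
#' double-non-recombinant outcomes are fully heterozygous and undetectable),
#' and 100% for MII NDJ (both sisters of one chromosome).
#'
#' @param mode Segregation mode, see [segregate()].
#' @param n_co Number of crossovers (ignored when `positions` is given).
#' @param positions Optional distinct crossover positions; defaults to
#'   `seq_len(n_co)` on an abstract axis (detection depends only on the
#'   pattern, not the positions).
#' @param pairs Optional fixed pair assignment matrix as in
#'   [build_bivalent()]; `NULL` marginalizes uniformly.
#' @param cen Centromere axis position for the abstract axis (default 0, i.e.
#'   all crossovers distal to the centromere on one arm; any value not
#'   colliding with `positions` gives identical results).
#' @return Probability in `[0, 1]`.
#' @examples
#' detection_probability("NORMAL", 1)   # 0.5
#' detection_probability("MI_NDJ", 1)   # 0.5
#' detection_probability("MII_NDJ", 1)  # 1
#' @export
detection_probability <- function(mode = SEGREGATION_MODES, n_co = 1,
                                  positions = NULL, pairs = NULL, cen = 0) {
  mode <- match.arg(mode)
  if (is.null(positions)) positions <- seq_len(n_co)
  k <- length(positions)
  if (k == 0) return(0)
  pair_sets <- if (is.null(pairs)) {
    grid <- expand.grid(rep(list(1:2), 2 * k))
    lapply(seq_len(nrow(grid)), function(r) {
      cbind(s1 = as.integer(grid[r, seq_len(k)]),
            s2 = as.integer(grid[r, k + seq_len(k)]))
    })
  } else {
    list(as.matrix(pairs))
  }
  detected <- 0; total <- 0
  cos <- data.frame(axis = positions)
  for (pr in pair_sets) {
    biv <- build_bivalent(cos, pairs = pr)
    for (inh in enumerate_inheritances(biv, mode)) {
      total <- total + 1
      if (length(visible_breakpoints(inh, cen)) > 0) detected <- detected + 1
    }
  }
  detected / total
}

#' MI NDJ inheritance-class probabilities for a single crossover
#'
#' Enumerates the four equally likely (homolog-1 chromatid, homolog-2
#' chromatid) combinations for a single-crossover bivalent and classifies
#' each by the number of recombinant chromatids inherited.
#'
#' @return Named numeric vector: `one_recombinant` (one recombinant + one
#'   non-recombinant; the only detectable class), `reciprocal_recombinants`,
#'   and `both_nonrecombinant`. Values 0.50 / 0.25 / 0.25.
#' @export
mi_inheritance_class_probs <- function() {
  biv <- build_bivalent(data.frame(axis = 1), pairs = cbind(s1 = 1L, s2 = 1L))
  classes <- c(one_recombinant = 0, reciprocal_recombinants = 0, both_nonrecombinant = 0)
  outs <- enumerate_inheritances(biv, "MI_NDJ")
  for (inh in outs) {
    r <- sum(vapply(inh, is_recombinant, TRUE))
    key <- c("both_nonrecombinant", "one_recombinant", "reciprocal_recombinants")[r + 1]
    classes[key] <- classes[key] + 1
  }
  classes / length(outs)
}
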