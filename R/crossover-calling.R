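# Segmentation of per-sample allele-frequency tracks into genotype states and
# crossover calls at state transitions.
#
# The visual "persistent change in allele frequency" criterion is replaced by
# a deterministic surrogate: a maximum a-posteriori state path under binomial
# emissions (alt reads ~ Binomial(depth, error-adjusted expected frequency))
# with a uniform per-transition penalty, followed by merging of segments
# shorter than `min_segment_snps` into the likelihood-cheaper neighbour.

#' Segmentation configuration
#'
#' @param seq_error Per-read flip probability used to adjust the expected
#'   state frequencies (`f' = f(1-e) + (1-f)e`).
#' @param switch_penalty Per-transition log cost (> 0). The default,
#'   `log(1e4)`, demands about four orders of magnitude of likelihood before
#'   a state change is accepted.
#' @param min_segment_snps Minimum SNPs per segment; shorter segments are
#'   merged into the cheaper neighbour (the "persistent" requirement).
#' @param state_freqs Named expected alt-allele frequencies of the genotype
#'   states, strictly increasing. Default is the three-state model of a
#'   two-chromatid track: `HOM_P2` = 0, `HET` = 0.25, `HOM_P1` = 0.5. For
#'   single-chromatid tracks (chromosomes X and 3) use
#'   `single_chromatid_states()`.
#' @param pool_noisy Logical per state: is the state's pooled frequency
#'   subject to sperm-split (pool-sampling) noise? A state is noise-free when
#'   every chromosome copy the father carries is identical at the locus
#'   (both homozygous states of a two-chromatid track; the absent state of a
#'   single-chromatid track), so its realized pool frequency equals the
#'   expectation exactly. Heterozygous-state levels instead shift by the
#'   binomial sperm split, sample-wide. Default marks the intermediate
#'   state(s) noisy.
#' @param hom_lrt_crit Log-likelihood-ratio (nats) beyond which a segment
#'   assigned to a noise-free state, but whose observed frequency rejects
#'   that state's expectation against a free frequency, is relabelled to the
#'   nearest pool-noisy state. This absorbs the per-sample heterozygous
#'   frequency offset caused by the sperm split instead of mis-calling it as
#'   a homozygous island.
#' @param estimate_het_split Estimate the per-sample sperm-split offset of
#'   the pool-noisy level (see Details) and, when it exceeds
#'   `min_het_split`, segment with the noisy state split into its two phase
#'   sublevels. The sublevels share the state's label, so phase switches —
#'   allele-frequency shifts at crossovers shared by both inherited
#'   chromatids, which carry no genotype-state information — never become
#'   crossover calls.
#' @param min_het_split Minimum estimated offset (frequency units) at which
#'   the split-level model is engaged.
#' @param flank_confidence Posterior mass the reported flanking-SNP interval
#'   must cover at each transition (see [calls_from_segmentation()]).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(seq_error = 0.005,
                                switch_penalty = log(1e4),
                                min_segment_snps = 10,
                                state_freqs = c(HOM_P2 = 0, HET = 0.25, HOM_P1 = 0.5),
                                pool_noisy = NULL,
                                hom_lrt_crit = log(1e4),
                                estimate_het_split = TRUE,
                                min_het_split = 0.03,
                                flank_confidence = 0.999) {
  stopifnot(switch_penalty > 0, min_segment_snps >= 1,
            !is.null(names(state_freqs)), length(state_freqs) >= 2,
            all(diff(state_freqs) > 0),
            flank_confidence > 0, flank_confidence < 1)
  if (is.null(pool_noisy)) {
    pool_noisy <- state_freqs > 0 & state_freqs < 0.5
  }
  stopifnot(length(pool_noisy) == length(state_freqs))
  structure(
    list(seq_error = seq_error, switch_penalty = switch_penalty,
         min_segment_snps = as.integer(min_segment_snps),
         state_freqs = state_freqs, pool_noisy = pool_noisy,
         hom_lrt_crit = hom_lrt_crit,
         estimate_het_split = estimate_het_split,
         min_het_split = min_het_split,
         flank_confidence = flank_confidence),
    class = "segmentation_config"
  )
}

#' Two-state model for single-chromatid tracks
#'
#' Chromosomes carried as a single maternal chromatid (X and 3 of the NDJ
#' male) take one of two pooled frequencies: 0 where the chromatid is
#' P2-derived and `q` (default 0.25) where it is P1-derived.
#'
#' @param q Expected pooled frequency of a P1-derived segment.
#' @return Named state-frequency vector for [segmentation_config()].
#' @export
single_chromatid_states <- function(q = 0.25) c(P2 = 0, P1 = q)

# Per-SNP, per-state binomial emission log-likelihoods for arbitrary
# expected frequencies.
emission_loglik_freqs <- function(alt, depth, freqs, seq_error) {
  p <- freqs * (1 - seq_error) + (1 - freqs) * seq_error
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  vapply(p, function(pk) dbinom(alt, depth, pk, log = TRUE), numeric(length(alt)))
}

emission_loglik <- function(alt, depth, config) {
  emission_loglik_freqs(alt, depth, config$state_freqs, config$seq_error)
}

# Estimate the per-sample sperm-split offset of the heterozygous level.
# The realized pooled frequency of a heterozygous-state stretch is
# 0.25 +/- delta (delta = |n1/pool - 1/2| / 2), alternating phase at
# breakpoints shared by both inherited chromatids. Profile likelihood of a
# symmetric two-level mixture over the SNPs initially assigned to the noisy
# state.
estimate_het_split <- function(alt, depth, het_freq, seq_error,
                               max_snps = 400) {
  if (length(alt) < 30) return(0)
  if (length(alt) > max_snps) {
    idx <- round(seq(1, length(alt), length.out = max_snps))
    alt <- alt[idx]; depth <- depth[idx]
  }
  mix_ll <- function(g) {
    d <- het_freq * g
    e1 <- emission_loglik_freqs(alt, depth, het_freq - d, seq_error)
    e2 <- emission_loglik_freqs(alt, depth, het_freq + d, seq_error)
    m <- pmax(e1, e2)
    sum(m + log(0.5 * exp(e1 - m) + 0.5 * exp(e2 - m)))
  }
  # coarse grid over the relative offset, then local refinement
  coarse <- seq(0, 0.9, by = 0.1)
  ll <- vapply(coarse, mix_ll, 0)
  g0 <- coarse[which.max(ll)]
  fine <- seq(max(0, g0 - 0.1), min(0.9, g0 + 0.1), by = 0.02)
  ll2 <- vapply(fine, mix_ll, 0)
  fine[which.max(ll2)] * het_freq
}

# Relabel segments assigned to a pool-noise-free state when a frequency
# inside the nearest pool-noisy state's plausible sperm-split band fits the
# segment decisively better (log-likelihood ratio above hom_lrt_crit): such
# segments are sperm-split-shifted heterozygous stretches, not homozygous
# islands. Constraining the alternative to the split band keeps genuinely
# homozygous segments (whose frequency sits outside it) untouchable.
validate_hom_segments <- function(path, alt, depth, freqs, noisy_flags,
                                  seq_error, crit) {
  noisy <- which(noisy_flags)
  if (length(noisy) == 0) return(path)
  p_adj <- freqs * (1 - seq_error) + (1 - freqs) * seq_error
  p_adj <- pmin(pmax(p_adj, 1e-12), 1 - 1e-12)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$values)) {
    s <- r$values[j]
    if (noisy_flags[s]) next
    idx <- starts[j]:ends[j]
    A <- sum(alt[idx]); D <- sum(depth[idx])
    if (D == 0) next
    p_hat <- A / D
    k <- noisy[which.min(abs(freqs[noisy] - p_hat))]
    q <- freqs[k]
    # sperm-split band of the noisy level (matches the split search range)
    band <- sort(c(0.1 * q, 1.9 * q) * (1 - seq_error) +
                   (1 - c(0.1 * q, 1.9 * q)) * seq_error)
    p_c <- min(max(p_hat, band[1]), band[2])
    p_c <- min(max(p_c, 1e-12), 1 - 1e-12)
    lr <- A * log(p_c / p_adj[s]) + (D - A) * log((1 - p_c) / (1 - p_adj[s]))
    if (lr > crit) r$values[j] <- k
  }
  inverse.rle(r)
}

# Merge runs shorter than min_n into the neighbour under which their SNPs are
# likelier; repeats until stable.
merge_short_segments <- function(path, emis, min_n) {
  repeat {
    r <- rle(path)
    if (length(r$lengths) <= 1) return(path)
    short <- which(r$lengths < min_n)
    if (length(short) == 0) return(path)
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- starts[j]:ends[j]
    cand <- c(if (j > 1) r$values[j - 1], if (j < length(r$values)) r$values[j + 1])
    ll <- vapply(cand, function(s) sum(emis[idx, s]), 0)
    path[idx] <- cand[which.max(ll)]
  }
}

#' Segment one allele-frequency track into genotype states
#'
#' @param pos SNP positions (chromosome-axis bp), sorted ascending; masked
#'   SNPs must already be removed.
#' @param alt,depth Alt-read counts and total depths per SNP.
#' @param config A [segmentation_config()].
#' @return Object of class `genotype_segmentation`: data.frame with one row
#'   per maximal run of inferred state — `state` (label), `state_freq`,
#'   `start`, `end` (SNP indices), `first_pos`, `last_pos`, `n_snps`,
#'   `mean_freq`. SNP positions and emissions are kept as attributes for the
#'   downstream call boundary refinement. Empty input gives a zero-row
#'   segmentation.
#' @export
segment_track <- function(pos, alt, depth, config = segmentation_config()) {
  stopifnot(length(pos) == length(alt), length(alt) == length(depth))
  keep <- !is.na(alt) & !is.na(depth)
  pos <- pos[keep]; alt <- alt[keep]; depth <- depth[keep]
  empty <- data.frame(state = character(), state_freq = numeric(),
                      start = integer(), end = integer(),
                      first_pos = numeric(), last_pos = numeric(),
                      n_snps = integer(), mean_freq = numeric())
  if (length(pos) == 0) {
    return(structure(empty, class = c("genotype_segmentation", "data.frame"),
                     config = config))
  }
  if (is.unsorted(pos)) {
    o <- order(pos)
    pos <- pos[o]; alt <- alt[o]; depth <- depth[o]
  }
  # first pass at the nominal state levels
  emis <- emission_loglik(alt, depth, config)
  if (!is.matrix(emis)) emis <- matrix(emis, nrow = 1)
  path <- viterbi_from_emissions(emis, config$switch_penalty)

  # effective state set: possibly split the (single) pool-noisy level into
  # its two sperm-split phases, estimated from the SNPs assigned to it
  eff_freqs <- unname(config$state_freqs)
  eff_labels <- names(config$state_freqs)
  eff_noisy <- config$pool_noisy
  noisy_idx <- which(config$pool_noisy)
  if (isTRUE(config$estimate_het_split) && length(noisy_idx) == 1) {
    sel <- path == noisy_idx
    delta <- estimate_het_split(alt[sel], depth[sel],
                                config$state_freqs[[noisy_idx]],
                                config$seq_error)
    if (delta >= config$min_het_split) {
      hf <- config$state_freqs[[noisy_idx]]
      f <- c(eff_freqs[-noisy_idx], hf - delta, hf + delta)
      l <- c(eff_labels[-noisy_idx], rep(eff_labels[noisy_idx], 2))
      ns <- c(eff_noisy[-noisy_idx], TRUE, TRUE)
      o <- order(f)
      eff_freqs <- f[o]; eff_labels <- l[o]; eff_noisy <- ns[o]
      emis <- emission_loglik_freqs(alt, depth, eff_freqs, config$seq_error)
      if (!is.matrix(emis)) emis <- matrix(emis, nrow = 1)
      path <- viterbi_from_emissions(emis, config$switch_penalty)
    }
  }

  # validate BEFORE merging: short-run absorption would contaminate the
  # per-segment frequency tests with SNPs of a different true state
  path <- validate_hom_segments(path, alt, depth, eff_freqs, eff_noisy,
                                config$seq_error, config$hom_lrt_crit)
  path <- merge_short_segments(path, emis, config$min_segment_snps)

  # report maximal runs of state LABEL: the two phases of a split noisy
  # level share a label, so phase switches never open a segment boundary
  lab_path <- eff_labels[path]
  r <- rle(lab_path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  freq <- ifelse(depth > 0, alt / depth, NA_real_)
  seg <- data.frame(
    state = r$values,
    state_freq = unname(config$state_freqs[r$values]),
    start = starts, end = ends,
    first_pos = pos[starts], last_pos = pos[ends],
    n_snps = r$lengths,
    mean_freq = vapply(seq_along(starts), function(i) {
      mean(freq[starts[i]:ends[i]], na.rm = TRUE)
    }, 0)
  )
  structure(seg, class = c("genotype_segmentation", "data.frame"),
            config = config, positions = pos, emissions = emis,
            state_path = path, eff_freqs = eff_freqs, eff_labels = eff_labels)
}

# Credible flanking interval per transition: posterior over the index m of
# the last left-state SNP within the two adjoining segments, from the
# emission log-likelihoods; the flanks are the outermost indices of the
# smallest set holding >= conf posterior mass.
transition_flanks <- function(seg, emis, pos, conf, path) {
  n_tr <- nrow(seg) - 1
  out <- data.frame(left = numeric(n_tr), right = numeric(n_tr))
  for (t in seq_len(n_tr)) {
    ia <- seg$start[t]; ja <- seg$end[t]
    ib <- seg$start[t + 1]; jb <- seg$end[t + 1]
    sa <- path[ja]; sb <- path[ib]
    idx <- ia:jb
    ea <- emis[idx, sa]; eb <- emis[idx, sb]
    # loglik of "last left-state SNP = m" for m in ia..jb-1
    d <- ea - eb
    ll <- cumsum(d[-length(d)])              # relative loglik, m = ia..jb-1
    ll <- ll - max(ll)
    post <- exp(ll) / sum(exp(ll))
    o <- order(post, decreasing = TRUE)
    need <- cumsum(post[o]) >= conf
    take <- o[seq_len(which(need)[1])]
    m_lo <- ia + min(take) - 1               # last-left index, lower bound
    m_hi <- ia + max(take) - 1
    out$left[t] <- pos[m_lo]
    out$right[t] <- pos[min(m_hi + 1, jb)]
  }
  out
}

#' Crossover calls from a genotype segmentation
#'
#' One call per adjacent-segment boundary. The reported flanking SNPs bound
#' the smallest local change-point credible set covering
#' `flank_confidence` posterior mass, so the interval honestly reflects how
#' precisely the flanking data localize the crossover; with unambiguous data
#' it collapses to the last SNP of the left segment and the first SNP of the
#' right segment. Direct `HOM_P1` <-> `HOM_P2` transitions are flagged
#' (`hom_switch`): they cannot arise from a single crossover in a
#' two-chromatid sample and feed the monosomy-rescue logic rather than the
#' crossover tally.
#'
#' @param seg A [segment_track()] result.
#' @param map Optional [chromosome_map()]; when given, each call is annotated
#'   with the arm of its midpoint and whether the interval spans the
#'   centromeric gap.
#' @return data.frame with one row per transition: `left_flank`,
#'   `right_flank`, `midpoint` (axis bp), `state_from`, `state_to`,
#'   `hom_switch`, and (with `map`) `arm`, `pos` (arm-local midpoint),
#'   `spans_gap`.
#' @export
calls_from_segmentation <- function(seg, map = NULL) {
  stopifnot(inherits(seg, "genotype_segmentation"))
  config <- attr(seg, "config")
  base <- data.frame(left_flank = numeric(), right_flank = numeric(),
                     midpoint = numeric(), state_from = character(),
                     state_to = character(), hom_switch = logical())
  if (nrow(seg) <= 1) {
    if (!is.null(map)) {
      base$arm <- character(); base$pos <- numeric(); base$spans_gap <- logical()
    }
    return(base)
  }
  pos <- attr(seg, "positions")
  emis <- attr(seg, "emissions")
  fl <- transition_flanks(seg, emis, pos, config$flank_confidence,
                          attr(seg, "state_path"))
  out <- data.frame(
    left_flank = fl$left, right_flank = fl$right,
    midpoint = (fl$left + fl$right) / 2,
    state_from = seg$state[-nrow(seg)],
    state_to = seg$state[-1]
  )
  out$hom_switch <- out$state_from %in% c("HOM_P1", "HOM_P2") &
    out$state_to %in% c("HOM_P1", "HOM_P2")
  if (!is.null(map)) {
    gap <- centromere_interval(map)
    loc <- axis_to_arm(map, out$midpoint)
    out$arm <- loc$arm
    out$pos <- loc$pos
    out$spans_gap <- out$left_flank < gap[1] & out$right_flank > gap[2]
  }
  out
}

#' Test for a crossover hidden in the centromeric gap
#'
#' Compares the genotype state adjacent to the unassembled centromeric gap on
#' the two arms: a differing state implies a state change (crossover) inside
#' the gap interval.
#'
#' @param seg A chromosome-wide [segment_track()] result.
#' @param map A metacentric [chromosome_map()].
#' @return A one-row data.frame describing the gap call (interval = the gap,
#'   states on either side), a zero-row data.frame when the proximal states
#'   agree, or `NULL` (with a message) when either arm lacks informative
#'   proximal coverage.
#' @export
call_cross_gap_event <- function(seg, map) {
  stopifnot(inherits(seg, "genotype_segmentation"), map$shape == "metacentric")
  gap <- centromere_interval(map)
  if (nrow(seg) == 0) {
    message("cross-gap call undetermined: empty segmentation")
    return(NULL)
  }
  left <- seg[seg$first_pos < gap[1], , drop = FALSE]
  right <- seg[seg$last_pos > gap[2], , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) {
    message("cross-gap call undetermined: no informative proximal SNPs on one arm")
    return(NULL)
  }
  s_left <- left$state[nrow(left)]
  s_right <- right$state[1]
  if (s_left == s_right) {
    return(data.frame(left_flank = numeric(), right_flank = numeric(),
                      state_from = character(), state_to = character()))
  }
  data.frame(left_flank = left$last_pos[nrow(left)],
             right_flank = right$first_pos[1],
             state_from = s_left, state_to = s_right)
}

#' Distances between same-arm double crossovers
#'
#' @param calls Calls from [calls_from_segmentation()] (annotated with `arm`).
#' @param gmap A [genetic_map()].
#' @param map The [chromosome_map()] used to produce the calls.
#' @return data.frame with one row per adjacent same-arm call pair: `arm`,
#'   midpoints of both calls (arm-local bp), `bp_distance`, `cM_distance`.
#' @export
double_crossover_metrics <- function(calls, gmap, map) {
  if (is.null(calls$arm)) stop("calls must be annotated with arms (pass `map` to calls_from_segmentation)")
  calls <- calls[!calls$hom_switch & !is.na(calls$arm), , drop = FALSE]
  out <- list()
  for (nm in unique(calls$arm)) {
    sub <- calls[calls$arm == nm, , drop = FALSE]
    sub <- sub[order(sub$midpoint), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      p1 <- sub$pos[i]; p2 <- sub$pos[i + 1]
      out[[length(out) + 1]] <- data.frame(
        arm = nm, pos_left = min(p1, p2), pos_right = max(p1, p2),
        bp_distance = abs(sub$midpoint[i + 1] - sub$midpoint[i]),
        cM_distance = abs(bp_to_cM(gmap, nm, p2) - bp_to_cM(gmap, nm, p1))
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(arm = character(), pos_left = numeric(),
                      pos_right = numeric(), bp_distance = numeric(),
                      cM_distance = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
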