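# Division-of-origin calls, monosomy-rescue flags, and cause categories.

#' Classify the erroneous meiotic division of one sample
#'
#' MI NDJ progeny inherit one chromatid from each homolog and are therefore
#' heterozygous across the centromere; MII NDJ progeny inherit both sisters
#' of one homolog and are homozygous for either parental genotype across the
#' centromere. Operationally, "across the centromere" is the state of the
#' innermost segment on each arm within a pericentric window (the
#' heterochromatin plus `pericentric_pad` bp of adjacent euchromatin).
#'
#' @param seg A chromosome-wide [segment_track()] result (three-state model).
#' @param map A [chromosome_map()].
#' @param pericentric_pad Euchromatin padding of the pericentric window, bp;
#'   capped at half of each arm's euchromatin length so the window never
#'   swallows an arm.
#' @return Object of class `division_call`: list with `division` (`"MI"`,
#'   `"MII"`, or `NA` when undetermined), `pericentric_state`, the per-side
#'   states `left_state`/`right_state`, and a `note`. Discordant sides are
#'   never silently resolved: they yield `NA` with a warning.
#' @export
classify_division <- function(seg, map, pericentric_pad = 1e6) {
  stopifnot(inherits(seg, "genotype_segmentation"))
  gap <- centromere_interval(map)
  side_state <- function(lo, hi, innermost_last) {
    hit <- seg[seg$last_pos >= lo & seg$first_pos <= hi, , drop = FALSE]
    if (nrow(hit) == 0) return(NA_character_)
    if (innermost_last) hit$state[nrow(hit)] else hit$state[1]
  }
  if (map$shape == "metacentric") {
    a1 <- map$arms[[1]]; a2 <- map$arms[[2]]
    pad1 <- min(pericentric_pad, a1$het_boundary / 2)
    pad2 <- min(pericentric_pad, a2$het_boundary / 2)
    win_left <- c(a1$het_boundary - pad1, gap[1])
    win_right <- c(gap[2], gap[2] + (a2$length - a2$het_boundary) + pad2)
    left_state <- side_state(win_left[1], win_left[2], TRUE)
    right_state <- side_state(win_right[1], win_right[2], FALSE)
  } else {
    a1 <- map$arms[[1]]
    pad1 <- min(pericentric_pad, a1$het_boundary / 2)
    win <- c(a1$het_boundary - pad1, a1$length)
    left_state <- side_state(win[1], win[2], TRUE)
    right_state <- NA_character_
  }
  states <- c(left_state, right_state)
  known <- states[!is.na(states)]
  if (length(known) == 0) {
    warning("no pericentric coverage: division undetermined")
    return(structure(list(division = NA_character_,
                          pericentric_state = NA_character_,
                          left_state = left_state, right_state = right_state,
                          note = "no_pericentric_coverage"),
                     class = "division_call"))
  }
  if (length(unique(known)) > 1) {
    warning("discordant pericentric states across the centromere: division undetermined")
    return(structure(list(division = NA_character_,
                          pericentric_state = NA_character_,
                          left_state = left_state, right_state = right_state,
                          note = "discordant_pericentric_states"),
                     class = "division_call"))
  }
  st <- known[1]
  division <- if (st == "HET") "MI" else if (st %in% c("HOM_P1", "HOM_P2")) "MII" else NA_character_
  structure(list(division = division, pericentric_state = st,
                 left_state = left_state, right_state = right_state,
                 note = ""),
            class = "division_call")
}

#' @export
print.division_call <- function(x, ...) {
  cat(sprintf("<division_call> %s (pericentric state %s; L=%s R=%s)%s\n",
              ifelse(is.na(x$division), "undetermined", x$division),
              x$pericentric_state, x$left_state, x$right_state,
              ifelse(nzchar(x$note), paste0(" [", x$note, "]"), "")))
  invisible(x)
}

#' Flag a monosomy-rescue candidate
#'
#' Monosomy rescue duplicates the single inherited chromatid, so the track is
#' homozygous everywhere; if that chromatid was recombinant, the genotype
#' switches directly between the two homozygous parental states at the
#' recombination site. A track with no heterozygous segment and at least one
#' `HOM` <-> `HOM` transition is therefore a definite candidate; a fully
#' homozygous single-state track cannot be told apart from a no-crossover
#' MII event and is reported as ambiguous.
#'
#' @param seg A chromosome-wide [segment_track()] result.
#' @return List with `candidate` (logical) and `status` (`"no"` when any HET
#'   segment exists, `"candidate"`, or `"ambiguous"`).
#' @export
flag_monosomy_rescue <- function(seg) {
  stopifnot(inherits(seg, "genotype_segmentation"))
  if (nrow(seg) == 0) return(list(candidate = FALSE, status = "ambiguous"))
  if (any(seg$state == "HET")) return(list(candidate = FALSE, status = "no"))
  if (nrow(seg) > 1) return(list(candidate = TRUE, status = "candidate"))
  list(candidate = FALSE, status = "ambiguous")
}

#' Cause-categorizer configuration
#'
#' @param distal_fraction Fraction of the arm (or chromosome) counted as
#'   distal (default 0.24).
#' @param pericentric_eu_fraction Fraction of the arm's euchromatin adjacent
#'   to the heterochromatin counted as pericentric (default 0.15).
#' @param distal_scope `"per_arm"` or `"per_chromosome"` — the normalizing
#'   length for `distal_fraction` on metacentric maps.
#' @return An object of class `categorizer_config`.
#' @export
categorizer_config <- function(distal_fraction = 0.24,
                               pericentric_eu_fraction = 0.15,
                               distal_scope = c("per_arm", "per_chromosome")) {
  stopifnot(distal_fraction > 0, distal_fraction < 1,
            pericentric_eu_fraction > 0, pericentric_eu_fraction < 1)
  structure(list(distal_fraction = distal_fraction,
                 pericentric_eu_fraction = pericentric_eu_fraction,
                 distal_scope = match.arg(distal_scope)),
            class = "categorizer_config")
}

CAUSE_CATEGORIES <- c("NO_CO", "DISTAL_CO", "PERICENTRIC_CO", "OTHER")

#' Categorize the most probable cause of one NDJ event
#'
#' Applies, in order of precedence: no observable recombination anywhere on
#' the chromosome (`NO_CO`, lack of a chiasma); all crossovers within the
#' distal fraction of the chromosome with no medial or proximal crossovers
#' (`DISTAL_CO`); at least one crossover within the pericentric
#' heterochromatin or the adjacent euchromatin fraction (`PERICENTRIC_CO`);
#' otherwise factors unrelated to recombination (`OTHER`).
#'
#' @param calls The event's full chromosome-wide call set from
#'   [calls_from_segmentation()] (with map annotation). `hom_switch`
#'   transitions count as recombination sites (the underlying chromatid was
#'   recombinant); gap-spanning calls count as pericentric.
#' @param map A [chromosome_map()].
#' @param config A [categorizer_config()].
#' @return One of `"NO_CO"`, `"DISTAL_CO"`, `"PERICENTRIC_CO"`, `"OTHER"`.
#' @export
categorize_cause <- function(calls, map, config = categorizer_config()) {
  if (nrow(calls) == 0) return("NO_CO")
  spans_gap <- if (!is.null(calls$spans_gap)) calls$spans_gap else rep(FALSE, nrow(calls))
  frac <- rep(NA_real_, nrow(calls))
  peri <- rep(TRUE, nrow(calls))  # gap-spanning calls are pericentric
  for (i in seq_len(nrow(calls))) {
    if (spans_gap[i] || is.na(calls$arm[i])) next
    frac[i] <- chromosome_fraction_from_telomere(map, calls$arm[i], calls$pos[i],
                                                 scope = config$distal_scope)
    peri[i] <- is_pericentric(map, calls$arm[i], calls$pos[i],
                              eu_fraction = config$pericentric_eu_fraction)
  }
  distal <- !is.na(frac) & frac <= config$distal_fraction
  if (any(distal & peri)) {
    warning("call(s) both distal and pericentric under this map; precedence applies")
  }
  if (all(distal)) return("DISTAL_CO")
  if (any(peri)) return("PERICENTRIC_CO")
  "OTHER"
}

#' Tabulate cause-category fractions over a cohort
#'
#' @param events data.frame with a `category` column (e.g. from
#'   [classify_events()]).
#' @return data.frame: `category`, `n`, `fraction` (fractions sum to 1).
#' @export
category_breakdown <- function(events) {
  if (nrow(events) == 0) stop("empty cohort")
  tab <- table(factor(events$category, levels = CAUSE_CATEGORIES))
  data.frame(category = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), row.names = NULL)
}

#' Classify every sample of a filtered cohort
#'
#' Convenience wrapper running segmentation, crossover calling, division
#' classification, monosomy-rescue flagging and cause categorization per
#' sample.
#'
#' @param counts A filtered [counts_matrix()] (masked rows are skipped).
#' @param map A [chromosome_map()].
#' @param seg_config A [segmentation_config()].
#' @param cat_config A [categorizer_config()].
#' @param pericentric_pad Pericentric window padding for
#'   [classify_division()], bp.
#' @return List with `events` (one row per sample: division, rescue status,
#'   category, per-arm call counts) and `calls` (all crossover calls with a
#'   `sample` column).
#' @export
classify_events <- function(counts, map, seg_config = segmentation_config(),
                            cat_config = categorizer_config(),
                            pericentric_pad = 1e6) {
  samples <- unique(counts$sample)
  if (length(samples) == 0) {
    ev <- data.frame(sample = character(), division = character(),
                     pericentric_state = character(),
                     rescue_status = character(), rescue_candidate = logical(),
                     category = character(), n_calls = integer())
    for (nm in arm_names(map)) ev[[paste0("n_calls_", nm)]] <- integer()
    return(list(events = ev,
                calls = data.frame(sample = character(), left_flank = numeric(),
                                   right_flank = numeric(), midpoint = numeric(),
                                   state_from = character(), state_to = character(),
                                   hom_switch = logical(), arm = character(),
                                   pos = numeric(), spans_gap = logical())))
  }
  events <- vector("list", length(samples))
  all_calls <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    sub <- counts[counts$sample == s & !counts$masked, , drop = FALSE]
    axis <- arm_axis_positions(map, sub$chrom, sub$pos)
    o <- order(axis)
    seg <- segment_track(axis[o], sub$alt_count[o], sub$depth[o], seg_config)
    calls <- calls_from_segmentation(seg, map)
    div <- classify_division(seg, map, pericentric_pad)
    rescue <- flag_monosomy_rescue(seg)
    # every state transition marks at least one crossover site; a direct
    # HOM<->HOM switch is one crossover shared by both inherited chromatids
    # (or the recombination site of a duplicated rescue chromatid)
    co_calls <- calls
    category <- categorize_cause(calls, map, cat_config)
    ev <- data.frame(sample = s,
                     division = div$division,
                     pericentric_state = div$pericentric_state,
                     rescue_status = rescue$status,
                     rescue_candidate = rescue$candidate,
                     category = category,
                     n_calls = nrow(co_calls))
    for (nm in arm_names(map)) {
      ev[[paste0("n_calls_", nm)]] <- sum(co_calls$arm == nm, na.rm = TRUE)
    }
    events[[i]] <- ev
    if (nrow(calls)) all_calls[[i]] <- cbind(sample = s, calls)
  }
  calls <- do.call(rbind, Filter(Negate(is.null), all_calls))
  if (is.null(calls)) {
    calls <- data.frame(sample = character(), left_flank = numeric(),
                        right_flank = numeric(), midpoint = numeric(),
                        state_from = character(), state_to = character(),
                        hom_switch = logical(), arm = character(),
                        pos = numeric(), spans_gap = logical())
  }
  list(events = do.call(rbind, events), calls = calls)
}

# Axis positions for (chrom = arm name, arm-local pos) pairs.
arm_axis_positions <- function(map, chrom, pos) {
  axis <- rep(NA_real_, length(pos))
  for (nm in arm_names(map)) {
    i <- chrom == nm
    if (any(i)) axis[i] <- arm_to_axis(map, nm, pos[i])
  }
  if (anyNA(axis)) stop("counts contain chromosome labels not present in the map")
  axis
}
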