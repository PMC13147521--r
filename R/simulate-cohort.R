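# Cohort-level simulation: the study conditions in one configuration object,
# plus writers/readers for the plain-TSV interchange formats.

#' Simulation configuration
#'
#' Defaults describe the cross this package emulates: a cohort of maternal
#' disomy-2 males recovered through the compound-chromosome backcross. The
#' mode mixture reflects the analyzed cohort composition (49 MI : 14 MII of
#' 63 events; monosomy rescue was not observed and defaults to 0). The
#' per-arm crossover-count distribution is chosen so that ~13.7% of simulated
#' chromosomes carry no crossover on either arm, matching the zero-crossover
#' fraction reported for normal meioses in the comparison dataset. Pool size,
#' depth and error rate are declared defaults, not inferred values.
#'
#' @param n_events Number of NDJ males to simulate.
#' @param mode_mixture Named probabilities over segregation modes
#'   (`NORMAL`, `MI_NDJ`, `MII_NDJ`, `MONOSOMY_RESCUE`); must sum to 1.
#' @param co_count_dist Per-arm probabilities of 0/1/2 crossovers.
#' @param co_position_density `"uniform_euchromatin"` or `"uniform_arm"`.
#' @param co_position_sampler Optional `(map, arm, n)` function returning
#'   telomere-distance positions, overriding the density preset.
#' @param pool_size Offspring per pooled library.
#' @param mean_depth Mean reads per SNP.
#' @param seq_error Per-read flip probability.
#' @param snp_spacing Mean spacing between informative SNPs, bp.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_events = 63,
                              mode_mixture = c(NORMAL = 0, MI_NDJ = 49 / 63,
                                               MII_NDJ = 14 / 63, MONOSOMY_RESCUE = 0),
                              co_count_dist = c(0.37, 0.53, 0.10),
                              co_position_density = "uniform_euchromatin",
                              co_position_sampler = NULL,
                              pool_size = 50, mean_depth = 30,
                              seq_error = 0.005, snp_spacing = 2e4,
                              seed = 1L) {
  mode_mixture <- unlist(mode_mixture)  # accept YAML-style lists
  co_count_dist <- unname(unlist(co_count_dist))
  mm <- rep(0, length(SEGREGATION_MODES))
  names(mm) <- SEGREGATION_MODES
  stopifnot(all(names(mode_mixture) %in% SEGREGATION_MODES))
  mm[names(mode_mixture)] <- mode_mixture
  if (abs(sum(mm) - 1) > 1e-8) stop("mode_mixture must sum to 1")
  stopifnot(n_events >= 0, pool_size >= 1, mean_depth > 0,
            seq_error >= 0, seq_error <= 1, snp_spacing > 0)
  structure(
    list(n_events = as.integer(n_events), mode_mixture = mm,
         co_count_dist = co_count_dist,
         co_position_density = co_position_density,
         co_position_sampler = co_position_sampler,
         pool_size = pool_size, mean_depth = mean_depth,
         seq_error = seq_error, snp_spacing = snp_spacing,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Evenly spaced informative-SNP panel over the assembled arms
#'
#' SNPs are placed at `spacing` intervals along each arm (including the
#' pericentric heterochromatin, where polymorphisms exist even though
#' crossovers are suppressed) and never inside the unassembled gap.
#'
#' @param map A [chromosome_map()].
#' @param spacing SNP spacing, bp.
#' @return data.frame with columns `chrom` (arm name), `pos` (arm-local) and
#'   `axis`, sorted by axis position.
#' @export
snp_panel <- function(map, spacing = 2e4) {
  rows <- lapply(arm_names(map), function(nm) {
    a <- get_arm(map, nm)
    pos <- seq(spacing / 2, a$length - 1, by = spacing)
    data.frame(chrom = nm, pos = pos, axis = arm_to_axis(map, nm, pos))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$axis), , drop = FALSE]
}

simulate_one_event <- function(map, config, panel, sample_id) {
  cen <- centromere_axis(map)
  mode <- sample(SEGREGATION_MODES, 1, prob = config$mode_mixture)
  cos <- draw_crossovers(map, config$co_count_dist,
                         density = config$co_position_density,
                         sampler = config$co_position_sampler)
  biv <- build_bivalent(cos)
  seg <- segregate(biv, mode)
  vis <- visible_breakpoints(seg$chromatids, cen)
  counts <- pooled_read_counts(seg$chromatids, panel$axis, cen,
                               pool_size = config$pool_size,
                               mean_depth = config$mean_depth,
                               seq_error = config$seq_error)
  counts <- data.frame(sample = sample_id, chrom = panel$chrom, pos = panel$pos,
                       ref_count = counts$ref_count, alt_count = counts$alt_count)
  truth_cos <- if (nrow(biv$crossovers) > 0) {
    loc <- axis_to_arm(map, biv$crossovers$axis)
    data.frame(sample = sample_id, arm = loc$arm, pos = loc$pos,
               axis = biv$crossovers$axis,
               s1 = biv$crossovers$s1, s2 = biv$crossovers$s2,
               visible = biv$crossovers$axis %in% vis)
  } else {
    data.frame(sample = character(), arm = character(), pos = numeric(),
               axis = numeric(), s1 = integer(), s2 = integer(),
               visible = logical())
  }
  arm_counts <- table(factor(truth_cos$arm, levels = arm_names(map)))
  event <- data.frame(sample = sample_id, mode = mode,
                      n_chromatids = seg$n_chromatids,
                      n_co_total = nrow(truth_cos),
                      n_co_visible = length(vis))
  for (nm in arm_names(map)) event[[paste0("n_co_", nm)]] <- as.integer(arm_counts[[nm]])
  list(counts = counts, event = event, truth_cos = truth_cos,
       inherited = seg$chromatids)
}

#' Forward-simulate a pooled-sequencing NDJ cohort
#'
#' Runs the full generative model for `config$n_events` males: crossover
#' draw, bivalent assembly, segregation under the sampled mode, backcross,
#' and pooled read sampling over a shared SNP panel. The seed in `config`
#' fully determines the output.
#'
#' @param config A [simulation_config()].
#' @param map A [chromosome_map()] (default: the packaged chromosome 2 map).
#' @param keep_chromatids Keep the inherited chromatid objects per sample
#'   (useful for oracle comparisons; off by default to save memory).
#' @return An object of class `ndj_simulation`: list with `counts`
#'   (long-format read counts: sample, chrom, pos, ref_count, alt_count),
#'   `events` (per-sample truth: mode, chromatid count, crossover counts),
#'   `crossovers` (per-crossover truth incl. chromatid pair and visibility),
#'   `panel`, `map`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), map = ndj_chr2_map(),
                            keep_chromatids = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- snp_panel(map, config$snp_spacing)
  ids <- sprintf("ndj_%03d", seq_len(config$n_events))
  counts <- vector("list", config$n_events)
  events <- vector("list", config$n_events)
  truth <- vector("list", config$n_events)
  chroms <- if (keep_chromatids) vector("list", config$n_events) else NULL
  for (i in seq_len(config$n_events)) {
    ev <- simulate_one_event(map, config, panel, ids[i])
    counts[[i]] <- ev$counts
    events[[i]] <- ev$event
    truth[[i]] <- ev$truth_cos
    if (keep_chromatids) chroms[[i]] <- ev$inherited
  }
  empty_counts <- data.frame(sample = character(), chrom = character(),
                             pos = numeric(), ref_count = integer(),
                             alt_count = integer())
  out <- list(
    counts = if (config$n_events) do.call(rbind, counts) else empty_counts,
    events = if (config$n_events) do.call(rbind, events) else
      data.frame(sample = character(), mode = character(),
                 n_chromatids = integer(), n_co_total = integer(),
                 n_co_visible = integer()),
    crossovers = if (config$n_events) do.call(rbind, truth) else
      data.frame(sample = character(), arm = character(), pos = numeric(),
                 axis = numeric(), s1 = integer(), s2 = integer(),
                 visible = logical()),
    panel = panel, map = map, config = config
  )
  rownames(out$counts) <- rownames(out$events) <- rownames(out$crossovers) <- NULL
  if (keep_chromatids) {
    names(chroms) <- ids
    out$chromatids <- chroms
  }
  structure(out, class = "ndj_simulation")
}

#' @export
print.ndj_simulation <- function(x, ...) {
  cat(sprintf("<ndj_simulation> %d events on chromosome %s, %d SNPs, seed %d\n",
              nrow(x$events), x$map$name, nrow(x$panel), x$config$seed))
  if (nrow(x$events)) print(table(x$events$mode))
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort to plain-TSV files
#'
#' Emits `counts.tsv` (sample, chrom, pos, ref_count, alt_count),
#' `truth_events.tsv` and `truth_crossovers.tsv` into `dir`. Files
#' round-trip through [read_counts_tsv()] / [read_truth()].
#'
#' @param sim An [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ndj_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_tsv(sim$events, file.path(dir, "truth_events.tsv"))
  write_tsv(sim$crossovers, file.path(dir, "truth_crossovers.tsv"))
  invisible(dir)
}

#' Read a read-count table from TSV
#'
#' @param path TSV with columns sample, chrom, pos, ref_count, alt_count.
#' @return A counts matrix (see [counts_matrix()]).
#' @export
read_counts_tsv <- function(path) {
  counts_matrix(read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sample = "character", chrom = "character")))
}

#' Read simulation ground truth written by [write_simulation()]
#' @param dir Directory holding `truth_events.tsv` and `truth_crossovers.tsv`.
#' @return List with `events` and `crossovers` data.frames.
#' @export
read_truth <- function(dir) {
  list(
    events = read.delim(file.path(dir, "truth_events.tsv"),
                        stringsAsFactors = FALSE),
    crossovers = read.delim(file.path(dir, "truth_crossovers.tsv"),
                            stringsAsFactors = FALSE)
  )
}

#' Monte-Carlo detection fraction for single-crossover meioses
#'
#' Simulates `n` meioses each carrying exactly one crossover (uniform
#' non-sister chromatid pair, uniform position in the euchromatin of either
#' arm, arm chosen proportional to euchromatin length), segregates them under
#' `mode`, and reports the fraction detected. With `method = "track"`
#' detection means the noiseless state track is non-constant; with
#' `method = "segmentation"` pooled depth-`mean_depth` read counts are drawn
#' and the full Viterbi caller must emit at least one crossover call.
#'
#' @param mode Segregation mode.
#' @param n Number of simulated meioses.
#' @param map A [chromosome_map()].
#' @param method `"track"` or `"segmentation"`.
#' @param pool_size,mean_depth,seq_error,snp_spacing Read-sampling parameters
#'   (segmentation method only).
#' @param seg_config A [segmentation_config()] for the caller.
#' @return Fraction of simulated meioses detected.
#' @export
mc_detection_fraction <- function(mode = "MI_NDJ", n = 20000,
                                  map = ndj_chr2_map(),
                                  method = c("track", "segmentation"),
                                  pool_size = 50, mean_depth = 30,
                                  seq_error = 0.005, snp_spacing = 2e4,
                                  seg_config = segmentation_config(seq_error = seq_error)) {
  method <- match.arg(method)
  cen <- centromere_axis(map)
  eu_len <- vapply(map$arms, `[[`, 0, "het_boundary")
  panel <- if (method == "segmentation") snp_panel(map, snp_spacing) else NULL
  detected <- 0L
  for (i in seq_len(n)) {
    nm <- sample(arm_names(map), 1, prob = eu_len)
    a <- get_arm(map, nm)
    d <- runif(1, 0, a$het_boundary)
    pos <- if (a$orientation == "telomere_to_centromere") d else a$length - d
    cos <- data.frame(arm = nm, pos = pos, axis = arm_to_axis(map, nm, pos))
    biv <- build_bivalent(cos)
    seg <- segregate(biv, mode)
    if (method == "track") {
      hit <- length(visible_breakpoints(seg$chromatids, cen)) > 0
    } else {
      counts <- pooled_read_counts(seg$chromatids, panel$axis, cen,
                                   pool_size = pool_size,
                                   mean_depth = mean_depth,
                                   seq_error = seq_error)
      gseg <- segment_track(panel$axis, counts$alt_count,
                            counts$ref_count + counts$alt_count, seg_config)
      hit <- nrow(gseg) > 1
    }
    detected <- detected + hit
  }
  detected / n
}
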