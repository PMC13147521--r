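# Shared fixtures and independent oracles for the test suite.

# Small metacentric map: two 1-Mb arms, 0.8 Mb euchromatin each, 0.2 Mb gap.
toy_map <- function() {
  chromosome_map(
    arms = list(
      arm_def("L", 1e6, "telomere_to_centromere", 8e5),
      arm_def("R", 1e6, "centromere_to_telomere", 8e5)
    ),
    shape = "metacentric", gap_length = 2e5, name = "toy"
  )
}

toy_telo_map <- function(length = 1e6, het = 8e5) {
  chromosome_map(
    arms = list(arm_def("T", length, "telomere_to_centromere", het)),
    shape = "telocentric", name = "toyX"
  )
}

toy_genetic_map <- function() {
  genetic_map(data.frame(
    arm = c("L", "L", "R", "R"),
    bp = c(0, 1e6, 0, 1e6),
    cM = c(0, 50, 50, 100)
  ))
}

# Read counts whose alt frequency follows the given per-SNP state exactly
# (alt = round(depth * freq)); depth chosen so the rounding is exact.
exact_counts <- function(freqs, depth = 40) {
  alt <- round(depth * freqs)
  data.frame(alt = alt, depth = rep(depth, length(freqs)))
}

# Independently coded textbook oracle for the two-sided two-proportion test:
# chi-square on the 2x2 table with optional Yates correction.
oracle_two_prop_p <- function(x1, n1, x2, n2, correct = TRUE) {
  o <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  adj <- if (correct) pmin(0.5, abs(o - e)) else 0
  x2stat <- sum((abs(o - e) - adj)^2 / e)
  pchisq(x2stat, df = 1, lower.tail = FALSE)
}

# Independent exhaustive enumeration of the Mann-Whitney permutation
# distribution (written separately from the implementation).
oracle_mw_exact <- function(x, y, alternative) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  obs <- u_of(seq_len(m))
  all_u <- apply(combn(length(pooled), m), 2, u_of)
  pl <- mean(all_u <= obs + 1e-9)
  pg <- mean(all_u >= obs - 1e-9)
  switch(alternative,
         less = pl, greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# Simulate a single sample end to end and segment it.
segment_simulated_sample <- function(map, mode, cos, pairs = NULL,
                                     spacing = 2e4, depth = 30,
                                     seq_error = 0.005, pool = 50,
                                     config = segmentation_config(seq_error = seq_error)) {
  panel <- snp_panel(map, spacing)
  cen <- centromere_axis(map)
  biv <- build_bivalent(cos, pairs = pairs)
  seg <- segregate(biv, mode)
  counts <- pooled_read_counts(seg$chromatids, panel$axis, cen,
                               pool_size = pool, mean_depth = depth,
                               seq_error = seq_error)
  gs <- segment_track(panel$axis, counts$alt_count,
                      counts$ref_count + counts$alt_count, config)
  list(seg = gs, inherited = seg$chromatids, panel = panel, cen = cen)
}
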