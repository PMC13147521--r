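test_that("bivalent assembly installs reciprocal breakpoints", {
  biv0 <- build_bivalent(data.frame(axis = numeric()))
  expect_true(all(vapply(c(biv0$h1, biv0$h2),
                         function(ch) length(ch$breakpoints) == 0, TRUE)))
  biv1 <- build_bivalent(data.frame(axis = 5e5), pairs = cbind(2, 1))
  carriers <- vapply(c(biv1$h1, biv1$h2),
                     function(ch) length(ch$breakpoints), 0L)
  expect_equal(carriers, c(0L, 1L, 1L, 0L))
  expect_equal(biv1$h1[[2]]$breakpoints, 5e5)
  expect_error(build_bivalent(data.frame(axis = c(1, 1))), "duplicate")
})

test_that("crossover chromatid pairs are uniform over the four non-sister pairs", {
  set.seed(101)
  same_pair <- replicate(4000, {
    biv <- build_bivalent(data.frame(axis = c(2e5, 6e5)))
    co <- biv$crossovers
    co$s1[1] == co$s1[2] && co$s2[1] == co$s2[2]
  })
  # both crossovers hit the same pair with probability 1/4
  p <- mean(same_pair)
  expect_lt(abs(p - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("chromatid origin is anchored at the centromere", {
  cen <- 1.1e6
  ch <- chromatid("P1", breakpoints = c(3e5, 7e5))
  # moving outward from the centromere the origin toggles at each breakpoint
  expect_equal(origin_at(ch, c(1e5, 5e5, 9e5, 1.5e6), cen),
               c("P1", "P2", "P1", "P1"))
  # crossing from the other side of the centromere nothing changes
  expect_equal(origin_at(ch, cen + 1, cen), "P1")
  expect_error(chromatid("P1", c(1, 1)), "duplicate")
})

test_that("segregation modes return the contracted chromatid sets", {
  set.seed(7)
  for (i in 1:50) {
    biv <- build_bivalent(draw_crossovers(toy_map()))
    n <- segregate(biv, "NORMAL")
    expect_length(n$chromatids, 1)
    mi <- segregate(biv, "MI_NDJ")
    expect_length(mi$chromatids, 2)
    expect_equal(mi$chromatids[[1]]$origin, "P1")
    expect_equal(mi$chromatids[[2]]$origin, "P2")
    mii <- segregate(biv, "MII_NDJ")
    expect_length(mii$chromatids, 2)
    expect_equal(mii$chromatids[[1]]$origin, mii$chromatids[[2]]$origin)
    mr <- segregate(biv, "MONOSOMY_RESCUE")
    expect_identical(mr$chromatids[[1]], mr$chromatids[[2]])
  }
})

test_that("centromeric state is HET for MI and HOM for MII/rescue by construction", {
  set.seed(11)
  m <- toy_map(); cen <- centromere_axis(m)
  for (i in 1:200) {
    biv <- build_bivalent(draw_crossovers(m))
    expect_equal(p1_copies(segregate(biv, "MI_NDJ")$chromatids, cen, cen), 1L)
    expect_true(p1_copies(segregate(biv, "MII_NDJ")$chromatids, cen, cen) %in% c(0L, 2L))
    expect_true(p1_copies(segregate(biv, "MONOSOMY_RESCUE")$chromatids, cen, cen) %in% c(0L, 2L))
  }
})

test_that("MI single-crossover inheritance classes are 50/25/25", {
  probs <- mi_inheritance_class_probs()
  expect_equal(unname(probs["one_recombinant"]), 0.5)
  expect_equal(unname(probs["reciprocal_recombinants"]), 0.25)
  expect_equal(unname(probs["both_nonrecombinant"]), 0.25)
  expect_equal(sum(probs), 1)
})

test_that("detection probabilities from exhaustive enumeration", {
  expect_equal(detection_probability("NORMAL", 1), 0.5)
  expect_equal(detection_probability("MI_NDJ", 1), 0.5)
  expect_equal(detection_probability("MII_NDJ", 1), 1)
  expect_equal(detection_probability("MONOSOMY_RESCUE", 1), 0.5)
  for (mode in c("NORMAL", "MI_NDJ", "MII_NDJ", "MONOSOMY_RESCUE")) {
    expect_equal(detection_probability(mode, 0), 0)
  }
  # fixed chromatid pair: a single crossover is always visible to MII when
  # the recombinant homolog is inherited, and never when pairs make both
  # inherited chromatids recombinant reciprocals in MI
  expect_equal(detection_probability("MI_NDJ", positions = 1,
                                     pairs = cbind(1, 1)), 0.5)
  # detection is independent of where the crossovers sit
  expect_equal(detection_probability("MI_NDJ", positions = c(0.2, 0.7)),
               detection_probability("MI_NDJ", 2))
})

test_that("detection probability agrees with Monte-Carlo segregation", {
  set.seed(23)
  m <- toy_map(); cen <- centromere_axis(m)
  for (mode in c("NORMAL", "MI_NDJ", "MII_NDJ")) {
    for (k in 1:2) {
      p_exact <- detection_probability(mode, k)
      n <- 4000
      hits <- replicate(n, {
        cos <- data.frame(axis = sort(runif(k, 0, 8e5)))
        biv <- build_bivalent(cos)
        inh <- segregate(biv, mode)$chromatids
        length(visible_breakpoints(inh, cen)) > 0
      })
      expect_lt(abs(mean(hits) - p_exact),
                3 * sqrt(p_exact * (1 - p_exact) / n) + 1e-9,
                label = sprintf("%s k=%d", mode, k))
    }
  }
})

test_that("crossover positions are uniform over the euchromatin", {
  set.seed(5)
  m <- toy_map()
  pos <- replicate(12000, {
    cos <- draw_crossovers(m, co_count_dist = c(0, 1, 0))
    cos$pos[1]  # arm L only reported in assembly = telomere-distance coords
  })
  # degenerate-at-1 distribution puts exactly one crossover per arm
  cos <- draw_crossovers(m, co_count_dist = c(0, 1, 0))
  expect_equal(nrow(cos), 2)
  expect_equal(sort(unique(cos$arm)), c("L", "R"))
  # zero-count distribution yields none
  expect_equal(nrow(draw_crossovers(m, co_count_dist = c(1, 0, 0))), 0)
  # KS against the closed-form uniform CDF on [0, het_boundary]
  ks <- suppressWarnings(stats::ks.test(pos, "punif", 0, 8e5))
  expect_gt(ks$p.value, 0.01)
})

test_that("pooled read counts hit the enumerated expected frequencies", {
  cen <- 1.1e6
  panel <- c(1e5, 5e5, 9e5)
  # both chromatids P1: every offspring is P1/P2 -> frequency exactly 1/2,
  # independent of the sperm split
  set.seed(31)
  two_p1 <- list(chromatid("P1"), chromatid("P1"))
  cts <- pooled_read_counts(two_p1, panel, cen, pool_size = 50,
                            mean_depth = 5000, seq_error = 0)
  expect_lt(max(abs(cts$alt_count / (cts$ref_count + cts$alt_count) - 0.5)), 0.03)
  # P1/P2 heterozygous father: expected frequency 1/4
  het <- list(chromatid("P1"), chromatid("P2"))
  f <- replicate(400, {
    cts <- pooled_read_counts(het, panel[1], cen, pool_size = 50,
                              mean_depth = 200, seq_error = 0)
    cts$alt_count / (cts$ref_count + cts$alt_count)
  })
  expect_lt(abs(mean(f) - 0.25), 0.01)
  # both P2 with error e: expected alt frequency e
  two_p2 <- list(chromatid("P2"), chromatid("P2"))
  cts <- pooled_read_counts(two_p2, rep(panel, 400), cen, pool_size = 50,
                            mean_depth = 50, seq_error = 0.01)
  expect_lt(abs(sum(cts$alt_count) / sum(cts$ref_count + cts$alt_count) - 0.01),
            0.003)
  # single chromatid: carried by half the pool -> frequency q = 1/4
  single <- list(chromatid("P1"))
  f1 <- replicate(400, {
    cts <- pooled_read_counts(single, panel[1], cen, pool_size = 50,
                              mean_depth = 200, seq_error = 0)
    cts$alt_count / (cts$ref_count + cts$alt_count)
  })
  expect_lt(abs(mean(f1) - 0.25), 0.01)
  expect_error(pooled_read_counts(het, panel, cen, pool_size = 0), "pool_size")
})

test_that("noiseless expected frequencies live on the state grid", {
  set.seed(17)
  m <- toy_map(); cen <- centromere_axis(m)
  panel <- snp_panel(m, 5e4)
  for (i in 1:20) {
    biv <- build_bivalent(draw_crossovers(m))
    for (mode in c("MI_NDJ", "MII_NDJ", "MONOSOMY_RESCUE")) {
      inh <- segregate(biv, mode)$chromatids
      ef <- expected_freq(noiseless_states(inh, panel$axis, cen), 2)
      expect_true(all(ef %in% c(0, 0.25, 0.5)))
    }
    efn <- expected_freq(noiseless_states(segregate(biv, "NORMAL")$chromatids,
                                          panel$axis, cen), 1)
    expect_true(all(efn %in% c(0, 0.25)))
  }
})

test_that("a fixed seed makes the simulation byte-reproducible", {
  cfg <- simulation_config(n_events = 4, seed = 77, snp_spacing = 1e5)
  s1 <- simulate_cohort(cfg, toy_map())
  s2 <- simulate_cohort(cfg, toy_map())
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$crossovers, s2$crossovers)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "counts.tsv")),
                   readLines(file.path(d2, "counts.tsv")))
})

test_that("simulation files round-trip through the readers", {
  cfg <- simulation_config(n_events = 2, seed = 3, snp_spacing = 1e5)
  sim <- simulate_cohort(cfg, toy_map())
  d <- file.path(tempdir(), "simRT")
  write_simulation(sim, d)
  counts <- read_counts_tsv(file.path(d, "counts.tsv"))
  expect_equal(nrow(counts), nrow(sim$counts))
  expect_equal(counts$alt_count, sim$counts$alt_count)
  tr <- read_truth(d)
  expect_equal(tr$events$mode, sim$events$mode)
  expect_equal(tr$crossovers$axis, sim$crossovers$axis)
  # empty cohort still writes valid headed files
  sim0 <- simulate_cohort(simulation_config(n_events = 0, seed = 1,
                                            snp_spacing = 1e5), toy_map())
  d0 <- file.path(tempdir(), "simEmpty")
  write_simulation(sim0, d0)
  expect_equal(nrow(read_counts_tsv(file.path(d0, "counts.tsv"))), 0)
  expect_equal(nrow(read_truth(d0)$events), 0)
})

test_that("simulated chromatid counts respect the per-mode contract", {
  sim <- simulate_cohort(simulation_config(
    n_events = 40, seed = 5, snp_spacing = 1e5,
    mode_mixture = c(NORMAL = 0.25, MI_NDJ = 0.25, MII_NDJ = 0.25,
                     MONOSOMY_RESCUE = 0.25)), toy_map())
  expected <- ifelse(sim$events$mode == "NORMAL", 1L, 2L)
  expect_equal(sim$events$n_chromatids, expected)
})
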