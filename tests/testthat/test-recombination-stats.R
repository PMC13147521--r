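test_that("two-proportion z matches the textbook chi-square oracle to 1e-10", {
  set.seed(83)
  for (i in 1:100) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    for (corr in c(TRUE, FALSE)) {
      p <- two_proportion_z_test(x1, n1, x2, n2, "two.sided", correct = corr)$p.value
      expect_equal(p, oracle_two_prop_p(x1, n1, x2, n2, correct = corr),
                   tolerance = 1e-10,
                   label = sprintf("x1=%d n1=%d x2=%d n2=%d corr=%d",
                                   x1, n1, x2, n2, corr))
    }
  }
})

test_that("two-proportion z agrees with the reference implementation", {
  set.seed(89)
  for (i in 1:40) {
    n1 <- sample(10:150, 1); n2 <- sample(10:150, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    for (alt in c("two.sided", "greater", "less")) {
      for (corr in c(TRUE, FALSE)) {
        mine <- two_proportion_z_test(x1, n1, x2, n2, alt, correct = corr)
        ref <- suppressWarnings(  # small-count approximation notice
          stats::prop.test(c(x1, x2), c(n1, n2), alternative = alt,
                           correct = corr))
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9,
                     label = sprintf("%s corr=%d x=%d/%d vs %d/%d",
                                     alt, corr, x1, n1, x2, n2))
      }
    }
  }
})

test_that("two-proportion z edge cases", {
  expect_equal(two_proportion_z_test(10, 100, 10, 100, "two.sided",
                                     correct = FALSE)$p.value, 1)
  expect_lt(two_proportion_z_test(0, 10, 10, 10, "two.sided")$p.value, 1e-4)
  expect_error(two_proportion_z_test(11, 10, 1, 10))
})

test_that("Mann-Whitney exact mode matches independent enumeration", {
  expect_equal(mann_whitney_test(c(1, 2, 3), c(4, 5, 6), "less")$p.value, 1 / 20)
  expect_equal(mann_whitney_test(c(4, 5, 6), c(1, 2, 3), "greater")$p.value, 1 / 20)
  x <- c(1, 2, 5, 7); y <- c(1, 2, 5, 7)
  expect_equal(mann_whitney_test(x, y, "two.sided")$p.value, 1)
  set.seed(97)
  for (i in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- sample(1:10, m, replace = TRUE)
    y <- sample(1:10, n, replace = TRUE)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mann_whitney_test(x, y, alt)$p.value,
                   oracle_mw_exact(x, y, alt),
                   label = sprintf("%s x=%s y=%s", alt,
                                   paste(x, collapse = ","),
                                   paste(y, collapse = ",")))
    }
  }
})

test_that("Mann-Whitney exact mode matches the reference implementation without ties", {
  set.seed(101)
  for (i in 1:20) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    v <- sample(1:50, m + n)  # distinct values, exact p well-defined
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mann_whitney_test(x, y, alt)$p.value,
                   stats::wilcox.test(x, y, alternative = alt,
                                      exact = TRUE)$p.value)
    }
  }
})

test_that("normal approximation tracks the exact p-value at n = 12", {
  set.seed(103)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, -1.5, 1.5))
    pe <- mann_whitney_test(x, y, "two.sided", exact = TRUE)$p.value
    pa <- mann_whitney_test(x, y, "two.sided", exact = FALSE)$p.value
    expect_lt(abs(pe - pa), 0.03)
  }
  # and against the reference normal approximation, with ties
  x <- c(1, 1, 2, 3, 5, 5, 8); y <- c(2, 2, 3, 6, 6, 9, 9, 10)
  for (alt in c("two.sided", "less", "greater")) {
    expect_equal(mann_whitney_test(x, y, alt, exact = FALSE)$p.value,
                 suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                                     exact = FALSE))$p.value)
  }
})

test_that("crossover-class fractions apply the MII halving to singles only", {
  arm_counts <- data.frame(
    class = c(rep("MI", 10), rep("MII", 10)),
    n_co = c(rep(0, 5), rep(1, 4), 2, rep(0, 5), rep(1, 4), 2))
  fr <- co_class_fractions(arm_counts, adjust_mii = TRUE)
  mi <- fr[fr$class == "MI", ]; mii <- fr[fr$class == "MII", ]
  expect_equal(mi$fraction, mi$fraction_adjusted)    # MI untouched
  expect_equal(mii$fraction[mii$co_class == "1"], 0.4)
  expect_equal(mii$fraction_adjusted[mii$co_class == "1"], 0.2)  # halved
  expect_equal(mii$fraction_adjusted[mii$co_class == "2"],
               mii$fraction[mii$co_class == "2"])    # doubles not adjusted
  expect_equal(sum(mii$fraction), 1)                 # raw fractions normalized
  off <- co_class_fractions(arm_counts, adjust_mii = FALSE)
  expect_equal(off$fraction, off$fraction_adjusted)
  expect_error(co_class_fractions(arm_counts[0, ]), "empty")
})

test_that("zero-crossover chromosome fraction matches hand tabulation", {
  ev <- data.frame(n_calls = c(rep(0, 20), rep(1, 19), rep(2, 10)))
  expect_equal(zero_co_chromosome_fraction(ev), 20 / 49)
  expect_equal(round(100 * zero_co_chromosome_fraction(ev), 1), 40.8)
  expect_equal(zero_co_chromosome_fraction(data.frame(n_calls = c(0, 0))), 1)
})

test_that("arm association tabulates conditionals per class", {
  ev <- data.frame(
    class = rep("MI", 10),
    left_co = c(0, 0, 0, 0, 0, 0, 1, 1, 2, 1),
    right_co = c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0))
  aa <- arm_association(ev)
  expect_equal(aa$p_right_given_left0, 3 / 6)
  expect_equal(aa$n_left0, 6)
  expect_equal(aa$p_right_given_left1plus, 2 / 4)
  expect_equal(aa$n_left1plus, 4)
  # all events with crossovers on both arms
  full <- data.frame(class = "x", left_co = c(1, 2), right_co = c(1, 1))
  aaf <- arm_association(full)
  expect_equal(aaf$p_right_given_left1plus, 1)
  expect_equal(aaf$n_left0, 0)
  expect_true(is.na(aaf$p_right_given_left0))
})

test_that("independently simulated arms show no association", {
  set.seed(107)
  n <- 4000
  ev <- data.frame(class = "MI",
                   left_co = rbinom(n, 2, 0.3),
                   right_co = rbinom(n, 2, 0.3))
  aa <- arm_association(ev)
  p <- 1 - (1 - 0.3)^2  # P(at least one right-arm crossover)
  expect_lt(abs(aa$p_right_given_left0 - p), 3 * sqrt(p * (1 - p) / aa$n_left0))
  expect_lt(abs(aa$p_right_given_left1plus - p),
            3 * sqrt(p * (1 - p) / aa$n_left1plus))
})

test_that("coefficient of exchange bins, corrects and conserves", {
  m <- toy_map()
  calls <- data.frame(arm = "L", pos = c(1.5e5, 1.6e5, 1.7e5, 1.8e5, 1.9e5),
                      hom_switch = FALSE)
  ce <- coefficient_of_exchange(calls, m, n_events = 100, mode = "NORMAL",
                                bin_bp = 1e5)
  hit <- ce[ce$arm == "L" & ce$bin_start == 1e5, ]
  expect_equal(hit$exchange, 5 / 100 * 2)  # x2 single-chromatid sampling
  expect_equal(sum(ce$n_co), 5)
  # conservation: total exchange = total crossovers / events x correction
  expect_equal(sum(ce$exchange), 5 / 100 * 2)
  # MII reveals all crossovers: no correction
  ce2 <- coefficient_of_exchange(calls, m, n_events = 100, mode = "MII_NDJ",
                                 bin_bp = 1e5)
  expect_equal(sum(ce2$exchange), 5 / 100)
  # no calls: all-zero track over both arms
  ce0 <- coefficient_of_exchange(calls[0, ], m, n_events = 10, bin_bp = 1e5)
  expect_true(all(ce0$exchange == 0))
  expect_equal(nrow(ce0), 20)
})

test_that("cross-chromosome comparison uses MI events and the declared tails", {
  ev <- data.frame(
    division = c(rep("MI", 30), rep("MII", 5)),
    chr2_co = c(rep(0, 10), rep(1, 10), rep(2, 10), rep(0, 5)),
    other_mean_co = c(rep(1, 10), rep(1, 10), rep(3, 10), rep(50, 5)))
  res <- cross_chromosome_co_comparison(ev)
  # identical strata: exact two-sided p of 1
  expect_equal(res[["0v1"]]$p.value, 1)
  # strongly shifted stratum: small one-sided p in the declared direction
  expect_lt(res[["0v2"]]$p.value, 0.01)
  expect_lt(res[["1v2"]]$p.value, 0.01)
  # the MII rows (other_mean_co = 50) were excluded: otherwise 0v1 would shift
  ev2 <- ev[ev$division == "MI", ]
  expect_identical(res[["0v1"]]$p.value,
                   cross_chromosome_co_comparison(ev2)[["0v1"]]$p.value)
  # empty stratum is reported, not an error
  res3 <- cross_chromosome_co_comparison(ev[ev$chr2_co != 2, ])
  expect_match(res3[["1v2"]], "empty stratum")
})
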