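test_that("line summaries reproduce the rate arithmetic of MA assays", {
  md <- tibble::tibble(line_id = c("B1", "W1"), genotype = c("brc-1", "wt"),
                       generations = c(300L, 240L))
  ev <- dplyr::bind_rows(
    ma_events(rep("B1", 10), "c1", seq(100, by = 5000, length.out = 10) ,
              seq(100, by = 5000, length.out = 10) + 2000,
              "TANDEM_DUPLICATION"),
    ma_events(rep("W1", 8), "c1", seq(100, by = 300, length.out = 8),
              seq(100, by = 300, length.out = 8) + 20, "DELETION")
  )
  ls <- summarize_lines(ev, md)
  td_b <- ls[ls$line_id == "B1" & ls$class == "TANDEM_DUPLICATION", ]
  expect_equal(td_b$count, 10L)
  expect_equal(td_b$rate, 10 / 300)
  del_w <- ls[ls$line_id == "W1" & ls$class == "DELETION", ]
  expect_equal(del_w$rate, 1 / 30)  # one deletion per 30 generations
  # rate * generations reproduces the integer count exactly
  expect_equal(ls$rate * ls$generations, as.numeric(ls$count))
  # a line with no events still appears, with all-zero rates
  ls0 <- summarize_lines(ev[0, ], md)
  expect_true(all(ls0$count == 0) && all(ls0$rate == 0))
  expect_error(summarize_lines(ma_events("X9", "c1", 1, 2, "DELETION"), md),
               "X9")
})

test_that("rate comparisons match an independently coded Welch computation", {
  md <- tibble::tibble(line_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                       genotype = rep(c("brc-1", "wt"), each = 3),
                       generations = 100L)
  rates_a <- c(0.30, 0.25, 0.28); rates_b <- c(0.03, 0.04, 0.02)
  ev <- dplyr::bind_rows(purrr::map2(
    md$line_id, round(c(rates_a, rates_b) * 100),
    function(l, k) ma_events(rep(l, k), "c1",
                             seq(10, by = 400, length.out = k),
                             seq(10, by = 400, length.out = k) + 15,
                             "DELETION")))
  ls <- summarize_lines(ev, md)
  cmp <- compare_rates(ls, "DELETION", "brc-1", "wt")
  oracle <- oracle_welch(rates_a, rates_b)
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$df, oracle$df, tolerance = 1e-10)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(cmp$sem_a, sd(rates_a) / sqrt(3))
  expect_equal(cmp$fold_change, mean(rates_a) / mean(rates_b))

  pooled <- compare_rates(ls, "DELETION", "brc-1", "wt", method = "pooled")
  oracle_p <- oracle_pooled_t(rates_a, rates_b)
  expect_equal(pooled$t_statistic, oracle_p$t, tolerance = 1e-10)
  expect_equal(pooled$p_value, oracle_p$p, tolerance = 1e-10)

  # antisymmetry: swapping the groups negates t and preserves p
  rev <- compare_rates(ls, "DELETION", "wt", "brc-1")
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$p_value, cmp$p_value)
})

test_that("identical groups give t = 0, p = 1 and small groups error", {
  md <- tibble::tibble(line_id = c("a1", "a2", "b1", "b2"),
                       genotype = rep(c("g1", "g2"), each = 2),
                       generations = 50L)
  ev <- dplyr::bind_rows(purrr::map(md$line_id, function(l)
    ma_events(rep(l, 5), "c1", seq(10, by = 100, length.out = 5),
              seq(10, by = 100, length.out = 5) + 10, "DELETION")))
  ls <- summarize_lines(ev, md)
  cmp <- compare_rates(ls, "DELETION", "g1", "g2")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_rates(ls[ls$line_id != "a2", ], "DELETION", "g1", "g2"),
               "at least 2 lines")
})

test_that("substitutions collapse onto the six pyrimidine-referenced classes", {
  expect_equal(classify_substitution("G", "A"), "C>T")
  expect_equal(classify_substitution("C", "T"), "C>T")
  pairs <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  cls <- classify_substitution(pairs$r, pairs$a)
  expect_equal(sort(unique(cls)),
               c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(cls) == 2))
  expect_error(classify_substitution("A", "A"), "must differ")
  expect_error(classify_substitution("A", "N"), "A,C,G,T")
})

test_that("the spectrum conserves SNV counts and pools generations", {
  md <- tibble::tibble(line_id = c("L1", "L2"), genotype = "brc-1",
                       generations = c(40L, 60L))
  ev <- ma_events(c("L1", "L1", "L2"), "c1", c(5, 9, 13), c(6, 10, 14), "SNV",
                  ref_base = c("G", "C", "A"), alt_base = c("A", "A", "C"))
  sp <- substitution_spectrum(ev, md)
  expect_equal(sum(sp$count), 3)
  expect_equal(sp$count[sp$class == "C>T"], 1L)  # the G>A
  expect_equal(sp$rate, sp$count / 100)
  sp0 <- substitution_spectrum(ev[0, ], md)
  expect_equal(sum(sp0$count), 0)
  expect_equal(nrow(sp0), 6)
})

test_that("dispersion screening flags outlier lines and calibrates near alpha", {
  md <- tibble::tibble(line_id = paste0("L", 1:4), genotype = "g",
                       generations = 40L)
  mk <- function(counts) {
    ev <- purrr::map2(md$line_id, counts, function(l, k) {
      if (k == 0) return(NULL)
      ma_events(rep(l, k), "c1", seq(10, by = 500, length.out = k),
                seq(10, by = 500, length.out = k) + 10, "DELETION")
    })
    summarize_lines(dplyr::bind_rows(ev), md)
  }
  same <- line_consistency_check(mk(c(5, 5, 5, 5)), "DELETION")
  expect_equal(same$dispersion, 0)
  expect_equal(same$p_value, 1)

  outlier <- line_consistency_check(mk(c(5, 5, 5, 50)), "DELETION")
  expect_lt(outlier$p_value, 0.01)

  # alpha calibration under the Poisson null (counts ~ Poisson(20) per line)
  set.seed(88)
  rejections <- 0L
  n_rep <- 150L
  for (i in seq_len(n_rep)) {
    p <- line_consistency_check(mk(pmax(rpois(4, 20), 1)), "DELETION")$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.02)
})

test_that("the pooled rate estimate tightens as total generations grow", {
  md_for <- function(gens) tibble::tibble(line_id = paste0("L", 1:5),
                                          genotype = "g", generations = gens)
  lambda <- 0.3
  mae <- purrr::map_dbl(c(40L, 640L), function(gens) {
    set.seed(gens)
    errs <- purrr::map_dbl(1:80, function(i) {
      counts <- rpois(5, lambda * gens)
      abs(sum(counts) / (5 * gens) - lambda)
    })
    mean(errs)
  })
  # 16x the exposure should shrink the error about 4-fold
  expect_lt(mae[2], mae[1] / 2)
})
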