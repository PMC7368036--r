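test_that("generated genomes follow the requested composition exactly", {
  g <- generate_genome(1e6, base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                       seed = 4)
  f <- g$base_freqs
  expect_true(all(abs(f - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e6)))

  g1 <- generate_genome(500, base_freqs = c(A = 1, C = 0, G = 0, T = 0),
                        seed = 1)
  expect_equal(unname(g1$contigs), paste(rep("A", 500), collapse = ""))

  ga <- generate_genome(1000, seed = 99)
  gb <- generate_genome(1000, seed = 99)
  expect_identical(ga$contigs, gb$contigs)
})

test_that("homology planting yields exactly the requested junction score", {
  set.seed(64)
  for (h in c(0L, 2L, 13L)) {
    g <- generate_genome(4000, seed = 100 + h)
    pl <- plant_deletion_with_homology(g, "chrS1", start = 2000, size = 40,
                                       h = h)
    hom <- junction_homology(pl$genome, "chrS1", pl$event$start, pl$event$end)
    expect_equal(hom$hom_total, h)
    expect_equal(pl$h_left + pl$h_right, h)
  }
  # tandem duplications use the same junction construction
  g <- generate_genome(4000, seed = 7)
  pl <- plant_deletion_with_homology(g, "chrS1", 1000, 200, h = 6,
                                     kind = "TANDEM_DUPLICATION")
  expect_equal(junction_homology(pl$genome, "chrS1", 1000, 1200)$hom_total, 6L)

  expect_error(plant_deletion_with_homology(g, "chrS1", 1000, 3, h = 5),
               "insufficient room")
  expect_error(plant_deletion_with_homology(g, "chrS1", 1, 10, h = 8),
               "insufficient room")
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simulation_config(genome_length = 1e5, n_lines = 2, seed = 31,
                           td_size_sampler = function(k)
                             sample(500:2000, k, replace = TRUE))
  a <- simulate_ma_lines(cfg)
  b <- simulate_ma_lines(cfg)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$calls, b$calls)
})

test_that("zero rates produce an empty truth set", {
  cfg <- simulation_config(
    genome_length = 5e4, n_lines = 2, seed = 3,
    rates = c(DELETION = 0, DELETION_INSERTION = 0,
              TANDEM_DUPLICATION = 0, SNV = 0),
    noise_per_rule = 0L, n_shared = 0L, n_gen0 = 0L)
  ts <- simulate_ma_lines(cfg)
  expect_equal(nrow(ts$truth), 0)
  expect_equal(nrow(ts$calls), 0)
})

test_that("per-line event counts follow the configured Poisson accrual", {
  cfg <- simulation_config(
    genome_length = 3e6, n_lines = 50L, generations = 40L, seed = 17,
    rates = c(DELETION = 0.25, DELETION_INSERTION = 0,
              TANDEM_DUPLICATION = 0, SNV = 0),
    noise_per_rule = 0L, n_shared = 0L, n_gen0 = 0L)
  ts <- simulate_ma_lines(cfg)
  per_line <- table(factor(ts$truth$line_id, levels = cfg$lines$line_id))
  m <- mean(per_line)
  # mean of 50 Poisson(10) draws: within 3 standard errors of 10
  expect_lt(abs(m - 10), 3 * sqrt(10 / 50))
  expect_gt(stats::var(per_line), 10 * 0.4)  # dispersion is Poisson-like
})

test_that("forced templating makes every long insertion classifiable", {
  cfg <- simulation_config(
    genome_length = 5e5, n_lines = 3, seed = 41, templated_prob = 1,
    rates = c(DELETION = 0, DELETION_INSERTION = 0.2,
              TANDEM_DUPLICATION = 0, SNV = 0),
    noise_per_rule = 0L, n_shared = 0L, n_gen0 = 0L)
  ts <- simulate_ma_lines(cfg)
  expect_gt(nrow(ts$truth), 5)
  ann <- annotate_junctions(ts$truth, ts$genome)
  expect_true(all(ann$insertion_class == "TEMPLATED"))

  cfg0 <- simulation_config(
    genome_length = 5e5, n_lines = 3, seed = 42, templated_prob = 0,
    rates = c(DELETION = 0, DELETION_INSERTION = 0.2,
              TANDEM_DUPLICATION = 0, SNV = 0),
    noise_per_rule = 0L, n_shared = 0L, n_gen0 = 0L)
  ts0 <- simulate_ma_lines(cfg0)
  ann0 <- annotate_junctions(ts0$truth, ts0$genome)
  expect_true(all(ann0$insertion_class == "NON_TEMPLATED"))
})
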