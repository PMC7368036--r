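test_that("junction homology matches hand-worked examples", {
  g <- tiny_genome("TTCAGGGCATT")
  h <- junction_homology(g, "c1", 2, 7)
  expect_equal(h$hom_left, 0L)
  expect_equal(h$hom_right, 2L)
  expect_equal(h$hom_total, 2L)
  expect_equal(h$hom_seq, "CA")
  expect_true(h$evaluable)

  h <- junction_homology(tiny_genome("AAAAAA"), "c1", 1, 3)
  expect_equal(h$hom_left, 1L)
  expect_equal(h$hom_right, 3L)
  expect_equal(h$hom_total, 4L)

  h <- junction_homology(tiny_genome("ACGTACGT"), "c1", 1, 2)
  expect_equal(h$hom_total, 0L)

  expect_error(junction_homology(g, "c1", 5, 5), "start < end")
  expect_error(junction_homology(g, "c1", 5, 99), "start < end")
})

test_that("hom_total equals the placement-enumeration oracle on fuzzed events", {
  set.seed(101)
  for (i in 1:250) {
    L <- sample(20:200, 1)
    seq <- random_seq(L)
    g <- tiny_genome(seq)
    size <- sample(1:min(12, L - 2), 1)
    s <- sample(0:(L - size), 1)
    kind <- sample(c("DELETION", "TANDEM_DUPLICATION"), 1)
    apply_fn <- if (kind == "DELETION") oracle_apply_deletion else oracle_apply_td
    h <- junction_homology(g, "c1", s, s + size)
    expect_equal(h$hom_total,
                 oracle_count_placements(seq, s, s + size, apply_fn) - 1L,
                 info = sprintf("seq=%s s=%d size=%d kind=%s", seq, s, size, kind))
  }
})

test_that("hom_total is invariant across equivalent placements of one event", {
  set.seed(77)
  for (i in 1:40) {
    seq <- random_seq(80)
    g <- tiny_genome(seq)
    size <- sample(1:6, 1)
    s <- sample(0:(80 - size), 1)
    placements <- oracle_equivalent_placements(seq, s, s + size,
                                               oracle_apply_deletion)
    homs <- junction_homology(g, "c1", placements, placements + size)$hom_total
    expect_true(all(homs == homs[1]))
  }
})

test_that("junctions touching N are flagged not evaluable", {
  g <- tiny_genome("ACGTNACGTA")
  # right scan from start 1 vs end 5: A/A match at offset 3? position 4 is N
  h <- junction_homology(g, "c1", 4, 6)
  expect_false(h$evaluable)
  # far from the N everything is fine
  h2 <- junction_homology(tiny_genome("ACGTACGTAC"), "c1", 4, 6)
  expect_true(h2$evaluable)
})

test_that("templated insertions are recovered from constructed genomes", {
  # plant "GGCAT" so it occupies positions start-8 .. start-3
  left <- "ACACAC"          # 6 bases
  tmpl <- "GGCAT"           # positions 6..10, i.e. start - 8 .. start - 4
  pad <- "TAC"              # brings start to 14
  body <- "TTTTT"
  right <- "CACACACACA"
  seq <- paste0(left, tmpl, pad, body, right)
  g <- tiny_genome(seq)
  s <- nchar(left) + nchar(tmpl) + nchar(pad)   # 14
  ev <- ma_events("L1", "c1", s, s + nchar(body), "DELETION_INSERTION",
                  inserted_seq = tmpl)
  cls <- classify_insertions(g, ev)
  expect_equal(cls$insertion_class, "TEMPLATED")
  expect_equal(cls$template_orient, "FWD")
  expect_equal(cls$template_pos, 6L)

  # reverse-complement template is also found
  ev_rc <- ma_events("L1", "c1", s, s + nchar(body), "DELETION_INSERTION",
                     inserted_seq = revcomp(tmpl))
  cls_rc <- classify_insertions(g, ev_rc)
  expect_equal(cls_rc$insertion_class, "TEMPLATED")
  expect_equal(cls_rc$template_orient, "REVCOMP")

  # a poly-A insertion into a C/G neighbourhood cannot be templated
  gcg <- tiny_genome(paste(rep("CG", 40), collapse = ""))
  ev2 <- ma_events("L1", "c1", 30, 40, "DELETION_INSERTION",
                   inserted_seq = "AAAAA")
  expect_equal(classify_insertions(gcg, ev2)$insertion_class, "NON_TEMPLATED")

  # below the minimum inspectable length
  ev3 <- ma_events("L1", "c1", 30, 40, "DELETION_INSERTION",
                   inserted_seq = "ACG")
  expect_equal(classify_insertions(gcg, ev3)$insertion_class, "TOO_SHORT")

  expect_error(classify_insertions(g, ma_events("L1", "c1", 1, 5, "DELETION")),
               "inserted_seq")
})

test_that("templated search is strand-symmetric", {
  set.seed(31)
  for (i in 1:20) {
    seq <- random_seq(120)
    g <- tiny_genome(seq)
    s <- sample(30:60, 1); e <- s + sample(5:20, 1)
    ins <- random_seq(6)
    ev <- ma_events("L1", "c1", s, e, "DELETION_INSERTION", inserted_seq = ins)
    cls <- classify_insertions(g, ev)$insertion_class
    # mirror the whole configuration
    L <- nchar(seq)
    g_rc <- tiny_genome(revcomp(seq))
    ev_rc <- ma_events("L1", "c1", L - e, L - s, "DELETION_INSERTION",
                       inserted_seq = revcomp(ins))
    expect_equal(classify_insertions(g_rc, ev_rc)$insertion_class, cls)
  }
})

test_that("homology distributions count and summarise evaluable events", {
  g <- tiny_genome("TTCAGGGCATTAAAAAACGTACGT")
  ev <- ma_events(c("L1", "L1"), "c1", c(2, 20), c(7, 21), "DELETION",
                  genotype = "brc-1")
  ann <- annotate_junctions(ev, g)
  hd <- homology_distribution(ann)
  expect_equal(hd$summary$fraction_with_homology, 0.5)
  expect_equal(sum(hd$bins$n), 2)

  empty <- homology_distribution(annotate_junctions(ev[0, ], g))
  expect_equal(nrow(empty$summary), 0)
  expect_s3_class(autoplot(hd), "ggplot")
})

test_that("planted homology lengths are recovered exactly through annotation", {
  cfg <- simulation_config(
    genome_length = 3e5, n_lines = 4, generations = 30, seed = 19,
    homology_sampler = function(k) sample(0:3, k, replace = TRUE),
    td_size_sampler = function(k) sample(500:2000, k, replace = TRUE),
    noise_per_rule = 0L, n_shared = 0L, n_gen0 = 0L)
  ts <- simulate_ma_lines(cfg)
  sv <- ts$truth[ts$truth$kind != "SNV", ]
  ann <- annotate_junctions(ts$truth, ts$genome)
  expect_equal(ann$hom_total, sv$planted_hom)
  # the sampler is uniform on 0..3; recovered bin proportions must agree
  # with the planted draws exactly, and with 0.25 within binomial error
  tab <- tabulate(ann$hom_total + 1L, nbins = 4) / nrow(ann)
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / nrow(ann))))
})
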