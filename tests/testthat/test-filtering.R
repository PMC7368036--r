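snv_rec <- function(gt = "HOM", gq = 80, dp = 30, line = "L1", pos = 100,
                    caller = "gatk", alt = "T", id = NULL) {
  tibble::tibble(record_id = id %||% paste0("s", pos, line, gq, dp, gt),
                 line_id = line, caller = caller, contig = "c1",
                 start = pos, end = pos + 1L, kind = "SNV", inserted_seq = "",
                 ref_base = "A", alt_base = alt, gt = gt, gq = gq, dp = dp,
                 support_fwd = NA_real_, support_rev = NA_real_,
                 ref_support = NA_real_)
}

sv_rec <- function(fwd = 10, rev = 10, refs = 5, line = "L1", s = 200,
                   e = 250, kind = "DELETION", caller = "manta", ins = "",
                   id = NULL) {
  tibble::tibble(record_id = id %||% paste0("v", s, line, caller, fwd, rev, refs),
                 line_id = line, caller = caller, contig = "c1",
                 start = s, end = e, kind = kind, inserted_seq = ins,
                 ref_base = NA_character_, alt_base = NA_character_,
                 gt = "HOM", gq = NA_real_, dp = NA_real_,
                 support_fwd = fwd, support_rev = rev, ref_support = refs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SNV filter enforces HOM, GQ and DP at the printed boundaries", {
  cases <- list(
    list(rec = snv_rec("HOM", 40, 8), reason = NA_character_),
    list(rec = snv_rec("HOM", 39, 50), reason = "LOW_GQ"),
    list(rec = snv_rec("HOM", 40, 7), reason = "LOW_DP"),
    list(rec = snv_rec("HOM", 99, 7), reason = "LOW_DP"),
    list(rec = snv_rec("HET", 99, 99), reason = "NOT_HOM"),
    list(rec = snv_rec("OTHER", 99, 99), reason = "NOT_HOM")
  )
  for (cs in cases) {
    out <- filter_snv_calls(cs$rec)
    expect_identical(out$reason, cs$reason)
  }
  expect_error(filter_snv_calls(sv_rec()), "SNV")
})

test_that("SV filter enforces orientation, support and reference-read rules", {
  cases <- list(
    list(rec = sv_rec(5, 0, 0), reason = "ONE_ORIENTATION"),
    list(rec = sv_rec(0, 5, 0), reason = "ONE_ORIENTATION"),
    list(rec = sv_rec(2, 2, 0), reason = "LOW_SUPPORT"),
    list(rec = sv_rec(3, 2, 100), reason = "HIGH_REF_SUPPORT"),
    list(rec = sv_rec(3, 2, 99), reason = NA_character_),
    list(rec = sv_rec(1, 4, 0), reason = NA_character_),
    list(rec = sv_rec(2, 2, 100), reason = "LOW_SUPPORT")
  )
  for (cs in cases) {
    out <- filter_sv_calls(cs$rec)
    expect_identical(out$reason, cs$reason)
  }
  expect_error(filter_sv_calls(snv_rec()), "structural")
})

test_that("caller merging unifies normalized duplicates and keeps provenance", {
  g <- tiny_genome(paste(rep("ACGT", 100), collapse = ""))
  two <- dplyr::bind_rows(sv_rec(8, 9, 10, caller = "manta", id = "a"),
                          sv_rec(6, 12, 4, caller = "pindel", id = "b"))
  m <- merge_caller_calls(two, g)
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "manta,pindel")
  expect_equal(m$support_fwd, 8)
  expect_equal(m$support_rev, 12)
  expect_equal(m$ref_support, 4)

  # same coordinates, different kind: never merged
  mixed <- dplyr::bind_rows(sv_rec(kind = "DELETION", caller = "manta"),
                            sv_rec(kind = "TANDEM_DUPLICATION", caller = "pindel"))
  expect_equal(nrow(merge_caller_calls(mixed, g)), 2)

  # homopolymer ambiguity: [100,120) and [101,121) normalize identically
  gA <- tiny_genome(paste(rep("A", 400), collapse = ""))
  amb <- dplyr::bind_rows(sv_rec(s = 100, e = 120, caller = "manta"),
                          sv_rec(s = 101, e = 121, caller = "pindel"))
  m2 <- merge_caller_calls(amb, gA, tolerance_bp = 0)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, 0L)  # shifted to the homopolymer start
})

test_that("uniqueness and generation-0 subtraction reject shared events", {
  g <- tiny_genome(paste(rep("ACGT", 200), collapse = ""))
  md <- tibble::tibble(line_id = c("L1", "L2", "L3"), genotype = "brc-1",
                       generations = 40L)
  recs <- dplyr::bind_rows(
    sv_rec(line = "L1", s = 200, e = 250, id = "u1"),          # unique -> accept
    snv_rec(line = "L1", pos = 400, id = "n1"),                # shared SNV
    snv_rec(line = "L2", pos = 400, id = "n2"),                # shared SNV
    snv_rec(line = "L3", pos = 400, alt = "G", id = "n3"),     # same site, other allele
    sv_rec(line = "L2", s = 600, e = 640, id = "g1")           # matches gen0
  )
  gen0 <- ma_events("gen0", "c1", 600, 640, "DELETION", genotype = "brc-1")
  rep <- filter_calls(recs, g, md, gen0 = gen0)
  expect_setequal(rep$accepted$line_id[rep$accepted$kind == "DELETION"], "L1")
  # the same-site SNV with a different alternate allele survives
  expect_true(any(rep$accepted$kind == "SNV" & rep$accepted$start == 400 &
                    rep$accepted$alt_base == "G"))
  rej <- rep$rejected
  expect_setequal(rej$record_id[rej$reason == "NOT_UNIQUE"], c("n1", "n2"))
  expect_equal(rej$record_id[rej$reason == "GENERATION0"], "g1")
})

test_that("the accepted set is order-independent and filtering is idempotent", {
  cfg <- simulation_config(genome_length = 2e5, n_lines = 3, seed = 23,
                           td_size_sampler = function(k)
                             sample(500:2000, k, replace = TRUE))
  ts <- simulate_ma_lines(cfg)
  rep1 <- filter_calls(ts$calls, ts$genome, ts$metadata, gen0 = ts$gen0)
  set.seed(9)
  shuffled <- ts$calls[sample(nrow(ts$calls)), ]
  rep2 <- filter_calls(shuffled, ts$genome, ts$metadata, gen0 = ts$gen0)
  expect_identical(event_key(rep1$accepted), event_key(rep2$accepted))

  # idempotence: re-filtering records built from the accepted set accepts all
  acc <- rep1$accepted
  again <- tibble::tibble(
    record_id = paste0("r", seq_len(nrow(acc))), line_id = acc$line_id,
    caller = "merged", contig = acc$contig, start = acc$start, end = acc$end,
    kind = acc$kind, inserted_seq = acc$inserted_seq, ref_base = acc$ref_base,
    alt_base = acc$alt_base, gt = "HOM", gq = 99, dp = 50,
    support_fwd = 10, support_rev = 10, ref_support = 0)
  rep3 <- filter_calls(again, ts$genome, ts$metadata, gen0 = ts$gen0)
  expect_equal(nrow(rep3$rejected), 0)
  expect_identical(event_key(rep3$accepted), event_key(acc))
})

test_that("on simulated data the accepted set equals the planted truth exactly", {
  cfg <- simulation_config(genome_length = 3e5, n_lines = 4, seed = 57,
                           td_size_sampler = function(k)
                             sample(500:2000, k, replace = TRUE))
  ts <- simulate_ma_lines(cfg)
  rep <- filter_calls(ts$calls, ts$genome, ts$metadata, gen0 = ts$gen0)
  truth_norm <- left_normalize(ts$truth, ts$genome)
  expect_identical(event_key(rep$accepted), event_key(truth_norm))
  # every injected noise record is rejected for precisely the planted reason
  got <- rep$rejected[, c("record_id", "reason")]
  joined <- dplyr::inner_join(ts$noise, got, by = "record_id")
  expect_equal(nrow(joined), nrow(ts$noise))
  expect_identical(joined$reason, joined$expected_reason)
  expect_s3_class(glance(rep), "tbl_df")
})
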