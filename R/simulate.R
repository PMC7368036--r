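#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently from `base_freqs`. The default composition
#' mimics the AT-rich C. elegans genome (GC about 0.354).
#'
#' @param length Contig length in bases.
#' @param base_freqs Named frequencies over `A`, `C`, `G`, `T`.
#' @param seed Optional integer seed.
#' @param contig_name Name of the single generated contig.
#' @return A [ref_genome()].
#' @export
generate_genome <- function(length,
                            base_freqs = c(A = 0.323, C = 0.177,
                                           G = 0.177, T = 0.323),
                            seed = NULL, contig_name = "chrS1") {
  stopifnot(length >= 1)
  f <- base_freqs[c("A", "C", "G", "T")]
  if (any(is.na(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-6) {
    abort("base_freqs must be non-negative frequencies over A,C,G,T summing to 1")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  # utf8 codes for A, C, G, T; intToUtf8 builds the string in one pass
  seq <- intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, length,
                                                    replace = TRUE, prob = f)])
  ref_genome(setNames(seq, contig_name))
}

random_dna <- function(n, base_freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE,
                                         prob = base_freqs[c("A", "C", "G", "T")])],
        collapse = "")
}

different_base <- function(b) {
  pool <- setdiff(c("A", "C", "G", "T"), b)
  pool[sample.int(3L, 1L)]
}

# core homology-planting edit on a character vector (0-based s, e = s + size)
plant_core <- function(chars, s, size, h_l, h_r) {
  e <- s + size
  L <- length(chars)
  if (h_l > size - 1L || h_r > size - 1L) {
    abort("each homology arm must be shorter than the event size")
  }
  if (s - h_l - 1L < 0L || e + h_r > L - 1L) {
    abort("insufficient room on the contig to plant the requested homology")
  }
  # right arm: bases after the junction repeat the event's first h_r bases
  if (h_r > 0L) chars[(e + 1L):(e + h_r)] <- chars[(s + 1L):(s + h_r)]
  chars[e + h_r + 1L] <- different_base(chars[s + h_r + 1L])
  # left arm: bases before the event repeat its last h_l bases
  if (h_l > 0L) chars[(s - h_l + 1L):s] <- chars[(e - h_l + 1L):e]
  chars[s - h_l] <- different_base(chars[e - h_l])
  chars
}

#' Plant a deletion or tandem duplication with exact junction homology
#'
#' Rewrites the bases flanking the interval `[start, start + size)` so that
#' the event's junction carries exactly `h` nucleotides of micro-homology
#' (`hom_total` as scored by [junction_homology()]): `h` is split into a left
#' and right arm, matching bases are copied into the flanks, and the first
#' base beyond each arm is forced to mismatch so no accidental extension
#' survives. The returned event refers to the edited genome.
#'
#' @param genome A [ref_genome()].
#' @param contig Contig name.
#' @param start 0-based event start.
#' @param size Event size in bases (`size >= 2` when `h > 0`).
#' @param h Requested total homology; must satisfy `h <= 2 * (size - 1)` and
#'   leave room on the contig.
#' @param kind `"DELETION"` (default) or `"TANDEM_DUPLICATION"`.
#' @param h_left Optional explicit left arm; default splits `h` uniformly
#'   over the admissible splits.
#' @param line_id Line identifier stamped on the event.
#' @return A list with `genome` (edited), `event` (one-row event tibble) and
#'   the realized `h_left`, `h_right`.
#' @export
plant_deletion_with_homology <- function(genome, contig, start, size, h,
                                         kind = "DELETION", h_left = NULL,
                                         line_id = "planted") {
  stopifnot(inherits(genome, "ref_genome"), h >= 0, size >= 1)
  seq <- genome_contig(genome, contig)
  if (h > 2L * (size - 1L)) {
    abort("insufficient room: h may not exceed 2 * (size - 1)")
  }
  if (is.null(h_left)) {
    lo <- max(0L, h - (size - 1L)); hi <- min(h, size - 1L)
    h_left <- if (lo == hi) lo else sample(lo:hi, 1L)
  }
  h_right <- h - h_left
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars <- plant_core(chars, as.integer(start), as.integer(size),
                      as.integer(h_left), as.integer(h_right))
  genome$contigs[[contig]] <- paste(chars, collapse = "")
  genome$base_freqs <- base_composition(genome$contigs)
  ev <- ma_events(line_id = line_id, contig = contig, start = start,
                  end = start + size, kind = kind)
  list(genome = genome, event = ev, h_left = h_left, h_right = h_right)
}

#' Genotype rate presets for the simulator
#'
#' Per-generation event-class rates whose magnitudes follow the mutation
#' accumulation literature on HR-deficient nematodes: wild-type-like lines
#' gain roughly one deletion per 30 generations and essentially no tandem
#' duplications; BRCA1-pathway-deficient ("brc-1-like") lines gain deletions
#' every 3-4 generations, of which roughly 30 percent carry an insertion,
#' plus tandem duplications at about a tenth of the deletion rate; TMEJ
#' double mutants ("brc-1 polq-1-like") lose most structural-variant
#' formation again. SNV rates are modest in all genotypes.
#'
#' @param preset One of `"wild-type-like"`, `"brc-1-like"`,
#'   `"brc-1 polq-1-like"`.
#' @return Named numeric rates for `DELETION`, `DELETION_INSERTION`,
#'   `TANDEM_DUPLICATION`, `SNV` (events per generation).
#' @export
genotype_presets <- function(preset = c("brc-1-like", "wild-type-like",
                                        "brc-1 polq-1-like")) {
  preset <- match.arg(preset)
  switch(preset,
    "wild-type-like" = c(DELETION = 1 / 30, DELETION_INSERTION = 0.003,
                         TANDEM_DUPLICATION = 0.001, SNV = 0.15),
    "brc-1-like" = c(DELETION = 0.21, DELETION_INSERTION = 0.09,
                     TANDEM_DUPLICATION = 1 / 30, SNV = 0.25),
    "brc-1 polq-1-like" = c(DELETION = 0.03, DELETION_INSERTION = 0.005,
                            TANDEM_DUPLICATION = 0.004, SNV = 0.25)
  )
}

#' Simulator configuration
#'
#' Collects every knob of the MA-line simulator with defaults that mirror the
#' statistical structure the analysis assumes: Poisson event accrual per
#' generation at genotype-specific class rates, log-uniform deletion
#' (5-100 bp) and tandem-duplication (1-20 kb) sizes, a junction-homology
#' distribution concentrated on 0-6 nt, insertions of 5-20 bp that are
#' templated from within `window` bases of the junction with probability
#' `templated_prob`, and noisy caller records (one injected record per
#' filter rule per line by default).
#'
#' @param genome_length Genome size in bases (default 1e6; a scaled-down
#'   stand-in for the 100 Mb nematode genome).
#' @param base_freqs Genome base composition.
#' @param n_lines,generations,genotype Used to build a default line table
#'   when `lines` is `NULL`.
#' @param lines Optional metadata tibble (`line_id`, `genotype`,
#'   `generations`).
#' @param rates Named per-generation class rates; default
#'   `genotype_presets(genotype)`.
#' @param homology_sampler Function `k -> integer` planted `hom_total`
#'   values; default samples 0-6 with decreasing weights (21 percent zeros).
#' @param insertion_len_sampler Insertion lengths; default uniform 5-20.
#' @param templated_prob Probability an insertion is copied from the
#'   junction neighbourhood (default 0.73).
#' @param deletion_size_sampler,td_size_sampler Size distributions; defaults
#'   log-uniform on [5, 100] and [1000, 20000].
#' @param window,min_template_len Junction parameters (25 and 5).
#' @param noise_per_rule Injected records violating each per-record filter
#'   rule, per line.
#' @param n_shared Events planted identically in two lines (exercise the
#'   uniqueness filter).
#' @param n_gen0 Events planted in the generation-0 call set.
#' @param sv_callers,snv_caller Caller labels stamped on the records.
#' @param seed Integer seed; the whole simulation is reproducible given it.
#' @return A list of class `ma_sim_config`.
#' @export
simulation_config <- function(genome_length = 1e6,
                              base_freqs = c(A = 0.323, C = 0.177,
                                             G = 0.177, T = 0.323),
                              n_lines = 6L, generations = 40L,
                              genotype = "brc-1-like", lines = NULL,
                              rates = NULL,
                              homology_sampler = NULL,
                              insertion_len_sampler = NULL,
                              templated_prob = 0.73,
                              deletion_size_sampler = NULL,
                              td_size_sampler = NULL,
                              window = 25L, min_template_len = 5L,
                              noise_per_rule = 1L, n_shared = 1L,
                              n_gen0 = 1L,
                              sv_callers = c("manta", "pindel"),
                              snv_caller = "gatk", seed = 1L) {
  if (is.null(lines)) {
    lines <- tibble(
      line_id = sprintf("L%02d", seq_len(n_lines)),
      genotype = genotype,
      generations = as.integer(rep_len(generations, n_lines))
    )
  }
  if (is.null(rates)) {
    rates <- genotype_presets(lines$genotype[1])
  }
  log_uniform <- function(lo, hi) {
    force(lo); force(hi)
    function(k) as.integer(round(exp(runif(k, log(lo), log(hi)))))
  }
  cfg <- list(
    genome_length = genome_length, base_freqs = base_freqs, lines = lines,
    rates = rates,
    homology_sampler = homology_sampler %||%
      function(k) sample(0:6, k, replace = TRUE,
                         prob = c(0.21, 0.30, 0.20, 0.12, 0.08, 0.05, 0.04)),
    insertion_len_sampler = insertion_len_sampler %||%
      function(k) sample(5:20, k, replace = TRUE),
    templated_prob = templated_prob,
    deletion_size_sampler = deletion_size_sampler %||% log_uniform(5, 100),
    td_size_sampler = td_size_sampler %||% log_uniform(1000, 20000),
    window = as.integer(window), min_template_len = as.integer(min_template_len),
    noise_per_rule = as.integer(noise_per_rule), n_shared = as.integer(n_shared),
    n_gen0 = as.integer(n_gen0), sv_callers = sv_callers,
    snv_caller = snv_caller, seed = as.integer(seed)
  )
  structure(cfg, class = "ma_sim_config")
}

# non-overlapping locus allocator over one contig; margin keeps every
# event's edits and template window private. Starts are drawn uniformly from
# the exact set of admissible positions (occupied intervals subtracted), so
# placement succeeds whenever room exists, even for multi-kb duplications.
new_allocator <- function(contig_len, margin) {
  occupied <- matrix(numeric(0), ncol = 2)
  list(
    place = function(size) {
      lo_b <- margin
      hi_b <- contig_len - size - margin
      if (hi_b < lo_b) abort("contig too short for the requested event")
      # a start s is forbidden when [s - margin, s + size + margin) touches
      # an occupied interval [lo, hi)
      allowed <- matrix(c(lo_b, hi_b + 1), ncol = 2)
      if (nrow(occupied)) {
        forb <- cbind(occupied[, 1] - size - margin, occupied[, 2] + margin)
        forb <- forb[order(forb[, 1]), , drop = FALSE]
        pieces <- list()
        for (i in seq_len(nrow(allowed))) {
          a <- allowed[i, 1]; b <- allowed[i, 2]
          for (j in seq_len(nrow(forb))) {
            fa <- forb[j, 1]; fb <- forb[j, 2]
            if (fb <= a || fa >= b) next
            if (fa > a) pieces[[length(pieces) + 1L]] <- c(a, fa)
            a <- max(a, fb)
            if (a >= b) break
          }
          if (a < b) pieces[[length(pieces) + 1L]] <- c(a, b)
        }
        if (length(pieces) == 0) {
          abort("no room left to place a non-overlapping event")
        }
        allowed <- do.call(rbind, pieces)
      }
      lens <- allowed[, 2] - allowed[, 1]
      u <- runif(1, 0, sum(lens))
      idx <- which(cumsum(lens) > u)[1]
      offset <- u - if (idx > 1) cumsum(lens)[idx - 1] else 0
      s <- as.integer(floor(allowed[idx, 1] + offset))
      occupied <<- rbind(occupied, c(s - margin, s + size + margin))
      return(s)
    }
  )
}

#' Simulate MA lines with a planted truth set and noisy caller records
#'
#' For every line, per-class event counts are drawn
#' `Poisson(rate x generations)`; deletions and tandem duplications are
#' planted with exact junction homology ([plant_deletion_with_homology()]);
#' deletion-insertions receive insertions copied from the junction
#' neighbourhood (either orientation) with probability `templated_prob`, or
#' random sequence verified absent from that neighbourhood; SNVs are uniform
#' with a uniform alternate base. Every truth event gets caller records that
#' pass all filters (SVs from two callers); in addition, noise records each
#' violating exactly one filter rule are injected, shared events are planted
#' in two lines, and a generation-0 call set is produced, so the full
#' consolidation path is exercised.
#'
#' @param config An [simulation_config()].
#' @param genome Optional pre-built [ref_genome()]; generated from the config
#'   when `NULL`.
#' @return A list of class `ma_truth_set`: `genome` (edited reference),
#'   `metadata`, `truth` (planted events with `planted_hom`,
#'   `expected_insertion_class`, template provenance), `calls` (record
#'   tibble), `noise` (record_id and the filter reason each noise record must
#'   trigger), `gen0` (events), `config`.
#' @export
simulate_ma_lines <- function(config, genome = NULL) {
  stopifnot(inherits(config, "ma_sim_config"))
  withr::local_seed(config$seed)
  if (is.null(genome)) {
    genome <- generate_genome(config$genome_length, config$base_freqs)
  }
  contig <- names(genome$contigs)[1]
  chars <- strsplit(genome$contigs[[contig]], "", fixed = TRUE)[[1]]
  margin <- 300L
  alloc <- new_allocator(length(chars), margin)
  md <- config$lines

  truth <- list(); calls <- list(); noise <- list(); gen0 <- list()
  rec_no <- 0L
  next_id <- function() {
    rec_no <<- rec_no + 1L
    sprintf("r%05d", rec_no)
  }

  sv_record <- function(line_id, caller, s, e, kind, ins = "",
                        fwd = NULL, rev = NULL, refs = NULL) {
    tibble(record_id = next_id(), line_id = line_id, caller = caller,
           contig = contig, start = s, end = e, kind = kind,
           inserted_seq = ins, ref_base = NA_character_,
           alt_base = NA_character_, gt = "HOM",
           gq = NA_real_, dp = NA_real_,
           support_fwd = fwd %||% sample(3:20, 1),
           support_rev = rev %||% sample(3:20, 1),
           ref_support = refs %||% sample(0:50, 1))
  }
  snv_record <- function(line_id, caller, pos, ref, alt, gt = "HOM",
                         gq = NULL, dp = NULL) {
    tibble(record_id = next_id(), line_id = line_id, caller = caller,
           contig = contig, start = pos, end = pos + 1L, kind = "SNV",
           inserted_seq = "", ref_base = ref, alt_base = alt, gt = gt,
           gq = gq %||% sample(40:99, 1), dp = dp %||% sample(8:60, 1),
           support_fwd = NA_real_, support_rev = NA_real_,
           ref_support = NA_real_)
  }

  plant_sv <- function(line_id, kind) {
    size <- if (kind == "TANDEM_DUPLICATION") config$td_size_sampler(1)
            else config$deletion_size_sampler(1)
    size <- max(size, 2L)
    s <- alloc$place(size)
    e <- s + size
    h <- min(config$homology_sampler(1), 2L * (size - 1L))
    lo <- max(0L, h - (size - 1L)); hi <- min(h, size - 1L)
    h_l <- if (lo == hi) lo else sample(lo:hi, 1L)
    chars <<- plant_core(chars, s, size, h_l, h - h_l)
    ins <- ""
    templated <- NA; expected_class <- "NONE"
    tpos <- NA_integer_; torient <- NA_character_
    if (kind == "DELETION_INSERTION") {
      len <- config$insertion_len_sampler(1)
      w <- config$window
      ws <- s - w; we <- e + w
      slice <- paste(chars[(ws + 1L):we], collapse = "")
      templated <- runif(1) < config$templated_prob
      if (templated) {
        src <- sample(0:(nchar(slice) - len), 1L)
        piece <- substr(slice, src + 1L, src + len)
        if (runif(1) < 0.5) {
          ins <- piece; torient <- "FWD"
        } else {
          ins <- revcomp(piece); torient <- "REVCOMP"
        }
        tpos <- ws + src
        expected_class <- if (len < config$min_template_len) "TOO_SHORT"
                          else "TEMPLATED"
      } else {
        for (try in 1:100) {
          ins <- random_dna(len)
          if (!grepl(ins, slice, fixed = TRUE) &&
              !grepl(revcomp(ins), slice, fixed = TRUE)) break
          if (try == 100) abort("could not draw a non-templated insertion")
        }
        expected_class <- if (len < config$min_template_len) "TOO_SHORT"
                          else "NON_TEMPLATED"
      }
    }
    list(event = tibble(
      line_id = line_id, contig = contig, start = s, end = e, kind = kind,
      inserted_seq = ins, planted_hom = h, planted_h_left = h_l,
      planted_templated = templated, expected_insertion_class = expected_class,
      template_src_pos = tpos, template_src_orient = torient))
  }

  plant_snv <- function(line_id) {
    s <- alloc$place(1L)
    ref <- chars[s + 1L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    tibble(line_id = line_id, contig = contig, start = s, end = s + 1L,
           kind = "SNV", inserted_seq = "", planted_hom = NA_integer_,
           planted_h_left = NA_integer_, planted_templated = NA,
           expected_insertion_class = "NONE", template_src_pos = NA_integer_,
           template_src_orient = NA_character_, ref_base = ref, alt_base = alt)
  }

  for (i in seq_len(nrow(md))) {
    line <- md$line_id[i]
    gens <- md$generations[i]
    for (kind in SV_KINDS) {
      k <- rpois(1, config$rates[[kind]] * gens)
      for (j in seq_len(k)) {
        pl <- plant_sv(line, kind)
        truth[[length(truth) + 1L]] <- pl$event
        for (cal in config$sv_callers) {
          calls[[length(calls) + 1L]] <-
            sv_record(line, cal, pl$event$start, pl$event$end, kind,
                      ins = pl$event$inserted_seq)
        }
      }
    }
    k <- rpois(1, config$rates[["SNV"]] * gens)
    for (j in seq_len(k)) {
      ev <- plant_snv(line)
      truth[[length(truth) + 1L]] <- ev
      calls[[length(calls) + 1L]] <-
        snv_record(line, config$snv_caller, ev$start, ev$ref_base, ev$alt_base)
    }
    # injected noise: one family of records per per-record filter rule
    for (r in seq_len(config$noise_per_rule)) {
      s <- alloc$place(1L); ref <- chars[s + 1L]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rec <- snv_record(line, config$snv_caller, s, ref, alt, gt = "HET")
      calls[[length(calls) + 1L]] <- rec
      noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                            expected_reason = "NOT_HOM")
      s <- alloc$place(1L); ref <- chars[s + 1L]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rec <- snv_record(line, config$snv_caller, s, ref, alt, gq = 39)
      calls[[length(calls) + 1L]] <- rec
      noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                            expected_reason = "LOW_GQ")
      s <- alloc$place(1L); ref <- chars[s + 1L]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rec <- snv_record(line, config$snv_caller, s, ref, alt, dp = 7)
      calls[[length(calls) + 1L]] <- rec
      noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                            expected_reason = "LOW_DP")
      for (spec in list(list(reason = "ONE_ORIENTATION", fwd = 8, rev = 0,
                             refs = 10),
                        list(reason = "LOW_SUPPORT", fwd = 2, rev = 2,
                             refs = 10),
                        list(reason = "HIGH_REF_SUPPORT", fwd = 6, rev = 6,
                             refs = 100))) {
        sz <- max(config$deletion_size_sampler(1), 2L)
        s <- alloc$place(sz)
        rec <- sv_record(line, config$sv_callers[1], s, s + sz, "DELETION",
                         fwd = spec$fwd, rev = spec$rev, refs = spec$refs)
        calls[[length(calls) + 1L]] <- rec
        noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                              expected_reason = spec$reason)
      }
    }
  }

  # shared events: identical call in two lines -> NOT_UNIQUE in both
  if (config$n_shared > 0 && nrow(md) >= 2) {
    for (r in seq_len(config$n_shared)) {
      sz <- max(config$deletion_size_sampler(1), 2L)
      s <- alloc$place(sz)
      pair <- sample(md$line_id, 2L)
      for (line in pair) {
        rec <- sv_record(line, config$sv_callers[1], s, s + sz, "DELETION")
        calls[[length(calls) + 1L]] <- rec
        noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                              expected_reason = "NOT_UNIQUE")
      }
    }
  }

  # generation-0 events: present in the founder call set and in one line
  if (config$n_gen0 > 0) {
    for (r in seq_len(config$n_gen0)) {
      sz <- max(config$deletion_size_sampler(1), 2L)
      s <- alloc$place(sz)
      line <- sample(md$line_id, 1L)
      gen0[[length(gen0) + 1L]] <- tibble(
        line_id = "gen0", genotype = md$genotype[md$line_id == line],
        contig = contig, start = s, end = s + sz, kind = "DELETION",
        inserted_seq = "", ref_base = NA_character_, alt_base = NA_character_)
      rec <- sv_record(line, config$sv_callers[1], s, s + sz, "DELETION")
      calls[[length(calls) + 1L]] <- rec
      noise[[length(noise) + 1L]] <- tibble(record_id = rec$record_id,
                                            expected_reason = "GENERATION0")
    }
  }

  genome$contigs[[contig]] <- paste(chars, collapse = "")
  genome$base_freqs <- base_composition(genome$contigs)
  truth_tbl <- bind_rows(truth)
  if (nrow(truth_tbl) == 0) {
    truth_tbl <- tibble(line_id = character(), contig = character(),
                        start = integer(), end = integer(), kind = character(),
                        inserted_seq = character(), planted_hom = integer(),
                        planted_h_left = integer(), planted_templated = logical(),
                        expected_insertion_class = character(),
                        template_src_pos = integer(),
                        template_src_orient = character())
  }
  if (!"ref_base" %in% names(truth_tbl)) {
    truth_tbl$ref_base <- NA_character_
    truth_tbl$alt_base <- NA_character_
  }
  calls_tbl <- bind_rows(calls)
  if (nrow(calls_tbl) == 0) {
    calls_tbl <- tibble(record_id = character(), line_id = character(),
                        caller = character(), contig = character(),
                        start = integer(), end = integer(), kind = character())
  }
  structure(
    list(genome = genome, metadata = md,
         truth = truth_tbl,
         calls = validate_call_records(calls_tbl),
         noise = bind_rows(noise),
         gen0 = bind_rows(gen0), config = config),
    class = "ma_truth_set"
  )
}

#' @export
print.ma_truth_set <- function(x, ...) {
  cat("<ma_truth_set> ", nrow(x$metadata), " lines, ",
      nrow(x$truth), " planted events, ", nrow(x$calls),
      " call records (", nrow(x$noise), " noise)\n", sep = "")
  invisible(x)
}
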