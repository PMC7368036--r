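#' Raw variant call records
#'
#' One row per caller observation. Columns: `record_id`, `line_id`, `caller`,
#' `contig`, `start`, `end` (0-based half-open), `kind`, `inserted_seq`,
#' `ref_base`, `alt_base`, `gt` (zygosity call: `HOM`, `HET` or `OTHER`),
#' `gq`, `dp` (SNV evidence), `support_fwd`, `support_rev`, `ref_support`
#' (SV evidence). Missing evidence fields are `NA`.
#'
#' @param ... Columns passed to [tibble::tibble()].
#' @return A validated call-record tibble.
#' @export
ma_call_records <- function(...) {
  rec <- tibble(...)
  validate_call_records(rec)
}

CALL_RECORD_COLS <- c("record_id", "line_id", "caller", "contig", "start",
                      "end", "kind", "inserted_seq", "ref_base", "alt_base",
                      "gt", "gq", "dp", "support_fwd", "support_rev",
                      "ref_support")

validate_call_records <- function(rec) {
  defaults <- list(record_id = NA_character_, caller = "caller",
                   inserted_seq = "", ref_base = NA_character_,
                   alt_base = NA_character_, gt = NA_character_,
                   gq = NA_real_, dp = NA_real_, support_fwd = NA_real_,
                   support_rev = NA_real_, ref_support = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(rec)) rec[[nm]] <- defaults[[nm]]
  }
  need <- c("line_id", "contig", "start", "end", "kind")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols)) {
    abort(paste0("call records missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(rec$kind), ALL_KINDS)
  if (length(bad_kind)) abort(paste0("unknown call kind: ", bad_kind[1]))
  num <- c("support_fwd", "support_rev", "ref_support")
  if (any(unlist(rec[rec$kind %in% SV_KINDS, num]) < 0, na.rm = TRUE)) {
    abort("support counts must be non-negative")
  }
  if (any(is.na(rec$record_id))) {
    rec$record_id <- ifelse(is.na(rec$record_id),
                            sprintf("rec%06d", seq_len(nrow(rec))),
                            rec$record_id)
  }
  rec[, union(CALL_RECORD_COLS, names(rec))]
}

#' SNV quality filter
#'
#' Accepts a record iff it is called homozygous with genotype quality
#' `GQ >= gq_min` and depth `DP >= dp_min` (defaults 40 and 8). The first
#' failing rule, in the order `NOT_HOM`, `LOW_GQ`, `LOW_DP`, is reported as
#' the rejection reason.
#'
#' @param records Call-record tibble, SNVs only.
#' @param gq_min,dp_min Inclusive thresholds.
#' @return The records with a `reason` column (`NA` when accepted).
#' @export
filter_snv_calls <- function(records, gq_min = 40, dp_min = 8) {
  if (any(records$kind != "SNV")) abort("filter_snv_calls expects SNV records only")
  records$reason <- dplyr::case_when(
    is.na(records$gt) | records$gt != "HOM" ~ "NOT_HOM",
    is.na(records$gq) | records$gq < gq_min ~ "LOW_GQ",
    is.na(records$dp) | records$dp < dp_min ~ "LOW_DP",
    TRUE ~ NA_character_
  )
  records
}

#' Structural-variant support filter
#'
#' Accepts a record iff it is covered by both forward and reverse supporting
#' reads (`support_fwd >= 1` and `support_rev >= 1`), carries at least
#' `min_support` supporting reads in total, and has fewer than
#' `max_ref_support` reads supporting the reference allele. The first failing
#' rule, in the order `ONE_ORIENTATION`, `LOW_SUPPORT`, `HIGH_REF_SUPPORT`,
#' is reported.
#'
#' @param records Call-record tibble, SV kinds only.
#' @param min_support Minimum total supporting reads (default 5).
#' @param max_ref_support Exclusive reference-read bound (default 100:
#'   `ref_support` must be strictly below it).
#' @return The records with a `reason` column (`NA` when accepted).
#' @export
filter_sv_calls <- function(records, min_support = 5, max_ref_support = 100) {
  if (any(!records$kind %in% SV_KINDS)) {
    abort("filter_sv_calls expects structural-variant records only")
  }
  fwd <- dplyr::coalesce(records$support_fwd, 0)
  rev <- dplyr::coalesce(records$support_rev, 0)
  refs <- dplyr::coalesce(records$ref_support, Inf)
  records$reason <- dplyr::case_when(
    fwd < 1 | rev < 1 ~ "ONE_ORIENTATION",
    fwd + rev < min_support ~ "LOW_SUPPORT",
    refs >= max_ref_support ~ "HIGH_REF_SUPPORT",
    TRUE ~ NA_character_
  )
  records
}

#' Merge records of the same event from multiple callers
#'
#' Deletion and tandem-duplication records are left-normalized first, so that
#' callers that placed an ambiguous junction differently become comparable.
#' Records of the same line, kind and contig merge when their normalized
#' `start` and `end` each differ by at most `tolerance_bp`. Merged evidence
#' takes the per-field maximum of supporting counts (and of `gq`/`dp`) and
#' the minimum of `ref_support`; caller provenance is retained in a `callers`
#' column. SNVs merge on exact position and alternate allele;
#' deletion-insertions additionally require an identical inserted sequence.
#'
#' @param records Call-record tibble (any mix of kinds, one or more callers).
#' @param genome A [ref_genome()].
#' @param tolerance_bp Coordinate slack after normalization (default 10).
#' @return Deduplicated records with `callers` and `n_callers` columns.
#' @export
merge_caller_calls <- function(records, genome, tolerance_bp = 10L) {
  records <- validate_call_records(records)
  if (nrow(records) == 0) {
    records$callers <- character(0)
    records$n_callers <- integer(0)
    return(records)
  }
  records <- left_normalize(records, genome)
  keys <- split(seq_len(nrow(records)),
                paste(records$line_id, records$kind, records$contig, sep = "\r"))
  merged <- purrr::map(keys, function(idx) {
    sub <- records[idx, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$caller), , drop = FALSE]
    cl <- cluster_intervals(sub, tolerance_bp,
                            exact = sub$kind[1] == "SNV",
                            match_seq = sub$kind[1] %in%
                              c("SNV", "DELETION_INSERTION"))
    purrr::map(split(seq_len(nrow(sub)), cl), function(j) collapse_records(sub[j, ]))
  })
  out <- bind_rows(purrr::flatten(merged))
  out[order(out$line_id, out$contig, out$start, out$end, out$kind), ]
}

# greedy single-linkage-by-seed clustering of sorted interval records
cluster_intervals <- function(sub, tol, exact = FALSE, match_seq = FALSE) {
  n <- nrow(sub)
  cl <- integer(n)
  seed_start <- seed_end <- integer(0)
  seed_key <- character(0)
  key <- if (match_seq) {
    if (sub$kind[1] == "SNV") dplyr::coalesce(sub$alt_base, "")
    else toupper(dplyr::coalesce(sub$inserted_seq, ""))
  } else rep("", n)
  for (i in seq_len(n)) {
    assigned <- 0L
    for (k in seq_along(seed_start)) {
      same <- if (exact) {
        sub$start[i] == seed_start[k] && sub$end[i] == seed_end[k]
      } else {
        abs(sub$start[i] - seed_start[k]) <= tol &&
          abs(sub$end[i] - seed_end[k]) <= tol
      }
      if (same && key[i] == seed_key[k]) { assigned <- k; break }
    }
    if (assigned == 0L) {
      seed_start <- c(seed_start, sub$start[i])
      seed_end <- c(seed_end, sub$end[i])
      seed_key <- c(seed_key, key[i])
      assigned <- length(seed_start)
    }
    cl[i] <- assigned
  }
  cl
}

collapse_records <- function(grp) {
  out <- grp[1, , drop = FALSE]
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  min_or_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  out$gq <- max_or_na(grp$gq)
  out$dp <- max_or_na(grp$dp)
  out$support_fwd <- max_or_na(grp$support_fwd)
  out$support_rev <- max_or_na(grp$support_rev)
  out$ref_support <- min_or_na(grp$ref_support)
  # a homozygous call from any caller outranks HET/OTHER
  gts <- unique(grp$gt[!is.na(grp$gt)])
  out$gt <- if ("HOM" %in% gts) "HOM" else if (length(gts)) gts[1] else NA_character_
  out$callers <- paste(sort(unique(grp$caller)), collapse = ",")
  out$n_callers <- length(unique(grp$caller))
  out
}

#' Consolidate raw calls into unique, well-supported MA events
#'
#' The full consolidation path: per-line multi-caller merging
#' ([merge_caller_calls()]), per-record quality filters
#' ([filter_snv_calls()], [filter_sv_calls()]), cross-sample uniqueness (an
#' event present in two or more lines is rejected in all of them, reason
#' `NOT_UNIQUE`) and generation-0 subtraction (an event matching a call made
#' on the founder DNA of its lineage is rejected, reason `GENERATION0`, so
#' that variation present at the start of the experiment is not counted as
#' new mutation).
#'
#' @param records Call-record tibble for all lines and callers.
#' @param genome A [ref_genome()].
#' @param metadata Line metadata (see [read_line_metadata()]).
#' @param gen0 Optional event tibble of generation-0 calls. If both `gen0`
#'   and the line carry a non-`NA` `genotype`, matching is restricted to the
#'   same genotype (the founder lineage).
#' @param gq_min,dp_min SNV thresholds (defaults 40, 8).
#' @param min_support,max_ref_support SV thresholds (defaults 5, 100).
#' @param tolerance_bp Coordinate slack for merging and uniqueness matching.
#' @return An object of class `ma_filter_report`: a list with `accepted`
#'   (typed event tibble with a `callers` column), `rejected` (merged records
#'   plus a `reason` column) and `params`.
#' @export
filter_calls <- function(records, genome, metadata, gen0 = NULL,
                         gq_min = 40, dp_min = 8, min_support = 5,
                         max_ref_support = 100, tolerance_bp = 10L) {
  merged <- merge_caller_calls(records, genome, tolerance_bp = tolerance_bp)
  is_snv <- merged$kind == "SNV"
  snv <- filter_snv_calls(merged[is_snv, , drop = FALSE], gq_min, dp_min)
  sv <- filter_sv_calls(merged[!is_snv, , drop = FALSE], min_support,
                        max_ref_support)
  scored <- bind_rows(snv, sv)
  surv <- scored[is.na(scored$reason), , drop = FALSE]
  surv <- mark_not_unique(surv, tolerance_bp)
  if (!is.null(gen0) && nrow(gen0) > 0) {
    gen0 <- left_normalize(gen0, genome)
    surv <- mark_generation0(surv, gen0, metadata, tolerance_bp)
  }
  rejected <- bind_rows(scored[!is.na(scored$reason), , drop = FALSE],
                        surv[!is.na(surv$reason), , drop = FALSE])
  accepted_rec <- surv[is.na(surv$reason), , drop = FALSE]
  accepted <- records_to_events(accepted_rec, metadata)
  structure(
    list(accepted = accepted, rejected = rejected,
         params = list(gq_min = gq_min, dp_min = dp_min,
                       min_support = min_support,
                       max_ref_support = max_ref_support,
                       tolerance_bp = tolerance_bp)),
    class = "ma_filter_report"
  )
}

event_match_id <- function(rec, tol) {
  # cluster events across lines: same kind/contig, coords within tol,
  # identical alt (SNV) or inserted sequence (deletion-insertion)
  id <- integer(nrow(rec))
  grp <- split(seq_len(nrow(rec)), paste(rec$kind, rec$contig, sep = "\r"))
  nxt <- 0L
  for (idx in grp) {
    sub <- rec[idx, , drop = FALSE]
    ord <- order(sub$start, sub$end)
    cl <- cluster_intervals(sub[ord, , drop = FALSE], tol,
                            exact = sub$kind[1] == "SNV",
                            match_seq = sub$kind[1] %in%
                              c("SNV", "DELETION_INSERTION"))
    id[idx[ord]] <- cl + nxt
    nxt <- nxt + max(cl)
  }
  id
}

mark_not_unique <- function(surv, tol) {
  if (nrow(surv) == 0) return(surv)
  mid <- event_match_id(surv, tol)
  shared <- tapply(surv$line_id, mid, function(x) length(unique(x)) >= 2)
  surv$reason <- ifelse(as.vector(shared[as.character(mid)]),
                        "NOT_UNIQUE", NA_character_)
  surv
}

mark_generation0 <- function(surv, gen0, metadata, tol) {
  live <- which(is.na(surv$reason))
  if (length(live) == 0 || nrow(gen0) == 0) return(surv)
  sub <- surv[live, , drop = FALSE]
  sub_geno <- metadata$genotype[match(sub$line_id, metadata$line_id)]
  g0_geno <- if ("genotype" %in% names(gen0)) gen0$genotype else
    rep(NA_character_, nrow(gen0))
  combined <- bind_rows(
    tibble(kind = sub$kind, contig = sub$contig, start = sub$start,
           end = sub$end, alt_base = sub$alt_base,
           inserted_seq = sub$inserted_seq, src = "line", i = seq_len(nrow(sub)),
           geno = sub_geno),
    tibble(kind = gen0$kind, contig = gen0$contig, start = gen0$start,
           end = gen0$end, alt_base = gen0$alt_base,
           inserted_seq = gen0$inserted_seq, src = "gen0",
           i = seq_len(nrow(gen0)), geno = g0_geno)
  )
  mid <- event_match_id(combined, tol)
  for (m in unique(mid)) {
    rows <- which(mid == m)
    g0 <- combined[rows, ][combined$src[rows] == "gen0", ]
    ln <- combined[rows, ][combined$src[rows] == "line", ]
    if (nrow(g0) == 0 || nrow(ln) == 0) next
    for (j in seq_len(nrow(ln))) {
      geno_ok <- any(is.na(g0$geno)) || is.na(ln$geno[j]) ||
        ln$geno[j] %in% g0$geno
      if (geno_ok) surv$reason[live[ln$i[j]]] <- "GENERATION0"
    }
  }
  surv
}

records_to_events <- function(rec, metadata) {
  if (nrow(rec) == 0) {
    ev <- ma_events(character(), character(), integer(), integer(), character())
    ev$callers <- character(0)
    return(ev)
  }
  ev <- ma_events(
    line_id = rec$line_id, contig = rec$contig, start = rec$start,
    end = rec$end, kind = rec$kind,
    genotype = metadata$genotype[match(rec$line_id, metadata$line_id)],
    inserted_seq = dplyr::coalesce(rec$inserted_seq, ""),
    ref_base = rec$ref_base, alt_base = rec$alt_base
  )
  ev$callers <- rec$callers %||% rec$caller
  ev
}

#' @export
print.ma_filter_report <- function(x, ...) {
  cat("<ma_filter_report> ", nrow(x$accepted), " accepted, ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' @rdname filter_calls
#' @param x An `ma_filter_report`.
#' @param ... Unused.
#' @method tidy ma_filter_report
#' @export
tidy.ma_filter_report <- function(x, ...) {
  bind_rows(
    mutate(x$accepted, status = "accepted", reason = NA_character_),
    mutate(select(x$rejected, -any_of("status")), status = "rejected")
  )
}

#' @rdname filter_calls
#' @method glance ma_filter_report
#' @export
glance.ma_filter_report <- function(x, ...) {
  reasons <- c("NOT_HOM", "LOW_GQ", "LOW_DP", "ONE_ORIENTATION", "LOW_SUPPORT",
               "HIGH_REF_SUPPORT", "NOT_UNIQUE", "GENERATION0")
  counts <- table(factor(x$rejected$reason, levels = reasons))
  out <- tibble(n_accepted = nrow(x$accepted), n_rejected = nrow(x$rejected))
  for (r in reasons) out[[paste0("n_", tolower(r))]] <- as.integer(counts[[r]])
  out
}

#' Write a filter report to TSV
#'
#' @param report An `ma_filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  td <- tidy(report)
  td[] <- lapply(td, function(col) {
    if (is.character(col)) ifelse(is.na(col) | col == "", ".", col) else col
  })
  write.table(td, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
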