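#' Read and write call-record tables
#'
#' TSV round-trip for [ma_call_records()] tibbles. Coordinates on disk are
#' 1-based inclusive (as in the event tables); `.` means missing.
#'
#' @param path Path to a TSV file.
#' @return A call-record tibble.
#' @export
read_call_records <- function(path) {
  raw <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = "character"))
  need <- c("line_id", "caller", "contig", "start", "end", "kind")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("call-record table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dot_na <- function(x) ifelse(is.na(x) | x == "." | x == "", NA_character_, x)
  num <- function(x) suppressWarnings(as.numeric(dot_na(x)))
  start1 <- suppressWarnings(as.integer(raw$start))
  end1 <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad)) abort(sprintf("malformed coordinates in call-record row %d", bad[1]))
  getc <- function(nm, default = NA_character_) {
    if (nm %in% names(raw)) dot_na(raw[[nm]]) else rep(default, nrow(raw))
  }
  getn <- function(nm) if (nm %in% names(raw)) num(raw[[nm]]) else rep(NA_real_, nrow(raw))
  ins <- getc("inserted_seq"); ins[is.na(ins)] <- ""
  validate_call_records(tibble(
    record_id = getc("record_id"), line_id = raw$line_id, caller = raw$caller,
    contig = raw$contig, start = start1 - 1L, end = end1, kind = raw$kind,
    inserted_seq = ins, ref_base = getc("ref_base"),
    alt_base = getc("alt_base"), gt = getc("gt"),
    gq = getn("gq"), dp = getn("dp"), support_fwd = getn("support_fwd"),
    support_rev = getn("support_rev"), ref_support = getn("ref_support")
  ))
}

#' @rdname read_call_records
#' @param records Call-record tibble.
#' @export
write_call_records <- function(records, path) {
  out <- as.data.frame(records[, intersect(CALL_RECORD_COLS, names(records))])
  out$start <- out$start + 1L
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    ifelse(is.na(col) | col == "", ".", col)
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full MA analysis pipeline
#'
#' Executes filter, junction annotation, homology distribution, random-null,
#' rate and spectrum stages on one set of inputs and (optionally) writes
#' every result plus a JSON manifest with the counts at each stage. Inputs
#' can be given as in-memory objects or as file paths (FASTA genome, TSV
#' call records / metadata / generation-0 events).
#'
#' @param genome A [ref_genome()] or FASTA path.
#' @param calls Call-record tibble or TSV path.
#' @param metadata Metadata tibble or TSV path.
#' @param gen0 Optional generation-0 event tibble or TSV path.
#' @param out_dir Optional output directory; created if needed. When `NULL`
#'   nothing is written.
#' @param gq_min,dp_min,min_support,max_ref_support,tolerance_bp Filter
#'   thresholds (see [filter_calls()]).
#' @param max_scan,min_template_len,window Junction parameters.
#' @param null_n Random deletions drawn for the null stage (0 skips it).
#' @param rate_method `"welch"` or `"pooled"` for genotype comparisons; every
#'   genotype is compared to the first genotype in the metadata.
#' @param seed Seed consumed by the stochastic null stage.
#' @return A list of class `ma_pipeline_result`: `report`, `annotations`,
#'   `hom_dist`, `null`, `line_summary`, `comparisons`, `spectrum`,
#'   `manifest`.
#' @export
run_pipeline <- function(genome, calls, metadata, gen0 = NULL, out_dir = NULL,
                         gq_min = 40, dp_min = 8, min_support = 5,
                         max_ref_support = 100, tolerance_bp = 10L,
                         max_scan = 200L, min_template_len = 5L, window = 25L,
                         null_n = 10000L, rate_method = "welch", seed = 1L) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(metadata)) metadata <- read_line_metadata(metadata)
  if (is.character(calls)) calls <- read_call_records(calls)
  if (is.character(gen0)) gen0 <- read_event_table(gen0, tibble(
    line_id = "gen0", genotype = NA_character_, generations = 1L))

  report <- filter_calls(calls, genome, metadata, gen0 = gen0,
                         gq_min = gq_min, dp_min = dp_min,
                         min_support = min_support,
                         max_ref_support = max_ref_support,
                         tolerance_bp = tolerance_bp)
  ann <- annotate_junctions(report$accepted, genome, max_scan = max_scan,
                            min_template_len = min_template_len,
                            window = window)
  hd <- homology_distribution(ann)
  nul <- if (null_n > 0) {
    null_homology_fraction(genome, n = null_n, seed = seed)
  }
  ls <- summarize_lines(report$accepted, metadata)
  genos <- unique(metadata$genotype)
  comparisons <- list()
  lines_per_geno <- table(metadata$genotype)
  if (length(genos) >= 2 && lines_per_geno[[genos[1]]] >= 2) {
    for (g in genos[-1]) {
      if (lines_per_geno[[g]] < 2) next
      for (cl in c(ALL_KINDS, "DELETION_ALL")) {
        comparisons[[length(comparisons) + 1L]] <-
          compare_rates(ls, cl, g, genos[1], method = rate_method)
      }
    }
  }
  comparisons <- bind_rows(comparisons)
  spec <- substitution_spectrum(report$accepted, metadata)

  manifest <- list(
    n_input_records = nrow(calls),
    n_accepted = nrow(report$accepted),
    n_rejected = nrow(report$rejected),
    n_rejected_by_reason = as.list(table(report$rejected$reason)),
    n_annotated = nrow(ann),
    n_evaluable = sum(ann$evaluable),
    n_templated = sum(ann$insertion_class == "TEMPLATED"),
    accepted_by_class = as.list(table(report$accepted$kind)),
    null_fraction_with_homology =
      if (!is.null(nul)) nul$fraction_with_homology else NULL,
    params = list(gq_min = gq_min, dp_min = dp_min, min_support = min_support,
                  max_ref_support = max_ref_support,
                  tolerance_bp = tolerance_bp, max_scan = max_scan,
                  min_template_len = min_template_len, window = window,
                  null_n = null_n, rate_method = rate_method, seed = seed)
  )

  res <- structure(
    list(report = report, annotations = ann, hom_dist = hd, null = nul,
         line_summary = ls, comparisons = comparisons, spectrum = spec,
         manifest = manifest),
    class = "ma_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, nm) {
    write.table(as.data.frame(x), file.path(out_dir, nm), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_filter_report(res$report, file.path(out_dir, "filter_report.tsv"))
  write_event_table(res$report$accepted[, c("line_id", "genotype", "contig",
                                            "start", "end", "kind",
                                            "inserted_seq", "ref_base",
                                            "alt_base")],
                    file.path(out_dir, "events.tsv"))
  tsv(res$annotations[, setdiff(names(res$annotations), "callers")],
      "junctions.tsv")
  tsv(res$hom_dist$bins, "homology_distribution.tsv")
  tsv(res$line_summary, "line_summary.tsv")
  if (nrow(res$comparisons)) tsv(res$comparisons, "rate_comparisons.tsv")
  tsv(res$spectrum, "spectrum.tsv")
  if (!is.null(res$null)) {
    tsv(res$null$histogram, "null_histogram.tsv")
    jsonlite::write_json(glance(res$null),
                         file.path(out_dir, "null_result.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ma_pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<ma_pipeline_result>\n",
      "  records in: ", m$n_input_records,
      "; accepted events: ", m$n_accepted,
      "; rejected: ", m$n_rejected, "\n", sep = "")
  if (!is.null(m$null_fraction_with_homology)) {
    cat("  null homology fraction: ",
        sprintf("%.3f", m$null_fraction_with_homology), "\n", sep = "")
  }
  invisible(x)
}

#' Write a truth set to files
#'
#' Materializes a simulated experiment as the on-disk formats the pipeline
#' consumes: genome FASTA, call-record TSV, metadata TSV, generation-0 event
#' TSV, truth event TSV and a JSON echo of the scalar configuration.
#'
#' @param truth_set An `ma_truth_set` from [simulate_ma_lines()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(truth_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(truth_set$genome, file.path(dir, "genome.fa"))
  write_call_records(truth_set$calls, file.path(dir, "calls.tsv"))
  write.table(as.data.frame(truth_set$metadata),
              file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(truth_set$gen0)) {
    write_event_table(truth_set$gen0, file.path(dir, "gen0_events.tsv"))
  }
  tr <- truth_set$truth
  tr$genotype <- truth_set$metadata$genotype[
    match(tr$line_id, truth_set$metadata$line_id)]
  write.table(as.data.frame(tr), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth_set$config
  scalars <- cfg[vapply(cfg, function(x)
    is.atomic(x) && length(x) <= 8 && !is.function(x), logical(1))]
  jsonlite::write_json(scalars, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
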