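#' Typed mutation events
#'
#' Events are rows of a tibble with columns `line_id`, `genotype` (optional,
#' `NA` allowed), `contig`, `start`, `end` (0-based half-open), `kind` (one of
#' `DELETION`, `DELETION_INSERTION`, `TANDEM_DUPLICATION`, `SNV`),
#' `inserted_seq` (empty unless the junction carries inserted bases),
#' `ref_base`, `alt_base` (SNVs only). SNVs occupy the single-base interval
#' `[pos, pos + 1)`.
#'
#' @param line_id,contig,start,end,kind Vectors of equal length (or length 1).
#' @param genotype,inserted_seq,ref_base,alt_base Optional columns; defaults
#'   are `NA` / empty.
#' @return A tibble of events.
#' @export
ma_events <- function(line_id, contig, start, end, kind,
                      genotype = NA_character_, inserted_seq = "",
                      ref_base = NA_character_, alt_base = NA_character_) {
  ev <- tibble(
    line_id = as.character(line_id),
    genotype = as.character(genotype),
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    kind = as.character(kind),
    inserted_seq = as.character(inserted_seq),
    ref_base = as.character(ref_base),
    alt_base = as.character(alt_base)
  )
  validate_events(ev)
}

validate_events <- function(ev, genome = NULL) {
  bad_kind <- setdiff(unique(ev$kind), ALL_KINDS)
  if (length(bad_kind)) abort(paste0("unknown event kind: ", bad_kind[1]))
  if (any(ev$start < 0) || any(ev$end <= ev$start)) {
    abort("event coordinates must satisfy 0 <= start < end")
  }
  ins <- !is.na(ev$inserted_seq) & nzchar(ev$inserted_seq)
  if (any(ev$kind == "DELETION" & ins)) {
    abort("DELETION events cannot carry inserted_seq (use DELETION_INSERTION)")
  }
  if (any(ev$kind == "DELETION_INSERTION" & !ins)) {
    abort("DELETION_INSERTION events require a non-empty inserted_seq")
  }
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    unknown <- setdiff(unique(ev$contig), names(lens))
    if (length(unknown)) abort(paste0("unknown contig: ", unknown[1]))
    if (any(ev$end > lens[ev$contig])) abort("event end exceeds contig length")
  }
  ev
}

#' Read MA-line metadata
#'
#' Tab-separated with header columns `line_id`, `genotype`, `generations`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per MA line.
#' @export
read_line_metadata <- function(path) {
  md <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character"))
  need <- c("line_id", "genotype", "generations")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  md$generations <- suppressWarnings(as.integer(md$generations))
  if (any(is.na(md$generations)) || any(md$generations < 1)) {
    abort("generations must be a positive integer for every line")
  }
  if (anyDuplicated(md$line_id)) abort("duplicate line_id in metadata")
  md[, need]
}

#' Read an event table
#'
#' Ingests flat event tables (TSV, header `line_id`, `genotype`, `contig`,
#' `start`, `end`, `kind`, `inserted_seq`, `ref_base`, `alt_base`; extra
#' columns tolerated; `.` means empty). Input coordinates are 1-based
#' inclusive and converted to the internal 0-based half-open convention.
#' Rows are cross-checked against the line metadata; a `DELETION` row carrying
#' inserted bases is reclassified `DELETION_INSERTION` with a warning.
#'
#' @param path Path to the TSV file.
#' @param metadata Line metadata tibble (see [read_line_metadata()]).
#' @return A tibble of typed events (possibly empty).
#' @export
read_event_table <- function(path, metadata) {
  raw <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = "character"))
  need <- c("line_id", "contig", "start", "end", "kind")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("event table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(ma_events(character(), character(), integer(), integer(), character()))
  }
  dot_na <- function(x) ifelse(is.na(x) | x == "." | x == "", NA_character_, x)
  start1 <- suppressWarnings(as.integer(raw$start))
  end1 <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad)) {
    abort(sprintf("malformed coordinates in event table row %d", bad[1]))
  }
  unknown <- setdiff(unique(raw$line_id), metadata$line_id)
  if (length(unknown)) {
    abort(paste0("event table references unknown line_id: ", unknown[1]))
  }
  ins <- dot_na(if ("inserted_seq" %in% names(raw)) raw$inserted_seq else NA)
  ins[is.na(ins)] <- ""
  kind <- raw$kind
  reclass <- kind == "DELETION" & nzchar(ins)
  if (any(reclass)) {
    warn(sprintf(
      "%d DELETION row(s) carry inserted bases; reclassified as DELETION_INSERTION",
      sum(reclass)))
    kind[reclass] <- "DELETION_INSERTION"
  }
  geno <- metadata$genotype[match(raw$line_id, metadata$line_id)]
  ma_events(
    line_id = raw$line_id, contig = raw$contig,
    start = start1 - 1L, end = end1, kind = kind,
    genotype = geno, inserted_seq = ins,
    ref_base = dot_na(if ("ref_base" %in% names(raw)) raw$ref_base else NA),
    alt_base = dot_na(if ("alt_base" %in% names(raw)) raw$alt_base else NA)
  )
}

#' Write an event table
#'
#' Inverse of [read_event_table()]: internal 0-based half-open coordinates are
#' written 1-based inclusive; empty fields are written `.`.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  und <- function(x) ifelse(is.na(x) | x == "", ".", x)
  out <- data.frame(
    line_id = events$line_id,
    genotype = und(events$genotype),
    contig = events$contig,
    start = events$start + 1L,
    end = events$end,
    kind = events$kind,
    inserted_seq = und(events$inserted_seq),
    ref_base = und(events$ref_base),
    alt_base = und(events$alt_base),
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Left-normalize deletions and tandem duplications
#'
#' An event `[s, e)` and its shift `[s - 1, e - 1)` describe the same mutated
#' sequence exactly when the genome base at `s - 1` equals the base at
#' `e - 1`. Ambiguous calls are shifted to the smallest possible start so that
#' records from different callers become comparable. Only `DELETION` and
#' `TANDEM_DUPLICATION` events move; other kinds are returned unchanged.
#' Shifting never crosses an `N`.
#'
#' @param events Event tibble (or a call-record tibble with `contig`, `start`,
#'   `end`, `kind` columns).
#' @param genome A [ref_genome()].
#' @return The tibble with normalized `start`/`end`.
#' @export
left_normalize <- function(events, genome) {
  if (nrow(events) == 0) return(events)
  lens <- contig_lengths(genome)
  unknown <- setdiff(unique(events$contig), names(lens))
  if (length(unknown)) abort(paste0("unknown contig: ", unknown[1]))
  if (any(events$start < 0 | events$end > lens[events$contig])) {
    abort("event coordinates out of contig range")
  }
  movable <- events$kind %in% c("DELETION", "TANDEM_DUPLICATION")
  for (i in which(movable)) {
    seq <- genome$contigs[[events$contig[i]]]
    s <- events$start[i]; e <- events$end[i]
    while (s > 0) {
      a <- base_at(seq, s - 1L); b <- base_at(seq, e - 1L)
      if (a != b || a == "N" || b == "N") break
      s <- s - 1L; e <- e - 1L
    }
    events$start[i] <- s; events$end[i] <- e
  }
  events
}
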