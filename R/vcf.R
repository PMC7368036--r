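#' Per-caller VCF ingestion
#'
#' Reads a single-sample VCF 4.2 produced by one caller for one MA line and
#' maps it onto the package's call-record tibble. SNVs are taken from
#' single-base REF/ALT rows with `GT`/`GQ`/`DP`; structural variants from
#' symbolic `<DEL>` / `<DUP:TANDEM>` alleles (or explicit-allele deletions)
#' with `INFO/END`. Supporting-read counts live in caller-specific fields;
#' `field_map` names them as `"FORMAT/<key>"` or `"INFO/<key>"` entries for
#' `support_fwd`, `support_rev` and `ref_support` (defaults match
#' [write_calls_vcf()]). Inserted sequence at a deletion junction may be
#' provided via `INFO/INSSEQ`.
#'
#' POS of a structural variant row is the anchor base before the affected
#' segment, so internal 0-based half-open coordinates are `start = POS`,
#' `end = INFO/END`. SNVs convert as `pos = POS - 1`.
#'
#' @param path VCF path (plain text or bgzip).
#' @param line_id MA line the file belongs to.
#' @param caller Caller label stamped on the records.
#' @param field_map Named list for the SV evidence fields, see above.
#' @return A call-record tibble.
#' @export
read_caller_vcf <- function(path, line_id, caller,
                            field_map = list(support_fwd = "FORMAT/SVF",
                                             support_rev = "FORMAT/SVR",
                                             ref_support = "FORMAT/SVREF")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_caller_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(validate_call_records(tibble(
      record_id = character(), line_id = character(), caller = character(),
      contig = character(), start = integer(), end = integer(),
      kind = character())))
  }
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  get_fmt <- function(key) {
    out <- tryCatch(vcfR::extract.gt(v, element = key),
                    error = function(e) NULL)
    if (is.null(out)) rep(NA_character_, n) else out[, 1]
  }
  get_info <- function(key) vcfR::extract.info(v, element = key)
  pick <- function(slot) {
    spec <- field_map[[slot]]
    if (is.null(spec)) return(rep(NA_real_, n))
    parts <- strsplit(spec, "/", fixed = TRUE)[[1]]
    val <- if (toupper(parts[1]) == "FORMAT") get_fmt(parts[2]) else
      get_info(parts[2])
    suppressWarnings(as.numeric(val))
  }
  svtype <- get_info("SVTYPE")
  end_info <- suppressWarnings(as.integer(get_info("END")))
  insseq <- get_info("INSSEQ")
  gt_raw <- get_fmt("GT")
  gt <- dplyr::case_when(
    gt_raw %in% c("1/1", "1|1") ~ "HOM",
    gt_raw %in% c("0/1", "1/0", "0|1", "1|0") ~ "HET",
    TRUE ~ "OTHER"
  )
  is_sym_del <- alt == "<DEL>"
  is_sym_dup <- alt %in% c("<DUP:TANDEM>", "<DUP>")
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  is_expl_del <- !is_snv & !is_sym_del & !is_sym_dup &
    nchar(ref) > 1 & !grepl("<", alt, fixed = TRUE)
  kind <- rep(NA_character_, n)
  kind[is_snv] <- "SNV"
  kind[is_sym_dup] <- "TANDEM_DUPLICATION"
  ins <- rep("", n)
  ins[!is.na(insseq) & !is_snv] <- toupper(insseq[!is.na(insseq) & !is_snv])
  # explicit-allele deletion: REF = anchor + deleted bases, ALT = anchor (+ ins)
  ins[is_expl_del] <- ifelse(nchar(alt[is_expl_del]) > 1,
                             toupper(substr(alt[is_expl_del], 2,
                                            nchar(alt[is_expl_del]))),
                             ins[is_expl_del])
  del <- is_sym_del | is_expl_del
  kind[del] <- ifelse(nzchar(ins[del]), "DELETION_INSERTION", "DELETION")
  if (any(is.na(kind))) {
    bad <- which(is.na(kind))[1]
    abort(sprintf("unsupported VCF record at %s:%s (REF=%s, ALT=%s)",
                  fix[bad, "CHROM"], fix[bad, "POS"], ref[bad], alt[bad]))
  }
  start <- ifelse(kind == "SNV", pos - 1L, pos)
  end <- ifelse(kind == "SNV", pos,
                ifelse(is_expl_del, pos + nchar(ref) - 1L, end_info))
  if (any(kind != "SNV" & (is.na(end) | end <= start))) {
    abort("structural-variant VCF records need a valid INFO/END")
  }
  validate_call_records(tibble(
    record_id = paste0(caller, "_", seq_len(n)),
    line_id = line_id, caller = caller,
    contig = fix[, "CHROM"], start = as.integer(start), end = as.integer(end),
    kind = kind, inserted_seq = ins,
    ref_base = ifelse(kind == "SNV", ref, NA_character_),
    alt_base = ifelse(kind == "SNV", alt, NA_character_),
    gt = gt,
    gq = suppressWarnings(as.numeric(get_fmt("GQ"))),
    dp = suppressWarnings(as.numeric(get_fmt("DP"))),
    support_fwd = pick("support_fwd"),
    support_rev = pick("support_rev"),
    ref_support = pick("ref_support")
  ))
}

#' Write call records for one line/caller as VCF 4.2
#'
#' Structural variants are written with symbolic alleles (`<DEL>`,
#' `<DUP:TANDEM>`), `INFO/END`, `INFO/INSSEQ` for junction insertions, and
#' FORMAT fields `SVF`/`SVR`/`SVREF` for forward/reverse supporting reads
#' and reference-supporting reads; SNVs carry `GT`/`GQ`/`DP`. The REF column
#' of SV rows holds the anchor base when a genome is supplied, `N`
#' otherwise.
#'
#' @param records Call-record tibble, one line and one caller.
#' @param path Output path.
#' @param genome Optional [ref_genome()] used for anchor bases.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(records, path, genome = NULL) {
  if (length(unique(records$line_id)) > 1 ||
      length(unique(records$caller)) > 1) {
    abort("write_calls_vcf expects records of a single line and caller")
  }
  sample_name <- if (nrow(records)) records$line_id[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Junction insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SVF,Number=1,Type=Integer,Description=\"Forward supporting reads\">",
    "##FORMAT=<ID=SVR,Number=1,Type=Integer,Description=\"Reverse supporting reads\">",
    "##FORMAT=<ID=SVREF,Number=1,Type=Integer,Description=\"Reference supporting reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  rows <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    gt <- switch(if (is.na(r$gt)) "HOM" else r$gt,
                 HOM = "1/1", HET = "0/1", "./.")
    if (r$kind == "SNV") {
      rows[i] <- paste(r$contig, r$start + 1L, r$record_id, r$ref_base,
                       r$alt_base, ".", "PASS", ".",
                       "GT:GQ:DP",
                       paste(gt, as.integer(r$gq), as.integer(r$dp), sep = ":"),
                       sep = "\t")
    } else {
      anchor <- if (!is.null(genome) && r$start >= 1) {
        fetch_seq(genome, r$contig, r$start - 1L, r$start)
      } else "N"
      alt <- if (r$kind == "TANDEM_DUPLICATION") "<DUP:TANDEM>" else "<DEL>"
      svtype <- if (r$kind == "TANDEM_DUPLICATION") "DUP" else "DEL"
      info <- paste0("SVTYPE=", svtype, ";END=", r$end)
      if (!is.na(r$inserted_seq) && nzchar(r$inserted_seq)) {
        info <- paste0(info, ";INSSEQ=", r$inserted_seq)
      }
      rows[i] <- paste(r$contig, r$start, r$record_id, anchor, alt, ".",
                       "PASS", info, "GT:SVF:SVR:SVREF",
                       paste(gt, as.integer(r$support_fwd),
                             as.integer(r$support_rev),
                             as.integer(r$ref_support), sep = ":"),
                       sep = "\t")
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
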