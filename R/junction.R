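#' Score micro-homology at a breakpoint junction
#'
#' Micro-homology is formalized as the placement-ambiguity length of the
#' event: `hom_right` is the longest common prefix of the two suffixes
#' beginning at `start` and at `end`, `hom_left` the longest common suffix of
#' the two prefixes ending at `start` and at `end`, and
#' `hom_total = hom_left + hom_right`. An event `[s, e)` has exactly
#' `hom_total + 1` equivalent placements on the genome, so the score does not
#' depend on how the caller placed the event. The same formula applies to
#' deletion and to tandem-duplication junctions, whose shift condition is
#' identical.
#'
#' Scans are capped at `max_scan` bases and at the contig boundaries. If a
#' compared base is `N` the scan stops there and the junction is flagged not
#' evaluable (`evaluable = FALSE`); lengths are reported as computed up to
#' the `N`.
#'
#' @param genome A [ref_genome()].
#' @param contig Contig name (scalar or vector).
#' @param start,end 0-based half-open event coordinates, `start < end`.
#' @param max_scan Maximum homology length scanned per side (default 200,
#'   far above any junction homology reported for TMEJ products).
#' @return A tibble with columns `hom_left`, `hom_right`, `hom_total`,
#'   `hom_seq` (the matched bases, left then right) and `evaluable`.
#' @examples
#' g <- ref_genome(c(c1 = "TTCAGGGCATT"))
#' junction_homology(g, "c1", 2, 7) # hom_right 2 ("CA")
#' @export
junction_homology <- function(genome, contig, start, end, max_scan = 200L) {
  n <- max(length(contig), length(start), length(end))
  contig <- rep_len(as.character(contig), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  lens <- contig_lengths(genome)
  unknown <- setdiff(unique(contig), names(lens))
  if (length(unknown)) abort(paste0("unknown contig: ", unknown[1]))
  if (any(start < 0 | start >= end | end > lens[contig])) {
    abort("junction coordinates must satisfy 0 <= start < end <= contig length")
  }
  hl <- hr <- integer(n)
  ev <- rep(TRUE, n)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    seq <- genome$contigs[[ct]]
    sc <- scan_junctions_vec(seq, start[idx], end[idx], max_scan)
    hl[idx] <- sc$hom_left; hr[idx] <- sc$hom_right; ev[idx] <- sc$evaluable
  }
  hom_seq <- character(n)
  has_hom <- hl + hr > 0L
  if (any(has_hom)) {
    i <- which(has_hom)
    seqs <- genome$contigs[contig[i]]
    hom_seq[i] <- paste0(substring(seqs, start[i] - hl[i] + 1L, start[i]),
                         substring(seqs, start[i] + 1L, start[i] + hr[i]))
  }
  tibble(hom_left = hl, hom_right = hr, hom_total = hl + hr,
         hom_seq = hom_seq, evaluable = ev)
}

# vectorized junction scan over one contig: advances all events one base per
# pass, so the number of passes equals the longest homology found (+1)
scan_junctions_vec <- function(seq, s, e, max_scan) {
  L <- nchar(seq)
  n <- length(s)
  r <- l <- integer(n)
  evaluable <- rep(TRUE, n)
  # rightward: seq[s + k] vs seq[e + k]
  active <- rep(TRUE, n)
  k <- 0L
  while (k < max_scan && any(active)) {
    active <- active & (e + k < L)
    if (!any(active)) break
    i <- which(active)
    a <- substring(seq, s[i] + k + 1L, s[i] + k + 1L)
    b <- substring(seq, e[i] + k + 1L, e[i] + k + 1L)
    isN <- a == "N" | b == "N"
    evaluable[i[isN]] <- FALSE
    match <- !isN & a == b
    r[i[match]] <- k + 1L
    active[i[!match]] <- FALSE
    k <- k + 1L
  }
  # leftward: seq[s - 1 - k] vs seq[e - 1 - k]
  active <- rep(TRUE, n)
  k <- 0L
  while (k < max_scan && any(active)) {
    active <- active & (s - 1L - k >= 0L)
    if (!any(active)) break
    i <- which(active)
    a <- substring(seq, s[i] - k, s[i] - k)
    b <- substring(seq, e[i] - k, e[i] - k)
    isN <- a == "N" | b == "N"
    evaluable[i[isN]] <- FALSE
    match <- !isN & a == b
    l[i[match]] <- k + 1L
    active[i[!match]] <- FALSE
    k <- k + 1L
  }
  list(hom_left = l, hom_right = r, evaluable = evaluable)
}

#' Classify a junction insertion as templated or not
#'
#' An insertion is called `TEMPLATED` when the inserted bases occur exactly,
#' in forward or reverse-complement orientation, within the reference slice
#' `[start - window, end + window)` around the event (the slice includes the
#' deleted or duplicated body) -- the hallmark of polymerase-theta snap-back
#' synthesis. Insertions shorter than `min_template_len` are `TOO_SHORT`
#' (too little sequence to map reliably); everything else is
#' `NON_TEMPLATED`.
#'
#' The reported template hit is the match nearest to a breakpoint; ties break
#' forward-orientation first, then leftmost.
#'
#' @param genome A [ref_genome()].
#' @param events Event tibble; every row must carry a non-empty
#'   `inserted_seq`.
#' @param min_template_len Minimum insertion length inspected (default 5).
#' @param window Bases scanned beyond each breakpoint (default 25).
#' @return A tibble with columns `insertion_class` (`TEMPLATED`,
#'   `NON_TEMPLATED`, `TOO_SHORT`), `template_pos` (0-based genome start of
#'   the matched template, `NA` if none), `template_orient` (`FWD` or
#'   `REVCOMP`) and `template_dist` (bases between the match and the nearest
#'   breakpoint).
#' @export
classify_insertions <- function(genome, events, min_template_len = 5L,
                                window = 25L) {
  ins <- events$inserted_seq
  if (any(is.na(ins) | !nzchar(ins))) {
    abort("classify_insertions requires events with a non-empty inserted_seq")
  }
  lens <- contig_lengths(genome)
  res <- purrr::map(seq_len(nrow(events)), function(i) {
    x <- toupper(ins[i])
    if (nchar(x) < min_template_len) {
      return(list(class = "TOO_SHORT", pos = NA_integer_,
                  orient = NA_character_, dist = NA_integer_))
    }
    seq <- genome$contigs[[events$contig[i]]]
    s <- events$start[i]; e <- events$end[i]
    ws <- max(0L, s - as.integer(window))
    we <- min(lens[[events$contig[i]]], e + as.integer(window))
    slice <- substr(seq, ws + 1L, we)
    hits <- template_hits(slice, x, ws, s, e)
    if (nrow(hits) == 0) {
      return(list(class = "NON_TEMPLATED", pos = NA_integer_,
                  orient = NA_character_, dist = NA_integer_))
    }
    hits <- hits[order(hits$dist, hits$orient != "FWD", hits$pos), , drop = FALSE]
    list(class = "TEMPLATED", pos = hits$pos[1], orient = hits$orient[1],
         dist = hits$dist[1])
  })
  tibble(
    insertion_class = purrr::map_chr(res, "class"),
    template_pos = purrr::map_int(res, "pos"),
    template_orient = purrr::map_chr(res, "orient"),
    template_dist = purrr::map_int(res, "dist")
  )
}

template_hits <- function(slice, x, offset0, s, e) {
  find <- function(pattern) {
    m <- gregexpr(pattern, slice, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L + offset0
  }
  w <- nchar(x)
  fwd <- find(x)
  rc <- find(revcomp(x))
  pos <- c(fwd, rc)
  orient <- rep(c("FWD", "REVCOMP"), c(length(fwd), length(rc)))
  if (length(pos) == 0) {
    return(data.frame(pos = integer(0), orient = character(0), dist = integer(0)))
  }
  # distance from the matched interval [pos, pos + w) to the nearer breakpoint
  dist_to <- function(p, bp) {
    if (bp >= p && bp <= p + w) 0L else as.integer(min(abs(p - bp), abs(p + w - bp)))
  }
  dist <- vapply(pos, function(p) min(dist_to(p, s), dist_to(p, e)), integer(1))
  data.frame(pos = pos, orient = orient, dist = dist, stringsAsFactors = FALSE)
}

#' Annotate structural events with junction features
#'
#' Runs [junction_homology()] on every deletion / deletion-insertion /
#' tandem-duplication event and [classify_insertions()] on the events that
#' carry inserted bases. Events without an insertion get
#' `insertion_class = "NONE"`.
#'
#' @param events Event tibble (SNVs, if present, are dropped with a message).
#' @param genome A [ref_genome()].
#' @param max_scan,min_template_len,window See [junction_homology()] and
#'   [classify_insertions()].
#' @return The event tibble with the annotation columns appended.
#' @export
annotate_junctions <- function(events, genome, max_scan = 200L,
                               min_template_len = 5L, window = 25L) {
  if (any(events$kind == "SNV")) {
    events <- filter(events, .data$kind != "SNV")
  }
  if (nrow(events) == 0) {
    return(mutate(events,
                  hom_left = integer(), hom_right = integer(),
                  hom_total = integer(), hom_seq = character(),
                  evaluable = logical(), insertion_class = character(),
                  template_pos = integer(), template_orient = character(),
                  template_dist = integer(), size = integer()))
  }
  hom <- junction_homology(genome, events$contig, events$start, events$end,
                           max_scan = max_scan)
  out <- dplyr::bind_cols(events, hom)
  out$size <- out$end - out$start
  out$insertion_class <- "NONE"
  out$template_pos <- NA_integer_
  out$template_orient <- NA_character_
  out$template_dist <- NA_integer_
  has_ins <- !is.na(out$inserted_seq) & nzchar(out$inserted_seq)
  if (any(has_ins)) {
    cls <- classify_insertions(genome, out[has_ins, , drop = FALSE],
                               min_template_len = min_template_len,
                               window = window)
    out$insertion_class[has_ins] <- cls$insertion_class
    out$template_pos[has_ins] <- cls$template_pos
    out$template_orient[has_ins] <- cls$template_orient
    out$template_dist[has_ins] <- cls$template_dist
  }
  out
}

#' Per-genotype micro-homology distribution
#'
#' Bins annotated events by `hom_total` (`0, 1, ..., cap, >cap`) and reports
#' the fraction of evaluable, insertion-free events with at least one
#' matching nucleotide at the junction. Events carrying an insertion are
#' counted in their own bins but excluded from `fraction_with_homology`,
#' which mirrors how the homology overrepresentation of TMEJ deletions is
#' quantified against a random baseline.
#'
#' @param annotations Output of [annotate_junctions()].
#' @param cap Largest individually binned homology length (default 10).
#' @param size_max Optional upper size bound (bases); events of size
#'   `>= size_max` are dropped first (e.g. 100 to restrict to small
#'   deletions).
#' @return An object of class `ma_homology_distribution`: a list with
#'   `bins` (tibble: genotype, hom_bin, has_insertion, n) and `summary`
#'   (tibble: genotype, n_evaluable, n_insertion_free, fraction_with_homology;
#'   the fraction is `NA` when no evaluable insertion-free events exist).
#' @export
homology_distribution <- function(annotations, cap = 10L, size_max = NULL) {
  ann <- annotations
  if (!is.null(size_max)) ann <- filter(ann, .data$size < size_max)
  ann <- filter(ann, .data$evaluable)
  if (!"genotype" %in% names(ann)) ann$genotype <- NA_character_
  ann$has_insertion <- !is.na(ann$inserted_seq) & nzchar(ann$inserted_seq)
  bin_levels <- c(as.character(0:cap), paste0(">", cap))
  if (nrow(ann) == 0) {
    res <- list(
      bins = tibble(genotype = character(), hom_bin = character(),
                    has_insertion = logical(), n = integer()),
      summary = tibble(genotype = character(), n_evaluable = integer(),
                       n_insertion_free = integer(),
                       fraction_with_homology = double()),
      cap = cap
    )
    return(structure(res, class = "ma_homology_distribution"))
  }
  ann$hom_bin <- ifelse(ann$hom_total > cap, paste0(">", cap),
                        as.character(ann$hom_total))
  ann$hom_bin <- factor(ann$hom_bin, levels = bin_levels)
  bins <- ann |>
    count(.data$genotype, .data$hom_bin, .data$has_insertion, name = "n") |>
    mutate(hom_bin = as.character(.data$hom_bin))
  summary <- ann |>
    group_by(.data$genotype) |>
    summarise(
      n_evaluable = n(),
      n_insertion_free = sum(!.data$has_insertion),
      fraction_with_homology = if (sum(!.data$has_insertion) == 0) NA_real_ else
        sum(.data$hom_total >= 1 & !.data$has_insertion) / sum(!.data$has_insertion),
      .groups = "drop"
    )
  structure(list(bins = bins, summary = summary, cap = cap),
            class = "ma_homology_distribution")
}

#' @export
print.ma_homology_distribution <- function(x, ...) {
  cat("<ma_homology_distribution>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname homology_distribution
#' @param x An `ma_homology_distribution`.
#' @param ... Unused.
#' @method tidy ma_homology_distribution
#' @export
tidy.ma_homology_distribution <- function(x, ...) x$bins

#' @rdname homology_distribution
#' @method glance ma_homology_distribution
#' @export
glance.ma_homology_distribution <- function(x, ...) x$summary
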