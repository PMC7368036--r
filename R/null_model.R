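#' Sample random deletions from a genome
#'
#' The in-silico null model for junction micro-homology: deletions placed
#' uniformly at random (contig chosen proportional to its length, start
#' uniform within the contig) with sizes drawn from `size_sampler`. Events
#' whose body contains an `N` or that exceed the contig bounds are
#' resampled.
#'
#' @param genome A [ref_genome()].
#' @param n Number of deletions.
#' @param size_sampler Function `n -> integer sizes`; default uniform
#'   integers on `[size_min, size_max]`.
#' @param size_min,size_max Bounds of the default size distribution
#'   (5 and 50).
#' @param min_size Smallest admissible size (default 2; size-1 deletions make
#'   the left and right junction comparisons overlap).
#' @param seed Optional integer seed; fixing it makes the draw reproducible.
#' @param max_attempts Resampling budget, as a multiple of `n` (default 100).
#' @return An event tibble of `n` `DELETION` rows (`line_id = "null"`).
#' @export
sample_random_deletions <- function(genome, n, size_sampler = NULL,
                                    size_min = 5L, size_max = 50L,
                                    min_size = 2L, seed = NULL,
                                    max_attempts = 100L) {
  stopifnot(inherits(genome, "ref_genome"), n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(size_sampler)) {
    size_sampler <- function(k) sample.int(size_max - size_min + 1L, k,
                                           replace = TRUE) + size_min - 1L
  }
  lens <- contig_lengths(genome)
  if (max(lens) < max(min_size, size_min)) {
    abort("genome contigs are shorter than the smallest deletion size")
  }
  has_n <- any(stringr::str_detect(genome$contigs, "N"))
  out_contig <- character(0); out_start <- integer(0); out_size <- integer(0)
  attempts <- 0L
  while (length(out_start) < n) {
    need <- n - length(out_start)
    attempts <- attempts + need
    if (attempts > max_attempts * n) {
      abort("could not place random deletions (genome too short or too many Ns)")
    }
    sizes <- as.integer(size_sampler(need))
    if (any(sizes < min_size)) abort("size_sampler produced sizes below min_size")
    ci <- sample.int(length(lens), need, replace = TRUE, prob = lens)
    fit <- lens[ci] - sizes >= 0
    starts <- ifelse(fit,
                     floor(runif(need) * (lens[ci] - sizes + 1)), NA_integer_)
    keep <- fit & !is.na(starts)
    if (has_n && any(keep)) {
      body_ok <- vapply(which(keep), function(j) {
        !stringr::str_detect(
          substr(genome$contigs[[ci[j]]], starts[j] + 1L, starts[j] + sizes[j]),
          "N")
      }, logical(1))
      keep[which(keep)] <- body_ok
    }
    out_contig <- c(out_contig, names(lens)[ci[keep]])
    out_start <- c(out_start, as.integer(starts[keep]))
    out_size <- c(out_size, sizes[keep])
  }
  ma_events(line_id = "null", contig = out_contig, start = out_start,
            end = out_start + out_size, kind = "DELETION")
}

#' Analytic micro-homology probability under i.i.d. bases
#'
#' For a random junction on an i.i.d. genome with base frequencies `f`,
#' two specific positions carry the same base with probability
#' `p = sum(f^2)`. At least one matched nucleotide on the right flank and on
#' the left flank each occur with probability `p`, independently, so the
#' probability that a random deletion junction shows any micro-homology
#' (`hom_total >= 1`) is `1 - (1 - p)^2`. This closed form is the validation
#' oracle for the Monte-Carlo null; on real (non-i.i.d.) genomes the
#' simulated value is authoritative.
#'
#' @param base_freqs Named numeric over `A`, `C`, `G`, `T`, summing to 1.
#' @return A probability.
#' @examples
#' expected_homology_fraction(c(A = .25, C = .25, G = .25, T = .25)) # 0.4375
#' @export
expected_homology_fraction <- function(base_freqs) {
  f <- base_freqs[c("A", "C", "G", "T")]
  if (any(is.na(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-6) {
    abort("base_freqs must be non-negative frequencies over A,C,G,T summing to 1")
  }
  p <- sum(f^2)
  1 - (1 - p)^2
}

#' Monte-Carlo null distribution of junction micro-homology
#'
#' Samples random deletions ([sample_random_deletions()]), scores each
#' junction with [junction_homology()] and reports the observed fraction with
#' `hom_total >= 1` alongside the analytic i.i.d. expectation for the
#' genome's base composition.
#'
#' @inheritParams sample_random_deletions
#' @param max_scan Homology scan cap (see [junction_homology()]).
#' @return An object of class `ma_null_result`: list with
#'   `fraction_with_homology`, `n`, `n_evaluable`, `analytic_expectation`,
#'   `mc_se` (binomial standard error at the analytic value) and `histogram`
#'   (tibble of `hom_total` counts over evaluable junctions).
#' @export
null_homology_fraction <- function(genome, n = 10000L, size_sampler = NULL,
                                   size_min = 5L, size_max = 50L,
                                   min_size = 2L, seed = NULL,
                                   max_scan = 200L) {
  ev <- sample_random_deletions(genome, n, size_sampler = size_sampler,
                                size_min = size_min, size_max = size_max,
                                min_size = min_size, seed = seed)
  hom <- junction_homology(genome, ev$contig, ev$start, ev$end,
                           max_scan = max_scan)
  ok <- hom$evaluable
  n_eval <- sum(ok)
  frac <- if (n_eval == 0) NA_real_ else mean(hom$hom_total[ok] >= 1)
  q <- expected_homology_fraction(genome$base_freqs)
  hist <- count(tibble(hom_total = hom$hom_total[ok]), .data$hom_total,
                name = "n")
  structure(
    list(fraction_with_homology = frac, n = n, n_evaluable = n_eval,
         analytic_expectation = q,
         mc_se = sqrt(q * (1 - q) / max(n_eval, 1)),
         histogram = hist),
    class = "ma_null_result"
  )
}

#' @export
print.ma_null_result <- function(x, ...) {
  cat("<ma_null_result> ", x$n_evaluable, " evaluable junctions\n",
      "  fraction with homology >= 1 nt: ",
      sprintf("%.4f", x$fraction_with_homology),
      " (analytic i.i.d. expectation ",
      sprintf("%.4f", x$analytic_expectation), ")\n", sep = "")
  invisible(x)
}

#' @rdname null_homology_fraction
#' @param x An `ma_null_result`.
#' @param ... Unused.
#' @method tidy ma_null_result
#' @export
tidy.ma_null_result <- function(x, ...) x$histogram

#' @rdname null_homology_fraction
#' @method glance ma_null_result
#' @export
glance.ma_null_result <- function(x, ...) {
  tibble(fraction_with_homology = x$fraction_with_homology,
         analytic_expectation = x$analytic_expectation,
         mc_se = x$mc_se, n = x$n, n_evaluable = x$n_evaluable)
}
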