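#' Per-line event counts and per-generation rates
#'
#' Tallies events per MA line and event class and divides by the number of
#' propagated generations, the rate definition used throughout MA
#' experiments (events per generation per line). Lines with no events
#' appear with zero counts. Besides the four elementary classes, the
#' combined class `DELETION_ALL` (`DELETION` plus `DELETION_INSERTION`) is
#' tallied, since figures in this field group the two either way.
#'
#' @param events Typed event tibble (e.g. the `accepted` set of
#'   [filter_calls()]).
#' @param metadata Line metadata tibble (`line_id`, `genotype`,
#'   `generations`).
#' @return A tibble with one row per line and class: `line_id`, `genotype`,
#'   `generations`, `class`, `count`, `rate`.
#' @examples
#' md <- tibble::tibble(line_id = "L1", genotype = "brc-1", generations = 50L)
#' ev <- ma_events("L1", "chrI", 100, 120, "DELETION")
#' summarize_lines(ev, md)
#' @export
summarize_lines <- function(events, metadata) {
  unknown <- setdiff(unique(events$line_id), metadata$line_id)
  if (length(unknown)) {
    abort(paste0("events reference line_id absent from metadata: ", unknown[1]))
  }
  classes <- c(ALL_KINDS, "DELETION_ALL")
  grid <- tidyr::expand_grid(line_id = metadata$line_id, class = classes)
  base_counts <- events |>
    count(.data$line_id, class = .data$kind, name = "count")
  combined <- events |>
    filter(.data$kind %in% c("DELETION", "DELETION_INSERTION")) |>
    count(.data$line_id, name = "count") |>
    mutate(class = "DELETION_ALL")
  counts <- bind_rows(base_counts, combined)
  grid |>
    left_join(counts, by = c("line_id", "class")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    left_join(metadata, by = "line_id") |>
    mutate(rate = .data$count / .data$generations) |>
    select("line_id", "genotype", "generations", "class", "count", "rate") |>
    arrange(match(.data$line_id, metadata$line_id), match(.data$class, classes))
}

#' Compare per-generation rates between two genotypes
#'
#' Two-tailed t-test on the per-line rates (each MA line is one biological
#' replicate), Welch by default with a pooled-variance option. Group SEMs use
#' the number of lines. When both groups have zero variance the statistic is
#' defined by continuity: `t = 0`, `p = 1` for equal means, `|t| = Inf`,
#' `p = 0` otherwise.
#'
#' @param line_summary Output of [summarize_lines()].
#' @param class Event class to compare.
#' @param genotype_a,genotype_b Genotype labels present in the summary.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return A one-row tibble: genotypes, class, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `fold_change` (`mean_a / mean_b`),
#'   `t_statistic`, `df`, `p_value`, `method`.
#' @export
compare_rates <- function(line_summary, class, genotype_a, genotype_b,
                          method = c("welch", "pooled")) {
  method <- match.arg(method)
  pick <- function(g) {
    line_summary$rate[line_summary$genotype == g & line_summary$class == class]
  }
  a <- pick(genotype_a); b <- pick(genotype_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("compare_rates needs at least 2 lines per genotype (SEM undefined otherwise)")
  }
  wt <- welch_t(a, b, pooled = method == "pooled")
  tibble(
    genotype_a = genotype_a, genotype_b = genotype_b, class = class,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sd(a) / sqrt(length(a)), sem_b = sd(b) / sqrt(length(b)),
    fold_change = mean(a) / mean(b),
    t_statistic = wt$t, df = wt$df, p_value = wt$p, method = method
  )
}

welch_t <- function(a, b, pooled = FALSE) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = na + nb - 2,
                p = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Collapse a base substitution to the six-class pyrimidine frame
#'
#' Substitutions are reported with a pyrimidine (`C` or `T`) reference base;
#' purine-reference changes are strand-complemented (`G>A` becomes `C>T`),
#' giving the conventional six classes `C>A`, `C>G`, `C>T`, `T>A`, `T>C`,
#' `T>G`.
#'
#' @param ref_base,alt_base Single bases in `{A,C,G,T}`, `ref != alt`
#'   elementwise. Vectorized.
#' @return Character vector of class labels.
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  ok <- ref_base %in% c("A", "C", "G", "T") & alt_base %in% c("A", "C", "G", "T")
  if (any(!ok)) abort("substitution bases must be in {A,C,G,T}")
  if (any(ref_base == alt_base)) abort("ref_base and alt_base must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref_base %in% c("A", "G")
  r <- ifelse(flip, comp[ref_base], ref_base)
  a <- ifelse(flip, comp[alt_base], alt_base)
  paste0(r, ">", a)
}

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Base-substitution spectrum per genotype
#'
#' Counts SNVs by the six pyrimidine-referenced classes and converts them to
#' per-generation rates using the summed generations of each genotype's
#' lines. Class counts always sum to the SNV count.
#'
#' @param events Typed event tibble (only `SNV` rows are used).
#' @param metadata Line metadata tibble.
#' @return A tibble: `genotype`, `class`, `count`, `rate` (per generation,
#'   pooled over the genotype's lines).
#' @export
substitution_spectrum <- function(events, metadata) {
  snv <- filter(events, .data$kind == "SNV")
  gens <- metadata |>
    group_by(.data$genotype) |>
    summarise(generations = sum(.data$generations), .groups = "drop")
  grid <- tidyr::expand_grid(genotype = unique(metadata$genotype),
                             class = SUBSTITUTION_CLASSES)
  if (nrow(snv)) {
    snv$genotype <- metadata$genotype[match(snv$line_id, metadata$line_id)]
    snv$class <- classify_substitution(snv$ref_base, snv$alt_base)
    counts <- count(snv, .data$genotype, .data$class, name = "count")
  } else {
    counts <- tibble(genotype = character(), class = character(),
                     count = integer())
  }
  grid |>
    left_join(counts, by = c("genotype", "class")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    left_join(gens, by = "genotype") |>
    mutate(rate = .data$count / .data$generations) |>
    select("genotype", "class", "count", "rate")
}

#' Check consistency of event counts across sibling lines
#'
#' Independent MA lines of one genotype should accrue events like Poisson
#' draws with exposure proportional to their generations. The per-genotype
#' dispersion statistic `sum((obs - exp)^2 / exp)` (exp from the pooled rate)
#' is compared to a chi-square distribution with `n_lines - 1` degrees of
#' freedom; a small tail probability flags an outlier line.
#'
#' @param line_summary Output of [summarize_lines()].
#' @param class Event class to check.
#' @return A tibble per genotype: `n_lines`, `total_count`,
#'   `total_generations`, `pooled_rate`, `dispersion`, `df`, `p_value`.
#'   Genotypes with fewer than 2 lines or zero pooled rate get
#'   `dispersion = 0`, `p_value = 1`.
#' @export
line_consistency_check <- function(line_summary, class) {
  sub <- filter(line_summary, .data$class == !!class)
  sub |>
    group_by(.data$genotype) |>
    summarise(
      n_lines = n(),
      total_count = sum(.data$count),
      total_generations = sum(.data$generations),
      pooled_rate = total_count / total_generations,
      dispersion = if (n_lines < 2 || total_count == 0) 0 else {
        expd <- pooled_rate * .data$generations
        sum((.data$count - expd)^2 / expd)
      },
      df = pmax(n_lines - 1L, 1L),
      p_value = if (n_lines < 2 || total_count == 0) 1 else
        pchisq(dispersion, df = n_lines - 1L, lower.tail = FALSE),
      .groups = "drop"
    )
}
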