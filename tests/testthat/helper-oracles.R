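# Independent oracles used across the suite. These reconstruct mutated
# sequences by plain string surgery and never call the package's scanning
# code, so they can arbitrate what the fast implementations must return.

oracle_apply_deletion <- function(seq, s, e) {
  paste0(substr(seq, 1, s), substr(seq, e + 1, nchar(seq)))
}

oracle_apply_td <- function(seq, s, e) {
  paste0(substr(seq, 1, e), substr(seq, s + 1, e), substr(seq, e + 1, nchar(seq)))
}

# number of placements of a same-size event anywhere on the genome that
# reconstruct the identical derived sequence; the ambiguity of the original
# call equals this count, and hom_total must equal it minus one
oracle_count_placements <- function(seq, s, e, apply_fn) {
  size <- e - s
  target <- apply_fn(seq, s, e)
  hits <- 0L
  for (s2 in 0:(nchar(seq) - size)) {
    if (apply_fn(seq, s2, s2 + size) == target) hits <- hits + 1L
  }
  hits
}

oracle_equivalent_placements <- function(seq, s, e, apply_fn) {
  size <- e - s
  target <- apply_fn(seq, s, e)
  keep <- integer(0)
  for (s2 in 0:(nchar(seq) - size)) {
    if (apply_fn(seq, s2, s2 + size) == target) keep <- c(keep, s2)
  }
  keep
}

# textbook Welch two-sample t-test, coded independently of stats::t.test
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_genome <- function(seq, name = "c1") ref_genome(setNames(seq, name))

# sorted event key for set comparisons
event_key <- function(ev) {
  sort(paste(ev$line_id, ev$contig, ev$start, ev$end, ev$kind,
             toupper(ifelse(is.na(ev$inserted_seq), "", ev$inserted_seq)),
             sep = ":"))
}
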