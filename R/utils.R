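# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end);
# conversion to/from the 1-based inclusive GFF3 convention happens only in
# readers and writers.

# Intersect a set of disjoint sorted intervals (tibble start/end) with a
# single range [lo, hi); returns the clipped non-empty pieces.
clip_intervals <- function(ivs, lo, hi) {
  if (nrow(ivs) == 0) {
    return(ivs)
  }
  out <- ivs |>
    mutate(start = pmax(.data$start, lo), end = pmin(.data$end, hi)) |>
    filter(.data$end > .data$start)
  out
}

# Vectorised point-in-intervals membership: positions `pos` against a small
# interval tibble.
points_in_intervals <- function(pos, ivs) {
  if (nrow(ivs) == 0) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(ivs))) {
    hit <- hit | (pos >= ivs$start[i] & pos < ivs$end[i])
  }
  hit
}

stop_tf <- function(..., class = "tfdirect_error") {
  rlang::abort(paste0(...), class = class)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_tf(name, " must be numeric and non-missing")
  }
  if (positive && any(x <= 0)) {
    stop_tf(name, " must be > 0")
  }
  if (non_negative && any(x < 0)) {
    stop_tf(name, " must be >= 0")
  }
  invisible(x)
}

# The seven feature categories, in reporting order.
feature_categories <- function() {
  c(
    "intergenic", "promoter", "five_prime_utr", "exon", "intron",
    "three_prime_utr", "tts"
  )
}
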