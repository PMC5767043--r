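#' Normalize read counts to reads per million (RPM)
#'
#' `rpm = count * 1e6 / library_size`.
#'
#' @param count Non-negative read count(s).
#' @param library_size Total mapped reads of the library (> 0).
#' @return Numeric vector of RPM values.
#' @examples
#' normalize_rpm(10, 1e6) # 10
#' normalize_rpm(37, 2.5e6) # 14.8
#' @export
normalize_rpm <- function(count, library_size) {
  check_number(count, "count", non_negative = TRUE)
  check_number(library_size, "library_size", positive = TRUE)
  count * 1e6 / library_size
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (`chrom start end value`, 0-based
#'   half-open).
#' @return Tibble with columns `chrom`, `start`, `end`, `count`, sorted by
#'   chromosome and start.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = as.numeric(gr$score)
  ) |>
    arrange(.data$chrom, .data$start)
}

# Deterministic bedGraph writer (plain text, integer-formatted counts).
write_bedgraph <- function(windows, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%g",
    windows$chrom, windows$start, windows$end, windows$count
  )
  writeLines(lines, path)
  invisible(path)
}

#' Call enriched loci from treatment vs control window counts
#'
#' Both tracks must share an identical window grid. Per window, treatment
#' and control counts are RPM-normalized and the enrichment ratio
#' `log2((rpm_t + pseudocount) / (rpm_c + pseudocount))` is computed.
#' Windows at or above `min_log2` (default 1.0, i.e. > 2-fold over the NT
#' control) are retained, and runs of adjacent retained windows on the same
#' chromosome are merged into one locus: counts are summed, RPM values
#' renormalized from the summed counts, and the ratio recomputed on the
#' merged RPMs.
#'
#' @param treatment,control Window-count tibbles (`chrom`, `start`, `end`,
#'   `count`) on the same grid, e.g. from [read_bedgraph()].
#' @param treatment_library_size,control_library_size Total mapped reads of
#'   each library.
#' @param min_log2 Minimum log2 enrichment ratio to retain (default 1.0).
#' @param pseudocount Pseudocount in RPM units added to both ratios
#'   (default 0.5); guards against zero-coverage control windows.
#' @return Tibble of class `tf_loci`: `chrom`, `start`, `end`, `n_windows`,
#'   `count_treatment`, `count_control`, `rpm_treatment`, `rpm_control`,
#'   `log2_ratio`.
#' @export
call_enriched_loci <- function(treatment, control,
                               treatment_library_size, control_library_size,
                               min_log2 = 1, pseudocount = 0.5) {
  check_number(pseudocount, "pseudocount", positive = TRUE)
  check_number(min_log2, "min_log2")
  if (nrow(treatment) != nrow(control) ||
    !all(treatment$chrom == control$chrom) ||
    !all(treatment$start == control$start) ||
    !all(treatment$end == control$end)) {
    i <- first_grid_divergence(treatment, control)
    stop_tf(
      "treatment and control window grids differ (first divergence at ",
      "window ", i, ")"
    )
  }
  if (any(treatment$count < 0) || any(control$count < 0)) {
    stop_tf("negative window counts")
  }

  w <- treatment |>
    transmute(
      chrom = .data$chrom, start = .data$start, end = .data$end,
      count_treatment = .data$count, count_control = control$count,
      rpm_treatment = normalize_rpm(.data$count, treatment_library_size),
      rpm_control = normalize_rpm(control$count, control_library_size)
    ) |>
    mutate(
      log2_ratio = log2(
        (.data$rpm_treatment + pseudocount) /
          (.data$rpm_control + pseudocount)
      )
    ) |>
    filter(.data$log2_ratio >= min_log2)

  if (nrow(w) == 0) {
    return(new_tf_loci(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_windows = integer(), count_treatment = numeric(),
      count_control = numeric(), rpm_treatment = numeric(),
      rpm_control = numeric(), log2_ratio = numeric()
    )))
  }

  w <- w |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      new_run = .data$chrom != lag(.data$chrom, default = "") |
        .data$start != lag(.data$end, default = -1L),
      run = cumsum(.data$new_run)
    )
  merged <- w |>
    group_by(.data$run) |>
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_windows = n(),
      count_treatment = sum(.data$count_treatment),
      count_control = sum(.data$count_control),
      .groups = "drop"
    ) |>
    mutate(
      rpm_treatment = normalize_rpm(
        .data$count_treatment, treatment_library_size
      ),
      rpm_control = normalize_rpm(.data$count_control, control_library_size),
      log2_ratio = log2(
        (.data$rpm_treatment + pseudocount) /
          (.data$rpm_control + pseudocount)
      )
    ) |>
    select(-"run") |>
    arrange(.data$chrom, .data$start)
  new_tf_loci(merged)
}

new_tf_loci <- function(x) {
  class(x) <- c("tf_loci", class(x))
  x
}

first_grid_divergence <- function(a, b) {
  n <- min(nrow(a), nrow(b))
  if (n > 0) {
    diff <- which(
      a$chrom[seq_len(n)] != b$chrom[seq_len(n)] |
        a$start[seq_len(n)] != b$start[seq_len(n)] |
        a$end[seq_len(n)] != b$end[seq_len(n)]
    )
    if (length(diff) > 0) {
      return(diff[1])
    }
  }
  n + 1L
}
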