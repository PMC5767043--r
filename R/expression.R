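#' Compute FPKM from a fragment count
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm = count * 1e9 / (gene_length_bp * library_size)`.
#'
#' @param count Non-negative fragment count(s).
#' @param gene_length_bp Transcript length in bp (> 0).
#' @param library_size Total mapped fragments of the sample (> 0).
#' @return Numeric vector of FPKM values.
#' @examples
#' compute_fpkm(100, 1000, 1e6) # 100
#' @export
compute_fpkm <- function(count, gene_length_bp, library_size) {
  check_number(count, "count", non_negative = TRUE)
  check_number(gene_length_bp, "gene_length_bp", positive = TRUE)
  check_number(library_size, "library_size", positive = TRUE)
  count * 1e9 / (gene_length_bp * library_size)
}

#' Build a long FPKM table from wide counts and a sample sheet
#'
#' @param counts Wide tibble: `gene_id`, `length_bp`, then one count column
#'   per sample id.
#' @param samples Sample sheet tibble: `sample_id`, `condition`,
#'   `replicate`, `library_size`.
#' @return Long tibble with one row per gene x sample: `gene_id`,
#'   `length_bp`, `sample_id`, `condition`, `replicate`, `library_size`,
#'   `count`, `fpkm`.
#' @export
fpkm_table <- function(counts, samples) {
  stopifnot(
    all(c("gene_id", "length_bp") %in% names(counts)),
    all(c("sample_id", "condition", "replicate", "library_size") %in%
      names(samples))
  )
  missing_cols <- setdiff(samples$sample_id, names(counts))
  if (length(missing_cols) > 0) {
    stop_tf(
      "count columns missing for sample(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  counts |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(samples$sample_id),
      names_to = "sample_id", values_to = "count"
    ) |>
    inner_join(samples, by = "sample_id") |>
    mutate(fpkm = compute_fpkm(
      .data$count, .data$length_bp, .data$library_size
    ))
}

#' Exclude genes with a zero-FPKM treatment condition
#'
#' A gene is excluded when its condition-mean FPKM is zero (all replicates
#' zero) in at least one of the treatment conditions; with
#' `strict = TRUE` a single zero-FPKM replicate in a treatment condition
#' suffices for exclusion.
#'
#' @param fpkm Long FPKM table from [fpkm_table()].
#' @param conditions Treatment condition names to scan for zeros; defaults
#'   to every condition except `control`.
#' @param control Control condition name (default `"NT"`), excluded from
#'   the scan.
#' @param strict If `TRUE`, exclude on any single zero-FPKM replicate.
#' @return Character vector of retained gene ids (sorted).
#' @export
filter_zero_fpkm <- function(fpkm, conditions = NULL, control = "NT",
                             strict = FALSE) {
  conditions <- conditions %||%
    sort(setdiff(unique(fpkm$condition), control))
  missing <- setdiff(conditions, unique(fpkm$condition))
  if (length(missing) > 0) {
    stop_tf(
      "condition(s) absent from FPKM table: ",
      paste(missing, collapse = ", ")
    )
  }
  status <- fpkm |>
    filter(.data$condition %in% conditions) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(
      zero = if (strict) any(.data$fpkm == 0) else mean(.data$fpkm) == 0,
      .groups = "drop"
    ) |>
    group_by(.data$gene_id) |>
    summarise(excluded = any(.data$zero), .groups = "drop")
  sort(status$gene_id[!status$excluded])
}

#' Call differentially expressed genes for one line against the control
#'
#' Fold change is `(mean_fpkm_treatment + c) / (mean_fpkm_control + c)`
#' with pseudocount `c` (default 1 FPKM); the p-value comes from a
#' two-sided Welch t-test on `log2(FPKM + 1)` across replicates. A gene is
#' `up` when `fold_change >= min_fc` and `p < alpha`, `down` when
#' `fold_change <= 1/min_fc` and `p < alpha`, else `none`. When both
#' replicate vectors are constant the Welch statistic is undefined; the
#' p-value is reported `NA` and the direction is `none`.
#'
#' @param fpkm Long FPKM table from [fpkm_table()].
#' @param condition Treatment condition to contrast against `control`.
#' @param control Control condition name (default `"NT"`).
#' @param genes Optional character vector restricting the gene universe
#'   (e.g. the output of [filter_zero_fpkm()]).
#' @param min_fc Fold-change threshold (> 1; default 1.5).
#' @param alpha P-value threshold (default 0.05, on the raw p-value).
#' @param fc_pseudocount Pseudocount in FPKM units for the fold change
#'   (default 1).
#' @return Tibble of class `tf_deg`, sorted by gene id: `gene_id`,
#'   `condition`, `mean_fpkm_treatment`, `mean_fpkm_control`,
#'   `fold_change`, `log2_fold_change`, `p_value`, `direction`.
#' @export
call_degs <- function(fpkm, condition, control = "NT", genes = NULL,
                      min_fc = 1.5, alpha = 0.05, fc_pseudocount = 1) {
  if (min_fc <= 1) {
    stop_tf("min_fc must be > 1")
  }
  check_number(alpha, "alpha", positive = TRUE)
  cond <- condition
  dat <- fpkm |> filter(.data$condition %in% c(cond, control))
  if (!is.null(genes)) {
    dat <- dat |> filter(.data$gene_id %in% genes)
  }
  n_rep <- dat |>
    distinct(.data$condition, .data$sample_id) |>
    count(.data$condition)
  for (grp in c(cond, control)) {
    k <- n_rep$n[n_rep$condition == grp]
    if (length(k) == 0 || k < 2) {
      stop_tf("condition '", grp, "' has fewer than 2 replicates")
    }
  }

  per_gene <- dat |>
    group_by(.data$gene_id) |>
    summarise(
      treat = list(.data$fpkm[.data$condition == cond]),
      ctrl = list(.data$fpkm[.data$condition == control]),
      .groups = "drop"
    )
  res <- per_gene |>
    mutate(
      condition = cond,
      mean_fpkm_treatment = purrr::map_dbl(.data$treat, mean),
      mean_fpkm_control = purrr::map_dbl(.data$ctrl, mean),
      fold_change = (.data$mean_fpkm_treatment + fc_pseudocount) /
        (.data$mean_fpkm_control + fc_pseudocount),
      log2_fold_change = log2(.data$fold_change),
      p_value = purrr::map2_dbl(.data$treat, .data$ctrl, welch_log2_p)
    ) |>
    mutate(
      direction = case_when(
        !is.na(.data$p_value) & .data$p_value < alpha &
          .data$fold_change >= min_fc ~ "up",
        !is.na(.data$p_value) & .data$p_value < alpha &
          .data$fold_change <= 1 / min_fc ~ "down",
        TRUE ~ "none"
      )
    ) |>
    select(
      "gene_id", "condition", "mean_fpkm_treatment", "mean_fpkm_control",
      "fold_change", "log2_fold_change", "p_value", "direction"
    ) |>
    arrange(.data$gene_id)
  attr(res, "min_fc") <- min_fc
  attr(res, "alpha") <- alpha
  class(res) <- c("tf_deg", class(res))
  res
}

# Two-sided Welch t-test on log2(FPKM + 1); NA when degenerate.
welch_log2_p <- function(x, y) {
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  if (stats::sd(lx) == 0 && stats::sd(ly) == 0) {
    return(NA_real_)
  }
  tryCatch(
    stats::t.test(lx, ly, var.equal = FALSE)$p.value,
    error = function(e) NA_real_
  )
}

#' Call DEGs for several lines at once
#'
#' Maps [call_degs()] over the treatment conditions and row-binds the
#' results.
#'
#' @inheritParams call_degs
#' @param conditions Treatment conditions; defaults to every condition
#'   except `control`.
#' @return A `tf_deg` tibble covering all requested conditions.
#' @export
call_degs_all <- function(fpkm, conditions = NULL, control = "NT",
                          genes = NULL, min_fc = 1.5, alpha = 0.05,
                          fc_pseudocount = 1) {
  conditions <- conditions %||%
    sort(setdiff(unique(fpkm$condition), control))
  res <- purrr::map(
    conditions,
    function(co) {
      tidy(call_degs(
        fpkm, co,
        control = control, genes = genes, min_fc = min_fc,
        alpha = alpha, fc_pseudocount = fc_pseudocount
      ))
    }
  ) |>
    purrr::list_rbind()
  attr(res, "min_fc") <- min_fc
  attr(res, "alpha") <- alpha
  class(res) <- c("tf_deg", class(res))
  res
}

#' @export
tidy.tf_deg <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.tf_deg <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$condition) |>
    summarise(
      n_genes = n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
}
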