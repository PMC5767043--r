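#' Integrate annotated enriched loci with per-line DEG calls
#'
#' Applies the five integration filters in order: (1) drop intergenic loci;
#' (2) keep loci with `log2_ratio >= min_log2`; (3) keep loci whose
#' assigned gene is up-regulated in the same line; (4) restrict to promoter
#' and 5'UTR loci; (5) collapse identical `(line, interval)` duplicates and
#' group the surviving loci by gene. The result is the gene-level direct
#' target set: genes both up-regulated and promoter/5'UTR-bound in at least
#' one line, each keeping its supporting loci as evidence.
#'
#' @param loci Annotated locus tibble with columns `line`, `chrom`,
#'   `start`, `end`, `log2_ratio`, `gene_id`, `category`,
#'   `distance_to_tss` (e.g. [call_enriched_loci()] output passed through
#'   [classify_loci()], with a `line` column added).
#' @param degs A `tf_deg` tibble covering the same lines (`condition`
#'   column matches `line`).
#' @param min_log2 Enrichment threshold re-applied at integration
#'   (default 1.0).
#' @return An object of class `tf_targets`: a list with
#'   \describe{
#'     \item{direct_targets}{tibble: `gene_id`, `n_lines`, `lines`
#'       (comma-separated, sorted), `n_loci`, `best_log2_ratio`,
#'       `distance_to_tss` (the signed distance of the closest supporting
#'       locus center).}
#'     \item{supporting_loci}{tibble of the loci behind each (gene, line).}
#'     \item{locus_table}{per line x category locus counts at the
#'       `enriched` stage (after filters 1-2) and the `up_regulated` stage
#'       (after filter 3).}
#'   }
#' @export
integrate_targets <- function(loci, degs, min_log2 = 1) {
  need <- c(
    "line", "chrom", "start", "end", "log2_ratio", "gene_id", "category",
    "distance_to_tss"
  )
  stopifnot(all(need %in% names(loci)))
  deg <- as_tibble(unclass(degs))
  lines_loci <- sort(unique(loci$line))
  lines_deg <- sort(unique(deg$condition))
  # lines without any enriched locus are legitimate; unknown lines are not
  if (!all(lines_loci %in% lines_deg)) {
    stop_tf(
      "line names differ between loci (",
      paste(lines_loci, collapse = ","), ") and DEG records (",
      paste(lines_deg, collapse = ","), ")"
    )
  }

  # filters 1-2: drop intergenic, enforce enrichment threshold
  step2 <- loci |>
    filter(.data$category != "intergenic", .data$log2_ratio >= min_log2)

  universe <- unique(deg$gene_id)
  orphan <- setdiff(unique(step2$gene_id), universe)
  if (length(orphan) > 0) {
    stop_tf(
      "locus gene(s) absent from the DEG universe: ",
      paste(head(orphan, 5), collapse = ", ")
    )
  }

  # filter 3: assigned gene up-regulated in the same line
  up <- deg |>
    filter(.data$direction == "up") |>
    distinct(line = .data$condition, .data$gene_id)
  step3 <- step2 |> semi_join(up, by = c("line", "gene_id"))

  locus_table <- bind_rows(
    step2 |> count(.data$line, .data$category) |> mutate(stage = "enriched"),
    step3 |>
      count(.data$line, .data$category) |>
      mutate(stage = "up_regulated")
  ) |>
    mutate(category = factor(.data$category, feature_categories())) |>
    select("stage", "line", "category", n = "n") |>
    arrange(.data$stage, .data$line, .data$category)

  # filters 4-5: promoter/5'UTR only, deduplicate, group by gene
  supporting <- step3 |>
    filter(.data$category %in% c("promoter", "five_prime_utr")) |>
    distinct(
      .data$line, .data$chrom, .data$start, .data$end,
      .keep_all = TRUE
    ) |>
    arrange(.data$gene_id, .data$line, .data$chrom, .data$start)

  if (nrow(supporting) == 0) {
    direct <- tibble(
      gene_id = character(), n_lines = integer(), lines = character(),
      n_loci = integer(), best_log2_ratio = numeric(),
      distance_to_tss = integer()
    )
    return(structure(
      list(
        direct_targets = direct,
        supporting_loci = supporting,
        locus_table = locus_table
      ),
      class = "tf_targets"
    ))
  }

  direct <- supporting |>
    group_by(.data$gene_id) |>
    summarise(
      n_lines = n_distinct(.data$line),
      lines = paste(sort(unique(.data$line)), collapse = ","),
      n_loci = n(),
      best_log2_ratio = max(.data$log2_ratio),
      distance_to_tss = .data$distance_to_tss[
        which.min(abs(.data$distance_to_tss))
      ],
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)

  structure(
    list(
      direct_targets = direct,
      supporting_loci = supporting,
      locus_table = locus_table
    ),
    class = "tf_targets"
  )
}

#' @export
print.tf_targets <- function(x, ...) {
  cat(
    "Direct-target set:", nrow(x$direct_targets), "genes,",
    nrow(x$supporting_loci), "supporting promoter/5'UTR loci across",
    length(unique(x$supporting_loci$line)), "line(s)\n"
  )
  invisible(x)
}

#' @export
tidy.tf_targets <- function(x, ...) {
  x$direct_targets
}

#' @export
glance.tf_targets <- function(x, ...) {
  tibble(
    n_genes = nrow(x$direct_targets),
    n_loci = nrow(x$supporting_loci),
    n_lines = length(unique(x$supporting_loci$line))
  )
}

#' Partition direct targets across the non-empty line subsets
#'
#' Counts each direct-target gene in exactly one cell of the Venn diagram
#' over the lines it is called in (15 non-empty subsets for four lines),
#' and reports per-line gene and supporting-locus totals.
#'
#' @param targets A `tf_targets` object from [integrate_targets()].
#' @param lines Optional full vector of line names (so lines with zero
#'   targets still appear); defaults to the lines present.
#' @return Object of class `tf_venn`: list with `cells` (tibble `subset`,
#'   `n_lines`, `n_genes`; every non-empty subset of `lines`, zero-filled)
#'   and `per_line` (tibble `line`, `n_genes`, `n_loci`).
#' @export
venn_partition <- function(targets, lines = NULL) {
  stopifnot(inherits(targets, "tf_targets"))
  direct <- targets$direct_targets
  lines <- sort(lines %||% unique(targets$supporting_loci$line))
  if (nrow(direct) > 0 && any(direct$n_lines == 0)) {
    stop_tf("direct target with empty line set")
  }

  subsets <- unlist(
    lapply(
      seq_along(lines),
      function(k) combn(lines, k, paste, collapse = ",", simplify = FALSE)
    )
  )
  observed <- direct |> count(subset = .data$lines, name = "n_genes")
  cells <- tibble(subset = subsets) |>
    left_join(observed, by = "subset") |>
    mutate(
      n_genes = tidyr::replace_na(.data$n_genes, 0L),
      n_lines = purrr::map_int(
        strsplit(.data$subset, ",", fixed = TRUE), length
      )
    ) |>
    select("subset", "n_lines", "n_genes")

  per_line <- tibble(line = lines) |>
    mutate(
      n_genes = purrr::map_int(
        .data$line,
        function(l) {
          sum(purrr::map_lgl(
            strsplit(direct$lines, ",", fixed = TRUE),
            function(s) l %in% s
          ))
        }
      ),
      n_loci = purrr::map_int(
        .data$line,
        function(l) sum(targets$supporting_loci$line == l)
      )
    )

  structure(list(cells = cells, per_line = per_line), class = "tf_venn")
}

#' @export
print.tf_venn <- function(x, ...) {
  cat(
    "Venn partition over", nrow(x$per_line), "lines:",
    sum(x$cells$n_genes), "direct-target genes in",
    sum(x$cells$n_genes > 0), "non-empty cells\n"
  )
  invisible(x)
}

#' @export
tidy.tf_venn <- function(x, ...) {
  x$cells
}

#' Per-line direct-target fraction of up-regulated genes
#'
#' `100 * |genes up in line and direct target in line| /
#' |genes up in line|`, reported to one decimal. Lines with zero
#' up-regulated genes get a missing fraction.
#'
#' @param targets A `tf_targets` object.
#' @param degs The `tf_deg` tibble used for integration.
#' @return Tibble: `line`, `n_up`, `n_direct`, `fraction_pct`.
#' @export
direct_target_fraction <- function(targets, degs) {
  stopifnot(inherits(targets, "tf_targets"))
  deg <- as_tibble(unclass(degs))
  target_lines <- targets$supporting_loci |>
    distinct(.data$line, .data$gene_id)
  deg |>
    filter(.data$direction == "up") |>
    group_by(line = .data$condition) |>
    summarise(
      n_up = n_distinct(.data$gene_id),
      n_direct = n_distinct(intersect(
        .data$gene_id,
        target_lines$gene_id[target_lines$line == .data$line[1]]
      )),
      .groups = "drop"
    ) |>
    right_join(
      tibble(line = sort(unique(deg$condition))),
      by = "line"
    ) |>
    mutate(
      n_up = tidyr::replace_na(.data$n_up, 0L),
      n_direct = tidyr::replace_na(.data$n_direct, 0L),
      fraction_pct = ifelse(
        .data$n_up > 0, round(100 * .data$n_direct / .data$n_up, 1),
        NA_real_
      )
    ) |>
    arrange(.data$line)
}
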