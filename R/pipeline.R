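#' Run the full direct-target pipeline
#'
#' Executes annotate -> enrich -> DEG -> integrate -> GO enrichment on a
#' complete input set and assembles a machine-readable run report. The
#' input is either a directory following the [simulate_experiment()] file
#' layout or a `tf_sim` object itself (in-memory run). The pipeline
#' contains no randomness: identical inputs and thresholds reproduce the
#' report byte for byte.
#'
#' @param input A directory path (with `genes.gff3`, `counts.tsv`,
#'   `samples.tsv`, `chip_samples.tsv` + bedGraphs, and optionally
#'   `go_annotation.tsv`/`go_terms.tsv`) or a `tf_sim` object.
#' @param output_dir Optional directory for `report.json`,
#'   `direct_targets.tsv`, `degs.tsv`, `loci.tsv`.
#' @param control Control condition/track name (default `"NT"`).
#' @param min_fc,alpha DEG thresholds (defaults 1.5, 0.05).
#' @param min_log2 ChIP enrichment threshold (default 1).
#' @param promoter_bp,tts_bp Feature-classification windows
#'   (defaults 2000, 1000).
#' @param rpm_pseudocount,fc_pseudocount Pseudocounts for the enrichment
#'   ratio (RPM units, default 0.5) and the expression fold change (FPKM
#'   units, default 1).
#' @param go_alpha FDR threshold for the GO report (default 0.05).
#' @param quiet Suppress stage log messages (default `FALSE`).
#' @return A list of class `tf_report`: `config` (thresholds used),
#'   `n_genes`, `n_retained_genes`, `deg_counts`, `locus_table`,
#'   `direct_targets`, `n_direct_target_genes`, `venn`, `fractions`,
#'   `go` (or NULL), plus the underlying `targets` and `degs` objects.
#' @export
run_pipeline <- function(input, output_dir = NULL, control = "NT",
                         min_fc = 1.5, alpha = 0.05, min_log2 = 1,
                         promoter_bp = 2000, tts_bp = 1000,
                         rpm_pseudocount = 0.5, fc_pseudocount = 1,
                         go_alpha = 0.05, quiet = FALSE) {
  log_stage <- function(...) {
    if (!quiet) message("[tfdirect] ", ...)
  }
  t0 <- Sys.time()
  dat <- if (inherits(input, "tf_sim")) {
    input
  } else {
    read_pipeline_inputs(input, control)
  }
  config <- list(
    control = control, min_fc = min_fc, alpha = alpha,
    min_log2 = min_log2, promoter_bp = promoter_bp, tts_bp = tts_bp,
    rpm_pseudocount = rpm_pseudocount, fc_pseudocount = fc_pseudocount,
    go_alpha = go_alpha
  )
  lines <- setdiff(names(dat$chip), control)

  log_stage("enrichment: ", length(lines), " line(s) vs ", control)
  nt <- dat$chip[[control]]
  loci <- purrr::map(lines, function(ln) {
    tr <- dat$chip[[ln]]
    call_enriched_loci(
      tr$windows, nt$windows, tr$library_size, nt$library_size,
      min_log2 = min_log2, pseudocount = rpm_pseudocount
    ) |>
      mutate(line = ln)
  }) |>
    purrr::list_rbind()

  log_stage("annotation: classifying ", nrow(loci), " enriched loci")
  loci <- classify_loci(
    dat$annotation, loci,
    promoter_bp = promoter_bp, tts_bp = tts_bp
  )

  log_stage("expression: FPKM + zero filter + DEG calling")
  fpkm <- fpkm_table(dat$counts, dat$samples)
  retained <- filter_zero_fpkm(fpkm, conditions = lines, control = control)
  degs <- call_degs_all(
    fpkm,
    conditions = lines, control = control, genes = retained,
    min_fc = min_fc, alpha = alpha, fc_pseudocount = fc_pseudocount
  )

  log_stage("integration: direct-target calling")
  # enriched loci on excluded genes cannot be scored against the DEG
  # universe; they are dropped with the intergenic filter's logic upfront
  loci_u <- loci |>
    filter(.data$category == "intergenic" |
      .data$gene_id %in% retained)
  targets <- integrate_targets(loci_u, degs, min_log2 = min_log2)
  venn <- venn_partition(targets, lines = lines)
  fractions <- direct_target_fraction(targets, degs)

  go_res <- NULL
  if (!is.null(dat$go)) {
    log_stage("go: singular enrichment of direct targets")
    study <- intersect(targets$direct_targets$gene_id, retained)
    go_res <- sea(
      study, retained, dat$go$gene2go,
      term_meta = dat$go$term_meta, alpha = go_alpha
    )
  }

  report <- list(
    config = config,
    lines = lines,
    n_genes = nrow(dat$annotation),
    n_retained_genes = length(retained),
    n_excluded_genes = nrow(dat$annotation) - length(retained),
    deg_counts = glance(degs),
    locus_table = targets$locus_table,
    n_direct_target_genes = nrow(targets$direct_targets),
    n_direct_target_loci = nrow(targets$supporting_loci),
    venn = venn,
    fractions = fractions,
    go = go_res,
    targets = targets,
    degs = degs
  )
  class(report) <- "tf_report"
  if (!is.null(output_dir)) {
    write_report(report, output_dir)
  }
  log_stage(
    "done in ", sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
    " s"
  )
  report
}

read_pipeline_inputs <- function(dir, control) {
  p <- function(f) file.path(dir, f)
  for (f in c("genes.gff3", "counts.tsv", "samples.tsv", "chip_samples.tsv")) {
    if (!file.exists(p(f))) stop_tf("missing pipeline input: ", p(f))
  }
  annotation <- read_gff_annotation(p("genes.gff3"))
  counts <- readr::read_tsv(p("counts.tsv"), show_col_types = FALSE)
  samples <- readr::read_tsv(p("samples.tsv"), show_col_types = FALSE)
  chip_sheet <- readr::read_tsv(p("chip_samples.tsv"), show_col_types = FALSE)
  chip <- purrr::pmap(chip_sheet, function(sample_id, role, library_size,
                                           path) {
    list(
      sample_id = sample_id,
      library_size = library_size,
      windows = read_bedgraph(p(path))
    )
  })
  names(chip) <- chip_sheet$sample_id
  if (!control %in% names(chip)) {
    stop_tf("control track '", control, "' absent from chip_samples.tsv")
  }
  go <- NULL
  if (file.exists(p("go_annotation.tsv"))) {
    go <- list(
      gene2go = read_gene2go(p("go_annotation.tsv")),
      term_meta = if (file.exists(p("go_terms.tsv"))) {
        readr::read_tsv(p("go_terms.tsv"), show_col_types = FALSE)
      } else {
        NULL
      }
    )
  }
  structure(
    list(
      annotation = annotation, counts = counts, samples = samples,
      chip = chip, go = go
    ),
    class = "tf_sim"
  )
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  readr::write_tsv(report$targets$direct_targets, p("direct_targets.tsv"))
  readr::write_tsv(tidy(report$degs), p("degs.tsv"))
  readr::write_tsv(report$targets$supporting_loci, p("loci.tsv"))
  json <- list(
    config = report$config,
    lines = report$lines,
    n_genes = report$n_genes,
    n_retained_genes = report$n_retained_genes,
    n_excluded_genes = report$n_excluded_genes,
    deg_counts = report$deg_counts,
    locus_table = report$locus_table |>
      mutate(category = as.character(.data$category)),
    n_direct_target_genes = report$n_direct_target_genes,
    n_direct_target_loci = report$n_direct_target_loci,
    venn_cells = report$venn$cells,
    venn_per_line = report$venn$per_line,
    fractions = report$fractions,
    go_significant = if (!is.null(report$go)) {
      tidy(report$go) |> filter(.data$significant)
    } else {
      NULL
    }
  )
  jsonlite::write_json(
    json, p("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(output_dir)
}

#' @export
print.tf_report <- function(x, ...) {
  cat("tfdirect run report\n")
  cat("  genes:", x$n_genes, "(", x$n_retained_genes, "retained )\n")
  cat("  direct targets:", x$n_direct_target_genes, "genes /",
      x$n_direct_target_loci, "loci\n")
  cat("  per-line fractions (% of up-regulated):\n")
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf(
      "    %s: %s%% (%d / %d)\n", f$line[i],
      format(f$fraction_pct[i]), f$n_direct[i], f$n_up[i]
    ))
  }
  invisible(x)
}
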