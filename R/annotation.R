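#' Read a GFF3 gene annotation into strand-aware gene models
#'
#' Parses a GFF3 file (1-based inclusive coordinates) and builds one gene
#' model per gene, taking a single representative transcript: the longest
#' mRNA, with ties broken by the lexicographically smallest transcript id.
#' Coordinates are converted to the package-internal 0-based half-open
#' convention. The transcription start site (TSS) and transcript end (TES)
#' are strand-aware: on the + strand the TSS is the span start and the TES
#' the last base; on the - strand the TSS is the last base and the TES the
#' span start. 5' and 3' UTRs are derived from the CDS (the exonic sequence
#' 5' of the first CDS base and 3' of the last, respectively) and are empty
#' when no CDS is annotated.
#'
#' @param path Path to a GFF3 file with `gene`, `mRNA` and `exon` records
#'   (optionally `CDS`).
#' @return A tibble of class `tf_annotation` with one row per gene:
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `tes`, and list-columns `exons`, `cds`, `utr5`, `utr3` (tibbles of
#'   `start`/`end` intervals, 0-based half-open, sorted).
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(
#'   "##gff-version 3",
#'   "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
#'   "chr1\tsrc\texon\t1001\t1400\t.\t+\t.\tParent=g1.t1",
#'   "chr1\tsrc\texon\t1601\t2000\t.\t+\t.\tParent=g1.t1"
#' ), gff)
#' ann <- read_gff_annotation(gff)
#' ann$tss  # 1000 in internal 0-based coordinates
#' @export
read_gff_annotation <- function(path) {
  validate_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0 || !any(df$type == "gene")) {
    return(empty_annotation())
  }
  df <- df |>
    mutate(
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      # internal 0-based half-open
      start0 = .data$start - 1L,
      end0 = as.integer(.data$end),
      ID = if ("ID" %in% names(df)) as.character(.data$ID) else NA_character_,
      parent = purrr::map_chr(
        if ("Parent" %in% names(df)) .data$Parent else vector("list", nrow(df)),
        function(p) if (length(p) == 0) NA_character_ else as.character(p[[1]])
      )
    )

  genes <- df |> filter(.data$type == "gene")
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$ID[!genes$strand %in% c("+", "-")][1]
    stop_tf("unknown strand for gene '", bad, "': must be '+' or '-'")
  }
  mrna <- df |> filter(.data$type == "mRNA")
  parts <- df |> filter(.data$type %in% c("exon", "CDS"))

  # representative transcript per gene: longest mRNA, tie -> smallest id
  rep_tx <- mrna |>
    mutate(len = .data$end0 - .data$start0) |>
    arrange(.data$parent, desc(.data$len), .data$ID) |>
    distinct(.data$parent, .keep_all = TRUE) |>
    select(gene_id = "parent", transcript_id = "ID")

  models <- genes |>
    select(
      gene_id = "ID", chrom = "chrom", strand = "strand",
      start = "start0", end = "end0"
    ) |>
    left_join(rep_tx, by = "gene_id")

  part_tbl <- function(tx, what) {
    p <- parts |> filter(.data$parent == tx, .data$type == what)
    p |>
      transmute(start = .data$start0, end = .data$end0) |>
      arrange(.data$start)
  }

  models <- models |>
    mutate(
      exons = purrr::map(.data$transcript_id, part_tbl, what = "exon"),
      cds = purrr::map(.data$transcript_id, part_tbl, what = "CDS")
    )

  # exons must be disjoint and lie within the gene span
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (nrow(ex) == 0) {
      stop_tf("gene '", models$gene_id[i], "' has a transcript with no exons")
    }
    if (any(ex$start < models$start[i]) || any(ex$end > models$end[i])) {
      stop_tf(
        "exon outside gene span for gene '", models$gene_id[i], "'"
      )
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop_tf("overlapping exons for gene '", models$gene_id[i], "'")
    }
  }

  models <- models |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
    )
  models <- derive_utrs(models)
  models <- models |> arrange(.data$chrom, .data$start)
  new_tf_annotation(models)
}

new_tf_annotation <- function(x) {
  class(x) <- c("tf_annotation", class(x))
  x
}

empty_annotation <- function() {
  new_tf_annotation(tibble(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    tss = integer(), tes = integer(),
    exons = list(), cds = list(), utr5 = list(), utr3 = list()
  ))
}

# UTRs derived from CDS extent, strand-aware; empty tibbles when CDS absent.
derive_utrs <- function(models) {
  iv0 <- tibble(start = integer(), end = integer())
  models |>
    mutate(
      utr5 = purrr::pmap(
        list(.data$exons, .data$cds, .data$strand),
        function(ex, cd, st) {
          if (nrow(cd) == 0) return(iv0)
          if (st == "+") {
            clip_intervals(ex, -Inf, min(cd$start))
          } else {
            clip_intervals(ex, max(cd$end), Inf)
          }
        }
      ),
      utr3 = purrr::pmap(
        list(.data$exons, .data$cds, .data$strand),
        function(ex, cd, st) {
          if (nrow(cd) == 0) return(iv0)
          if (st == "+") {
            clip_intervals(ex, max(cd$end), Inf)
          } else {
            clip_intervals(ex, -Inf, min(cd$start))
          }
        }
      )
    )
}

# Pre-scan raw GFF3 lines for defects rtracklayer does not report per line.
validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop_tf("malformed GFF3 record at line ", i, ": fewer than 8 fields")
    }
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s) {
      stop_tf(
        "malformed coordinates at line ", i, " (start=", f[4],
        ", end=", f[5], ")"
      )
    }
    if (f[3] %in% c("gene", "mRNA") && !f[7] %in% c("+", "-")) {
      stop_tf("unknown strand '", f[7], "' at line ", i)
    }
  }
  invisible(TRUE)
}

#' Classify genomic positions into the seven feature categories
#'
#' Assigns each query position to the gene with the nearest TSS on the same
#' chromosome and classifies it into exactly one of seven categories:
#' `intergenic`, `promoter`, `five_prime_utr`, `exon`, `intron`,
#' `three_prime_utr`, `tts`. Resolution order within the assigned gene:
#' positions inside the gene span are 5'UTR, 3'UTR, exon or intron;
#' otherwise a position within `promoter_bp` upstream of the TSS
#' (strand-aware) is `promoter`; within `tts_bp` downstream of the TES is
#' `tts`; everything else (including the unnamed 2-10 kb upstream zone) is
#' `intergenic`. The reported distance to TSS is signed in the gene's
#' orientation (negative = upstream), so `promoter` always satisfies
#' `-promoter_bp <= distance_to_tss < 0`.
#'
#' Nearest-TSS ties are resolved deterministically: prefer the gene whose
#' span contains the position; if neither or both qualify, the smallest
#' `gene_id`.
#'
#' @param annotation A `tf_annotation` from [read_gff_annotation()].
#' @param chrom Character vector of chromosome names (recycled against
#'   `pos`).
#' @param pos Integer vector of 0-based positions.
#' @param promoter_bp Promoter window upstream of the TSS (default 2000).
#' @param tts_bp TTS window downstream of the TES (default 1000).
#' @return A tibble with one row per query: `chrom`, `pos`, `gene_id`
#'   (NA on a gene-less chromosome), `category`, `distance_to_tss`.
#' @export
classify_positions <- function(annotation, chrom, pos,
                               promoter_bp = 2000, tts_bp = 1000) {
  stopifnot(inherits(annotation, "tf_annotation"))
  check_number(promoter_bp, "promoter_bp", positive = TRUE)
  check_number(tts_bp, "tts_bp", positive = TRUE)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)

  out <- tibble(
    chrom = chrom, pos = pos,
    gene_id = NA_character_,
    category = NA_character_,
    distance_to_tss = NA_integer_
  )
  known <- unique(annotation$chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    genes <- annotation |> filter(.data$chrom == ch)
    if (nrow(genes) == 0) {
      if (!(ch %in% known) && nrow(annotation) > 0) {
        stop_tf("unknown chromosome '", ch, "'")
      }
      out$category[idx] <- "intergenic"
      next
    }
    res <- classify_on_chrom(genes, pos[idx], promoter_bp, tts_bp)
    out$gene_id[idx] <- res$gene_id
    out$category[idx] <- res$category
    out$distance_to_tss[idx] <- res$distance_to_tss
  }
  out
}

classify_on_chrom <- function(genes, pos, promoter_bp, tts_bp) {
  m <- nrow(genes)
  # nearest-TSS assignment by absolute genomic distance
  dmat <- abs(outer(pos, genes$tss, "-"))
  assigned <- max.col(-dmat, ties.method = "first")
  dmin <- dmat[cbind(seq_along(pos), assigned)]
  # deterministic tie-break: containing span, then smallest gene_id
  tie_rows <- which(rowSums(dmat == dmin) > 1)
  for (q in tie_rows) {
    ties <- which(dmat[q, ] == dmin[q])
    {
      contains <- ties[genes$start[ties] <= pos[q] & pos[q] < genes$end[ties]]
      cand <- if (length(contains) == 1) contains else ties
      assigned[q] <- cand[order(genes$gene_id[cand])][1]
    }
  }

  category <- character(length(pos))
  dist <- integer(length(pos))
  for (gi in unique(assigned)) {
    qs <- which(assigned == gi)
    g <- genes[gi, ]
    p <- pos[qs]
    d <- if (g$strand == "+") p - g$tss else g$tss - p
    doff <- if (g$strand == "+") p - g$tes else g$tes - p
    in_span <- p >= g$start & p < g$end
    cat_g <- rep("intergenic", length(p))
    cat_g[!in_span & d >= -promoter_bp & d < 0] <- "promoter"
    cat_g[!in_span & cat_g == "intergenic" &
      doff >= 1 & doff <= tts_bp] <- "tts"
    if (any(in_span)) {
      pin <- p[in_span]
      sub <- rep("intron", length(pin))
      sub[points_in_intervals(pin, g$exons[[1]])] <- "exon"
      sub[points_in_intervals(pin, g$utr3[[1]])] <- "three_prime_utr"
      sub[points_in_intervals(pin, g$utr5[[1]])] <- "five_prime_utr"
      cat_g[in_span] <- sub
    }
    category[qs] <- cat_g
    dist[qs] <- as.integer(d)
  }
  tibble(
    gene_id = genes$gene_id[assigned],
    category = category,
    distance_to_tss = dist
  )
}

#' Classify genomic intervals by their center position
#'
#' Reduces each locus to its center, `floor((start + end) / 2)`, and applies
#' [classify_positions()]: the category and nearest-TSS gene of a binding
#' locus are those of its center, and the distance to TSS is measured from
#' the center.
#'
#' @param annotation A `tf_annotation`.
#' @param loci Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open); extra columns are preserved.
#' @inheritParams classify_positions
#' @return `loci` with `gene_id`, `category` and `distance_to_tss` appended.
#' @export
classify_loci <- function(annotation, loci, promoter_bp = 2000,
                          tts_bp = 1000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)))
  if (any(loci$end <= loci$start)) {
    stop_tf("empty locus interval (end <= start)")
  }
  centers <- floor((loci$start + loci$end) / 2)
  res <- classify_positions(
    annotation, loci$chrom, centers,
    promoter_bp = promoter_bp, tts_bp = tts_bp
  )
  loci |>
    mutate(
      gene_id = res$gene_id,
      category = res$category,
      distance_to_tss = res$distance_to_tss
    )
}
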