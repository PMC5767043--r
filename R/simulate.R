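#' Configuration for the synthetic regulatory-genomics experiment
#'
#' The generator emulates a four-line TF-overexpression study: four
#' transgenic lines plus a non-transgenic (NT) control, two RNA-Seq
#' replicates per condition, one pooled ChIP track per line plus the NT
#' background, and planted ground truth (which genes are up/down-regulated
#' in which line, and where each line binds).
#'
#' Genes are laid out on a regular grid of `slot_bp` slots, each gene a
#' fixed two-exon model (1 kb exons flanking a 1 kb intron, 500 bp UTRs)
#' placed centrally in its slot on a random strand. The fixed geometry
#' guarantees every feature category contains at least one whole,
#' grid-aligned coverage window, so planted binding intervals can be
#' snapped to a window whose center provably classifies to the planted
#' category.
#'
#' @param n_chromosomes Number of chromosomes (default 4).
#' @param n_genes Total genes (default 1000), distributed evenly.
#' @param slot_bp Per-gene slot width (default 12000).
#' @param chrom_length_bp Chromosome length (default `slot_bp` times the
#'   genes per chromosome).
#' @param promoter_bp,tts_bp Promoter and TTS window widths used for
#'   planting and self-consistency checks (defaults 2000 / 1000).
#' @param window_bp ChIP coverage window width (default 200, matching
#'   100-200 bp chromatin fragments).
#' @param lines Treatment line names (default `TF1`..`TF4`).
#' @param control Control name (default `"NT"`).
#' @param replicates RNA-Seq replicates per condition (default 2).
#' @param expr_depth Mean RNA library size in fragments (default 5e6).
#' @param expr_sdlog Log-normal sd of baseline gene expression (default 1).
#' @param expr_dispersion Negative-binomial dispersion (default 0.002,
#'   i.e. `size = 1/dispersion`; near-technical replicate variability, low
#'   enough that a planted 4-fold effect is detectable by a two-replicate
#'   Welch test).
#' @param effect_fc Planted expression fold change (default 4).
#' @param binding_enrichment Planted ChIP coverage multiplier (default 8).
#' @param chip_background Mean background ChIP reads per window
#'   (default 100).
#' @param fraction_up,fraction_down Per-line fractions of genes planted
#'   up-/down-regulated (defaults 0.1 / 0.1; disjoint sets).
#' @param fraction_bound Per-line fraction of genes with one planted
#'   binding locus (default 0.5).
#' @param category_mix Named proportions of planted binding across the
#'   seven feature categories (must sum to 1).
#' @return A validated list of class `tf_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       n_genes = 1000,
                       slot_bp = 12000,
                       chrom_length_bp = NULL,
                       promoter_bp = 2000,
                       tts_bp = 1000,
                       window_bp = 200,
                       lines = paste0("TF", 1:4),
                       control = "NT",
                       replicates = 2,
                       expr_depth = 5e6,
                       expr_sdlog = 1,
                       expr_dispersion = 0.002,
                       effect_fc = 4,
                       binding_enrichment = 8,
                       chip_background = 100,
                       fraction_up = 0.1,
                       fraction_down = 0.1,
                       fraction_bound = 0.5,
                       category_mix = c(
                         intergenic = 0.28, promoter = 0.30,
                         five_prime_utr = 0.05, exon = 0.13,
                         intron = 0.10, three_prime_utr = 0.06,
                         tts = 0.08
                       )) {
  genes_per_chrom <- ceiling(n_genes / n_chromosomes)
  chrom_length_bp <- chrom_length_bp %||% (genes_per_chrom * slot_bp)
  cfg <- list(
    n_chromosomes = n_chromosomes, n_genes = n_genes, slot_bp = slot_bp,
    chrom_length_bp = chrom_length_bp, promoter_bp = promoter_bp,
    tts_bp = tts_bp, window_bp = window_bp, lines = lines,
    control = control, replicates = replicates, expr_depth = expr_depth,
    expr_sdlog = expr_sdlog, expr_dispersion = expr_dispersion,
    effect_fc = effect_fc, binding_enrichment = binding_enrichment,
    chip_background = chip_background, fraction_up = fraction_up,
    fraction_down = fraction_down, fraction_bound = fraction_bound,
    category_mix = category_mix
  )
  for (f in c("fraction_up", "fraction_down", "fraction_bound")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_tf(f, " must be in [0, 1]")
  }
  if (fraction_up + fraction_down > 1) {
    stop_tf("fraction_up + fraction_down must be <= 1")
  }
  if (!setequal(names(category_mix), feature_categories())) {
    stop_tf(
      "category_mix must name all seven categories: ",
      paste(feature_categories(), collapse = ", ")
    )
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop_tf("category_mix must sum to 1")
  }
  if (slot_bp %% window_bp != 0 || slot_bp < 12000) {
    stop_tf("slot_bp must be a multiple of window_bp and >= 12000")
  }
  if (genes_per_chrom * slot_bp > chrom_length_bp) {
    stop_tf(
      "chromosome capacity exceeded: ", genes_per_chrom, " genes x ",
      slot_bp, " bp > ", chrom_length_bp, " bp"
    )
  }
  if (anyDuplicated(lines) || control %in% lines) {
    stop_tf("line names must be unique and distinct from the control")
  }
  structure(cfg, class = "tf_sim_config")
}

# Fixed gene geometry within a slot (0-based offsets relative to gene
# start): two 1 kb exons around a 1 kb intron; CDS spans the inner 500 bp
# of each exon, leaving 500 bp UTRs at both ends.
gene_geometry <- function() {
  list(
    span = 3000L, offset = 4500L,
    exon1 = c(0L, 1000L), intron = c(1000L, 2000L), exon2 = c(2000L, 3000L),
    cds = c(500L, 2500L), utr_len = 500L
  )
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping two-exon genes (with UTRs, mixed
#' strands) on a slot grid and returns both the in-memory gene models and
#' the corresponding GFF3 text, which round-trips exactly through
#' [read_gff_annotation()]. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `annotation` (`tf_annotation`), `gff` (character vector of
#'   GFF3 lines), `chrom_sizes` (tibble `chrom`, `length`).
#' @export
generate_genome <- function(config, seed) {
  stopifnot(inherits(config, "tf_sim_config"))
  geo <- gene_geometry()
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- tibble(chrom = chroms, length = config$chrom_length_bp)
  if (config$n_genes == 0) {
    gff <- c("##gff-version 3", sprintf(
      "##sequence-region %s 1 %d", chroms, config$chrom_length_bp
    ))
    return(list(
      annotation = empty_annotation(), gff = gff, chrom_sizes = chrom_sizes
    ))
  }
  gene_chrom <- chroms[((seq_len(config$n_genes) - 1) %%
    config$n_chromosomes) + 1]
  slot_index <- (seq_len(config$n_genes) - 1) %/% config$n_chromosomes
  strand <- withr::with_seed(
    seed,
    sample(c("+", "-"), config$n_genes, replace = TRUE)
  )
  gstart <- slot_index * config$slot_bp + geo$offset
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    chrom = gene_chrom,
    strand = strand,
    start = as.integer(gstart),
    end = as.integer(gstart + geo$span)
  )
  gff <- build_gff(genes, chrom_sizes, geo)
  ann <- genes |>
    mutate(
      transcript_id = paste0(.data$gene_id, ".t1"),
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
      exons = purrr::map(.data$start, function(s) {
        tibble(
          start = s + c(geo$exon1[1], geo$exon2[1]),
          end = s + c(geo$exon1[2], geo$exon2[2])
        )
      }),
      cds = purrr::map(.data$start, function(s) {
        tibble(
          start = s + c(geo$cds[1], geo$exon2[1]),
          end = s + c(geo$exon1[2], geo$cds[2])
        )
      })
    ) |>
    select(
      "gene_id", "transcript_id", "chrom", "strand", "start", "end",
      "tss", "tes", "exons", "cds"
    )
  ann <- derive_utrs(ann) |> arrange(.data$chrom, .data$start)
  list(
    annotation = new_tf_annotation(ann), gff = gff,
    chrom_sizes = chrom_sizes
  )
}

# GFF3 text for the slot-grid genes (1-based inclusive).
build_gff <- function(genes, chrom_sizes, geo) {
  header <- c(
    "##gff-version 3",
    sprintf(
      "##sequence-region %s 1 %d", chrom_sizes$chrom, chrom_sizes$length
    )
  )
  rows <- purrr::pmap(genes, function(gene_id, chrom, strand, start, end) {
    s1 <- start + 1L # 1-based
    tid <- paste0(gene_id, ".t1")
    fmt <- function(type, a, b, attrs) {
      sprintf(
        "%s\ttfdirect_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
        chrom, type, a, b, strand, attrs
      )
    }
    c(
      fmt("gene", s1, end, paste0("ID=", gene_id)),
      fmt("mRNA", s1, end, paste0("ID=", tid, ";Parent=", gene_id)),
      fmt(
        "exon", s1 + geo$exon1[1], start + geo$exon1[2],
        paste0("Parent=", tid)
      ),
      fmt(
        "exon", s1 + geo$exon2[1], start + geo$exon2[2],
        paste0("Parent=", tid)
      ),
      fmt(
        "CDS", s1 + geo$cds[1], start + geo$exon1[2],
        paste0("Parent=", tid)
      ),
      fmt(
        "CDS", s1 + geo$exon2[1], start + geo$cds[2],
        paste0("Parent=", tid)
      )
    )
  })
  c(header, unlist(rows))
}

#' Plant the ground truth: regulation and binding per gene per line
#'
#' Per line, disjoint `up` and `down` gene sets are drawn, and a bound set
#' receives one binding interval each, with the feature category sampled
#' from `category_mix`. Every planted interval is a single coverage window
#' fully inside the claimed feature region of its gene (the `intergenic`
#' region is placed 3-4 kb upstream of the TSS, beyond the promoter but
#' still nearest to its gene), and its center is verified to classify to
#' the planted category.
#'
#' @param config A [sim_config()].
#' @param annotation The annotation from [generate_genome()].
#' @param seed Integer seed.
#' @return List of class `tf_truth`: `regulation` (tibble `line`,
#'   `gene_id`, `regulation`, `fold`), `binding` (tibble `line`,
#'   `gene_id`, `chrom`, `start`, `end`, `category`, `enrichment`),
#'   `genes` (the gene universe).
#' @export
generate_truth <- function(config, annotation, seed) {
  stopifnot(inherits(config, "tf_sim_config"))
  n <- nrow(annotation)
  withr::with_seed(seed, {
    reg <- purrr::map(config$lines, function(ln) {
      ids <- sample(annotation$gene_id)
      n_up <- round(config$fraction_up * n)
      n_down <- round(config$fraction_down * n)
      tibble(
        line = ln,
        gene_id = ids,
        regulation = c(
          rep("up", n_up), rep("down", n_down),
          rep("null", n - n_up - n_down)
        )
      )
    }) |>
      purrr::list_rbind() |>
      mutate(fold = dplyr::case_when(
        .data$regulation == "up" ~ config$effect_fc,
        .data$regulation == "down" ~ 1 / config$effect_fc,
        TRUE ~ 1
      ))

    bind <- purrr::map(config$lines, function(ln) {
      bound <- sort(sample(n, round(config$fraction_bound * n)))
      cats <- sample(
        names(config$category_mix), length(bound),
        replace = TRUE, prob = config$category_mix
      )
      purrr::map2(bound, cats, function(i, cat) {
        g <- annotation[i, ]
        win <- plant_window(g, cat, config)
        tibble(
          line = ln, gene_id = g$gene_id, chrom = g$chrom,
          start = win[1], end = win[2], category = cat,
          enrichment = config$binding_enrichment
        )
      }) |>
        purrr::list_rbind()
    }) |>
      purrr::list_rbind()
  })

  # self-consistency: planted centers classify to the planted category
  if (nrow(bind) > 0) {
    chk <- classify_loci(
      annotation, bind,
      promoter_bp = config$promoter_bp, tts_bp = config$tts_bp
    )
    bad <- which(chk$category != bind$category | chk$gene_id != bind$gene_id)
    if (length(bad) > 0) {
      stop_tf(
        "planted interval failed self-consistency at gene ",
        bind$gene_id[bad[1]], " (planted ", bind$category[bad[1]],
        ", classified ", chk$category[bad[1]], ")"
      )
    }
  }
  structure(
    list(
      regulation = reg, binding = bind, genes = annotation$gene_id,
      config = config
    ),
    class = "tf_truth"
  )
}

# One grid-aligned window fully inside the feature region of gene `g`.
plant_window <- function(g, category, config) {
  geo <- gene_geometry()
  w <- config$window_bp
  s <- g$start
  plus <- g$strand == "+"
  region <- switch(category,
    promoter = if (plus) c(g$tss - config$promoter_bp, g$tss) else
      c(g$tss + 1L, g$tss + config$promoter_bp + 1L),
    five_prime_utr = if (plus) c(s, s + geo$utr_len) else
      c(g$end - geo$utr_len, g$end),
    exon = if (plus) c(s + geo$cds[1], s + geo$exon1[2]) else
      c(s + geo$exon2[1], s + geo$cds[2]),
    intron = c(s + geo$intron[1], s + geo$intron[2]),
    three_prime_utr = if (plus) c(g$end - geo$utr_len, g$end) else
      c(s, s + geo$utr_len),
    tts = if (plus) c(g$tes + 1L, g$tes + config$tts_bp + 1L) else
      c(g$tes - config$tts_bp, g$tes),
    intergenic = if (plus) c(g$tss - 4000L, g$tss - 3000L) else
      c(g$tss + 3001L, g$tss + 4001L)
  )
  first <- ceiling(region[1] / w) * w
  last <- floor(region[2] / w) * w - w
  if (last < first) {
    stop_tf(
      "no aligned window fits the ", category, " region of gene ",
      g$gene_id
    )
  }
  pick <- first + w * sample.int((last - first) / w + 1, 1) - w
  c(as.integer(pick), as.integer(pick + w))
}

#' The planted direct-target gene set of one line
#'
#' Genes planted `up` in the line whose planted binding category is
#' promoter or 5'UTR — the recovery oracle for the integration pipeline.
#'
#' @param truth A `tf_truth` from [generate_truth()].
#' @param line Line name.
#' @return Sorted character vector of gene ids.
#' @export
truth_direct_targets <- function(truth, line) {
  stopifnot(inherits(truth, "tf_truth"))
  up <- truth$regulation |>
    filter(.data$line == !!line, .data$regulation == "up")
  bound <- truth$binding |>
    filter(
      .data$line == !!line,
      .data$category %in% c("promoter", "five_prime_utr")
    )
  sort(intersect(up$gene_id, bound$gene_id))
}

#' Generate RNA-Seq fragment counts with planted fold changes
#'
#' Baseline gene abundances are log-normal; counts are negative binomial
#' with mean `depth * weight * fold`, where `fold` is the planted effect
#' in the gene's line (1 elsewhere, including the NT control). Library
#' sizes are the realized column sums, so planted genes slightly inflate
#' treated libraries (a real compositional effect of overexpression).
#'
#' @param truth A `tf_truth`.
#' @param config The [sim_config()] used to build `truth`.
#' @param seed Integer seed.
#' @return List: `counts` (wide tibble `gene_id`, `length_bp`, one column
#'   per sample), `samples` (tibble `sample_id`, `condition`, `replicate`,
#'   `library_size`).
#' @export
generate_expression <- function(truth, config, seed) {
  stopifnot(inherits(truth, "tf_truth"))
  genes <- truth$genes
  n <- length(genes)
  geo <- gene_geometry()
  exon_len <- (geo$exon1[2] - geo$exon1[1]) + (geo$exon2[2] - geo$exon2[1])
  conditions <- c(config$control, config$lines)
  sample_ids <- as.vector(t(outer(
    conditions, seq_len(config$replicates),
    function(c, r) sprintf("%s_rep%d", c, r)
  )))
  fold <- matrix(1, nrow = n, ncol = length(conditions),
                 dimnames = list(genes, conditions))
  for (ln in config$lines) {
    reg <- truth$regulation |> filter(.data$line == ln)
    fold[reg$gene_id, ln] <- reg$fold
  }
  counts <- withr::with_seed(seed, {
    w <- rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)
    w <- w / sum(w)
    out <- matrix(0L, nrow = n, ncol = length(sample_ids),
                  dimnames = list(genes, sample_ids))
    for (j in seq_along(sample_ids)) {
      cond <- rep(conditions, each = config$replicates)[j]
      mu <- config$expr_depth * w * fold[, cond]
      out[, j] <- rnbinom(n, mu = mu, size = 1 / config$expr_dispersion)
    }
    out
  })
  samples <- tibble(
    sample_id = sample_ids,
    condition = rep(conditions, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(conditions)),
    library_size = as.numeric(colSums(counts))
  )
  counts_tbl <- bind_cols(
    tibble(gene_id = genes, length_bp = exon_len),
    as_tibble(counts)
  )
  list(counts = counts_tbl, samples = samples)
}

#' Generate ChIP coverage tracks with planted binding
#'
#' Windows tile each chromosome at `window_bp`. All tracks draw Poisson
#' background counts at `chip_background` per window; in a line's track,
#' windows overlapping that line's planted binding intervals have their
#' rate multiplied by `binding_enrichment`. The NT track is pure
#' background. Library size is the realized total count of the track.
#'
#' @param truth A `tf_truth`.
#' @param config The [sim_config()].
#' @param chrom_sizes Tibble `chrom`, `length` from [generate_genome()].
#' @param seed Integer seed.
#' @return Named list (control first, then lines) of tracks: each a list
#'   with `sample_id`, `library_size`, `windows` (tibble `chrom`, `start`,
#'   `end`, `count`).
#' @export
generate_chip <- function(truth, config, chrom_sizes, seed) {
  stopifnot(inherits(truth, "tf_truth"))
  grid <- purrr::pmap(chrom_sizes, function(chrom, length) {
    starts <- seq(0L, length - config$window_bp, by = config$window_bp)
    tibble(chrom = chrom, start = starts, end = starts + config$window_bp)
  }) |>
    purrr::list_rbind() |>
    arrange(.data$chrom, .data$start)
  track_names <- c(config$control, config$lines)
  # windows are a regular grid, so interval -> window indices is arithmetic
  offsets <- grid |>
    mutate(row = dplyr::row_number()) |>
    group_by(.data$chrom) |>
    summarise(first_row = min(.data$row), .groups = "drop")
  window_hits <- function(b) {
    unique(unlist(purrr::pmap(
      list(b$chrom, b$start, b$end),
      function(ch, s, e) {
        o <- offsets$first_row[offsets$chrom == ch]
        o + seq(
          floor(s / config$window_bp),
          ceiling(e / config$window_bp) - 1
        )
      }
    )))
  }
  withr::with_seed(seed, {
    tracks <- purrr::map(track_names, function(tn) {
      lambda <- rep(config$chip_background, nrow(grid))
      if (tn != config$control) {
        b <- truth$binding |> filter(.data$line == tn)
        if (nrow(b) > 0) {
          hit <- window_hits(b)
          lambda[hit] <- lambda[hit] * config$binding_enrichment
        }
      }
      counts <- rpois(nrow(grid), lambda)
      list(
        sample_id = tn,
        library_size = sum(counts),
        windows = grid |> mutate(count = as.numeric(counts))
      )
    })
    setNames(tracks, track_names)
  })
}

#' Score called direct targets against the planted truth
#'
#' Per line: `precision = |called and planted| / |called|` (1 when both
#' sets are empty, missing when nothing is called but targets were
#' planted) and `recall = |called and planted| / |planted|` (1 when
#' nothing was planted).
#'
#' @param targets A `tf_targets` from [integrate_targets()].
#' @param truth The `tf_truth` the inputs were generated from.
#' @return Tibble: `line`, `n_called`, `n_truth`, `n_correct`,
#'   `precision`, `recall`.
#' @export
evaluate_recovery <- function(targets, truth) {
  stopifnot(inherits(targets, "tf_targets"), inherits(truth, "tf_truth"))
  called_all <- unique(targets$supporting_loci$gene_id)
  alien <- setdiff(called_all, truth$genes)
  if (length(alien) > 0) {
    stop_tf(
      "called genes outside the truth universe: ",
      paste(head(alien, 5), collapse = ", ")
    )
  }
  purrr::map(truth$config$lines, function(ln) {
    called <- unique(
      targets$supporting_loci$gene_id[targets$supporting_loci$line == ln]
    )
    planted <- truth_direct_targets(truth, ln)
    n_correct <- length(intersect(called, planted))
    tibble(
      line = ln,
      n_called = length(called),
      n_truth = length(planted),
      n_correct = n_correct,
      precision = if (length(called) > 0) {
        n_correct / length(called)
      } else if (length(planted) == 0) 1 else NA_real_,
      recall = if (length(planted) > 0) {
        n_correct / length(planted)
      } else {
        1
      }
    )
  }) |>
    purrr::list_rbind()
}

#' Generate a synthetic GO annotation with planted enrichment
#'
#' Assigns each gene a Poisson number of random terms over three
#' namespaces; two planted terms preferentially annotate the union of
#' planted direct-target genes, so a SEA of recovered targets against the
#' expressed population should flag them.
#'
#' @param truth A `tf_truth`.
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @param n_terms Number of background terms (default 40).
#' @return List: `gene2go` (tibble `gene_id`, `term_id`), `term_meta`
#'   (tibble `term_id`, `name`, `namespace`).
#' @export
generate_go <- function(truth, config, seed, n_terms = 40) {
  stopifnot(inherits(truth, "tf_truth"))
  genes <- truth$genes
  term_ids <- sprintf("SYN:%04d", seq_len(n_terms + 2))
  namespaces <- rep(
    c("biological_process", "molecular_function", "cellular_component"),
    length.out = n_terms + 2
  )
  planted_terms <- term_ids[1:2]
  target_union <- sort(unique(unlist(
    purrr::map(config$lines, truth_direct_targets, truth = truth)
  )))
  withr::with_seed(seed, {
    k <- rpois(length(genes), 2)
    background <- tibble(
      gene_id = rep(genes, k),
      term_id = sample(term_ids[-(1:2)], sum(k), replace = TRUE)
    )
    planted <- purrr::map(planted_terms, function(tm) {
      in_t <- target_union[
        stats::runif(length(target_union)) < 0.6
      ]
      rest <- setdiff(genes, target_union)
      in_r <- rest[stats::runif(length(rest)) < 0.02]
      tibble(gene_id = c(in_t, in_r), term_id = tm)
    }) |>
      purrr::list_rbind()
    gene2go <- bind_rows(background, planted) |>
      distinct() |>
      arrange(.data$gene_id, .data$term_id)
  })
  list(
    gene2go = gene2go,
    term_meta = tibble(
      term_id = term_ids,
      name = sprintf("synthetic term %d", seq_along(term_ids)),
      namespace = namespaces
    )
  )
}

#' Generate the complete synthetic experiment
#'
#' Runs [generate_genome()], [generate_truth()], [generate_expression()],
#' [generate_chip()] and [generate_go()] with sub-seeds derived from
#' `seed`, returning everything in memory and optionally writing the
#' standard file layout (`genes.gff3`, `chrom.sizes`, `counts.tsv`,
#' `samples.tsv`, `chip_<sample>.bedGraph`, `chip_samples.tsv`,
#' `go_annotation.tsv`, `go_terms.tsv`, `truth.json`). All outputs are
#' byte-deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (< 2^31 - 10).
#' @param dir Optional output directory; created if missing.
#' @return List of class `tf_sim`: `config`, `annotation`, `gff`,
#'   `chrom_sizes`, `truth`, `counts`, `samples`, `chip` (track list),
#'   `go`, and `dir` (NULL or the output path).
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1,
                                dir = NULL) {
  stopifnot(inherits(config, "tf_sim_config"))
  if (seed > 2^31 - 10) stop_tf("seed too large")
  genome <- generate_genome(config, seed + 1)
  truth <- generate_truth(config, genome$annotation, seed + 2)
  expr <- generate_expression(truth, config, seed + 3)
  chip <- generate_chip(truth, config, genome$chrom_sizes, seed + 4)
  go <- generate_go(truth, config, seed + 5)
  sim <- structure(
    list(
      config = config, annotation = genome$annotation, gff = genome$gff,
      chrom_sizes = genome$chrom_sizes, truth = truth,
      counts = expr$counts, samples = expr$samples, chip = chip, go = go,
      dir = dir
    ),
    class = "tf_sim"
  )
  if (!is.null(dir)) {
    write_simulation(sim, dir)
  }
  sim
}

write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeLines(sim$gff, p("genes.gff3"))
  readr::write_tsv(sim$chrom_sizes, p("chrom.sizes"), col_names = FALSE)
  readr::write_tsv(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$samples, p("samples.tsv"))
  chip_sheet <- purrr::imap(sim$chip, function(tr, nm) {
    f <- sprintf("chip_%s.bedGraph", nm)
    write_bedgraph(tr$windows, p(f))
    tibble(
      sample_id = nm,
      role = if (nm == sim$config$control) "control" else "treatment",
      library_size = tr$library_size,
      path = f
    )
  }) |>
    purrr::list_rbind()
  readr::write_tsv(chip_sheet, p("chip_samples.tsv"))
  readr::write_tsv(sim$go$gene2go, p("go_annotation.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(sim$go$term_meta, p("go_terms.tsv"))
  truth_json <- list(
    regulation = sim$truth$regulation,
    binding = sim$truth$binding,
    direct_targets = setNames(
      purrr::map(
        sim$config$lines, truth_direct_targets,
        truth = sim$truth
      ),
      sim$config$lines
    )
  )
  jsonlite::write_json(
    truth_json, p("truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
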