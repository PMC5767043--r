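test_that("simulation config is validated", {
  expect_error(sim_config(fraction_up = 0.7, fraction_down = 0.5), "<= 1")
  expect_error(sim_config(fraction_bound = 1.2), "must be in")
  expect_error(
    sim_config(category_mix = c(promoter = 1)), "seven categories"
  )
  expect_error(
    sim_config(n_genes = 1000, n_chromosomes = 1, chrom_length_bp = 1e6),
    "capacity"
  )
  expect_error(sim_config(lines = c("A", "A", "B", "C")), "unique")
})

test_that("genome generation is byte-deterministic and supports n_genes = 0", {
  cfg <- small_config()
  a <- generate_genome(cfg, seed = 5)
  b <- generate_genome(cfg, seed = 5)
  expect_identical(a$gff, b$gff)
  c <- generate_genome(cfg, seed = 6)
  expect_false(identical(a$gff, c$gff))

  empty <- generate_genome(sim_config(n_genes = 0), seed = 1)
  expect_equal(nrow(empty$annotation), 0)
  path <- tempfile(fileext = ".gff3")
  writeLines(empty$gff, path)
  expect_equal(nrow(read_gff_annotation(path)), 0)
})

test_that("generated genes are non-overlapping two-exon models with UTRs", {
  cfg <- small_config()
  ann <- generate_genome(cfg, seed = 2)$annotation
  by_chrom <- split(ann, ann$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
  expect_true(all(sapply(ann$exons, nrow) >= 2))
  expect_true(all(sapply(ann$utr5, nrow) >= 1))
  expect_true(all(sapply(ann$utr3, nrow) >= 1))
  expect_true(all(c("+", "-") %in% ann$strand))
})

test_that("planted binding intervals classify to their planted category", {
  cfg <- sim_config(
    n_genes = 120, n_chromosomes = 2,
    # equal planting pressure on every category
    category_mix = setNames(
      rep(1 / 7, 7), tfdirect:::feature_categories()
    ),
    fraction_bound = 1
  )
  gen <- generate_genome(cfg, seed = 31)
  truth <- generate_truth(cfg, gen$annotation, seed = 32)
  expect_true(all(tfdirect:::feature_categories() %in%
    truth$binding$category))
  chk <- classify_loci(gen$annotation, truth$binding)
  expect_identical(chk$category, truth$binding$category)
  expect_identical(chk$gene_id, truth$binding$gene_id)
})

test_that("expression generator plants detectable fold changes", {
  # null case: effect_fc = 1 leaves planted genes at fold ~ 1
  cfg0 <- sim_config(
    n_genes = 500, n_chromosomes = 2, effect_fc = 1,
    expr_dispersion = 1e-4
  )
  gen <- generate_genome(cfg0, seed = 41)
  truth <- generate_truth(cfg0, gen$annotation, seed = 42)
  expr <- generate_expression(truth, cfg0, seed = 43)
  fp <- fpkm_table(expr$counts, expr$samples)
  fold_of <- function(fp, truth, line) {
    up <- truth$regulation$gene_id[
      truth$regulation$line == line & truth$regulation$regulation == "up"
    ]
    m <- fp |>
      dplyr::filter(gene_id %in% up, condition %in% c(line, "NT")) |>
      dplyr::group_by(gene_id, condition) |>
      dplyr::summarise(mu = mean(fpkm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = condition, values_from = mu)
    mean(m[[line]] / m[["NT"]])
  }
  expect_equal(fold_of(fp, truth, "TF1"), 1, tolerance = 0.05)

  # law-of-large-numbers case: small planted fractions, tiny dispersion,
  # realized FPKM fold approaches effect_fc (library composition keeps it
  # a few percent below)
  cfg <- sim_config(
    n_genes = 500, n_chromosomes = 2, effect_fc = 4,
    expr_dispersion = 1e-4, fraction_up = 0.02, fraction_down = 0.02
  )
  gen <- generate_genome(cfg, seed = 41)
  truth <- generate_truth(cfg, gen$annotation, seed = 42)
  expr <- generate_expression(truth, cfg, seed = 43)
  fp <- fpkm_table(expr$counts, expr$samples)
  expect_equal(fold_of(fp, truth, "TF1"), 4, tolerance = 0.1)

  # determinism
  expr2 <- generate_expression(truth, cfg, seed = 43)
  expect_identical(expr$counts, expr2$counts)
})

test_that("ChIP generator: planted promoter windows are recovered, null is quiet", {
  cfg <- sim_config(
    n_genes = 200, n_chromosomes = 1, chip_background = 20,
    binding_enrichment = 8, fraction_bound = 1,
    category_mix = c(
      intergenic = 0, promoter = 1, five_prime_utr = 0, exon = 0,
      intron = 0, three_prime_utr = 0, tts = 0
    )
  )
  gen <- generate_genome(cfg, seed = 51)
  recovered <- sapply(1:10, function(s) {
    truth <- generate_truth(cfg, gen$annotation, seed = 100 + s)
    chip <- generate_chip(truth, cfg, gen$chrom_sizes, seed = 200 + s)
    tr <- chip[["TF1"]]
    nt <- chip[["NT"]]
    loci <- call_enriched_loci(
      tr$windows, nt$windows, tr$library_size, nt$library_size
    )
    b <- truth$binding |> dplyr::filter(line == "TF1")
    hit <- sapply(seq_len(nrow(b)), function(i) {
      any(loci$chrom == b$chrom[i] & loci$start < b$end[i] &
        loci$end > b$start[i])
    })
    mean(hit)
  })
  expect_gte(mean(recovered), 0.95)

  # binding_enrichment = 1: retained loci are threshold false positives only
  cfg_null <- sim_config(
    n_genes = 200, n_chromosomes = 1, chip_background = 20,
    binding_enrichment = 1, fraction_bound = 1
  )
  truth0 <- generate_truth(cfg_null, gen$annotation, seed = 61)
  chip0 <- generate_chip(truth0, cfg_null, gen$chrom_sizes, seed = 62)
  loci0 <- call_enriched_loci(
    chip0$TF1$windows, chip0$NT$windows,
    chip0$TF1$library_size, chip0$NT$library_size
  )
  n_windows <- nrow(chip0$NT$windows)
  # Poisson(20) vs Poisson(20) clears a 2-fold RPM ratio ~1.6% of the time
  expect_lt(sum(loci0$n_windows), 0.05 * n_windows)

  chip0b <- generate_chip(truth0, cfg_null, gen$chrom_sizes, seed = 62)
  expect_identical(chip0$TF1$windows, chip0b$TF1$windows)
})

test_that("recovery scoring handles exact, empty and partial calls", {
  cfg <- small_config()
  sim <- simulate_experiment(cfg, seed = 71)
  # perfect call: build targets directly from truth
  lines <- cfg$lines
  sup <- purrr::map(lines, function(ln) {
    tibble(line = ln, gene_id = truth_direct_targets(sim$truth, ln))
  }) |> purrr::list_rbind()
  perfect <- structure(
    list(
      direct_targets = sup |> dplyr::distinct(gene_id),
      supporting_loci = sup, locus_table = tibble()
    ),
    class = "tf_targets"
  )
  ev <- evaluate_recovery(perfect, sim$truth)
  expect_true(all(ev$precision == 1))
  expect_true(all(ev$recall == 1))

  empty <- structure(
    list(
      direct_targets = tibble(),
      supporting_loci = tibble(line = character(), gene_id = character()),
      locus_table = tibble()
    ),
    class = "tf_targets"
  )
  ev0 <- evaluate_recovery(empty, sim$truth)
  expect_true(all(ev0$recall[ev0$n_truth > 0] == 0))
  expect_true(all(is.na(ev0$precision[ev0$n_truth > 0])))

  alien <- perfect
  alien$supporting_loci <- tibble(line = "TF1", gene_id = "NOT_A_GENE")
  expect_error(evaluate_recovery(alien, sim$truth), "universe")
})

test_that("the full simulation is deterministic given one seed", {
  cfg <- small_config()
  d1 <- tempfile("sim1")
  d2 <- tempfile("sim2")
  simulate_experiment(cfg, seed = 9, dir = d1)
  simulate_experiment(cfg, seed = 9, dir = d2)
  f1 <- sort(list.files(d1))
  expect_true(length(f1) >= 10)
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_equal(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
})
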