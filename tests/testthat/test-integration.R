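make_deg_stub <- function(df) {
  # minimal tf_deg-shaped tibble: gene_id, condition, direction
  out <- df |>
    mutate(
      mean_fpkm_treatment = 10, mean_fpkm_control = 5,
      fold_change = ifelse(direction == "up", 3, 1),
      log2_fold_change = log2(fold_change), p_value = 0.01
    )
  class(out) <- c("tf_deg", class(out))
  out
}

make_locus <- function(line, gene, category, log2r = 2, start = 1000) {
  tibble(
    line = line, chrom = "chr1", start = start, end = start + 200,
    log2_ratio = log2r, gene_id = gene, category = category,
    distance_to_tss = -500L
  )
}

test_that("each integration filter acts once in the three-locus example", {
  loci <- bind_rows(
    make_locus("TF1", "A", "promoter", start = 1000),
    make_locus("TF1", "B", "exon", start = 3000),
    make_locus("TF1", "C", "promoter", start = 5000)
  )
  degs <- make_deg_stub(tibble(
    gene_id = c("A", "B", "C"), condition = "TF1",
    direction = c("up", "up", "none")
  ))
  res <- integrate_targets(loci, degs)
  expect_equal(res$direct_targets$gene_id, "A")
  tab <- res$locus_table
  get_n <- function(stage, cat) {
    x <- tab$n[tab$stage == stage & tab$category == cat]
    if (length(x) == 0) 0L else x
  }
  expect_equal(get_n("enriched", "promoter"), 2L)
  expect_equal(get_n("enriched", "exon"), 1L)
  expect_equal(get_n("up_regulated", "promoter"), 1L)
  expect_equal(get_n("up_regulated", "exon"), 1L)
})

test_that("no up-regulated genes means no direct targets", {
  loci <- make_locus("TF1", "A", "promoter")
  degs <- make_deg_stub(tibble(
    gene_id = "A", condition = "TF1", direction = "none"
  ))
  res <- integrate_targets(loci, degs)
  expect_equal(nrow(res$direct_targets), 0)
})

test_that("loci on genes outside the DEG universe and line mismatches error", {
  loci <- make_locus("TF1", "Z", "promoter")
  degs <- make_deg_stub(tibble(
    gene_id = "A", condition = "TF1", direction = "up"
  ))
  expect_error(integrate_targets(loci, degs), "Z")

  degs2 <- make_deg_stub(tibble(
    gene_id = "Z", condition = "TF9", direction = "up"
  ))
  expect_error(integrate_targets(loci, degs2), "line names differ")
})

test_that("identical (line, interval) duplicates collapse; distinct loci stay", {
  loci <- bind_rows(
    make_locus("TF1", "A", "promoter", start = 1000),
    make_locus("TF1", "A", "promoter", start = 1000), # exact duplicate
    make_locus("TF1", "A", "promoter", start = 1400) # second locus
  )
  degs <- make_deg_stub(tibble(
    gene_id = "A", condition = "TF1", direction = "up"
  ))
  res <- integrate_targets(loci, degs)
  expect_equal(nrow(res$supporting_loci), 2)
  expect_equal(res$direct_targets$n_loci, 2L)
})

test_that("integration recovers exactly the planted truth set-algebra", {
  cfg <- small_config()
  sim <- simulate_experiment(cfg, seed = 17)
  rep <- run_pipeline(sim, quiet = TRUE)
  deg <- tidy(rep$degs)
  # independent set-algebra oracle over planted truth and called DEGs:
  # per line, {genes with planted promoter/5'UTR binding} intersect
  # {genes called up}, restricted to genes whose planted window was
  # recovered by enrichment -- under strong effects recovery is complete,
  # so the oracle reduces to truth-binding x called-up
  for (ln in cfg$lines) {
    bound <- sim$truth$binding |>
      filter(line == ln, category %in% c("promoter", "five_prime_utr"))
    up <- deg |> filter(condition == ln, direction == "up")
    want <- sort(intersect(bound$gene_id, up$gene_id))
    got <- sort(unique(
      rep$targets$supporting_loci$gene_id[
        rep$targets$supporting_loci$line == ln
      ]
    ))
    expect_equal(got, want, info = ln)
  }
})

test_that("filters only shrink the locus set and dedup only shrinks genes", {
  cfg <- small_config()
  sim <- simulate_experiment(cfg, seed = 23)
  rep <- run_pipeline(sim, quiet = TRUE)
  tab <- rep$targets$locus_table
  n_enriched <- sum(tab$n[tab$stage == "enriched"])
  n_up <- sum(tab$n[tab$stage == "up_regulated"])
  expect_lte(n_up, n_enriched)
  expect_lte(
    nrow(rep$targets$direct_targets), nrow(rep$targets$supporting_loci)
  )
})

test_that("Venn cells partition the direct-target genes", {
  # all genes in all four lines -> only the 4-way cell is non-zero
  lines4 <- paste(paste0("TF", 1:4), collapse = ",")
  targets_all <- structure(
    list(
      direct_targets = tibble(
        gene_id = paste0("g", 1:5), n_lines = 4L, lines = lines4,
        n_loci = 4L, best_log2_ratio = 2, distance_to_tss = -100L
      ),
      supporting_loci = tibble(
        line = rep(paste0("TF", 1:4), each = 5),
        gene_id = rep(paste0("g", 1:5), 4)
      ),
      locus_table = tibble()
    ),
    class = "tf_targets"
  )
  v <- venn_partition(targets_all, lines = paste0("TF", 1:4))
  expect_equal(nrow(v$cells), 15)
  expect_equal(sum(v$cells$n_genes), 5)
  expect_equal(v$cells$n_genes[v$cells$subset == lines4], 5)
  expect_true(all(v$per_line$n_genes == 5))

  # disjoint singleton memberships -> only exclusive cells filled
  targets_disj <- structure(
    list(
      direct_targets = tibble(
        gene_id = paste0("g", 1:4), n_lines = 1L,
        lines = paste0("TF", 1:4),
        n_loci = 1L, best_log2_ratio = 2, distance_to_tss = -100L
      ),
      supporting_loci = tibble(
        line = paste0("TF", 1:4), gene_id = paste0("g", 1:4)
      ),
      locus_table = tibble()
    ),
    class = "tf_targets"
  )
  v2 <- venn_partition(targets_disj, lines = paste0("TF", 1:4))
  expect_equal(sum(v2$cells$n_genes), 4)
  expect_true(all(v2$cells$n_genes[v2$cells$n_lines > 1] == 0))
})

test_that("random line memberships match exhaustive subset enumeration", {
  set.seed(77)
  lines <- paste0("TF", 1:4)
  genes <- sprintf("g%03d", 1:200)
  membership <- lapply(genes, function(g) {
    sort(sample(lines, sample(1:4, 1)))
  })
  targets <- structure(
    list(
      direct_targets = tibble(
        gene_id = genes,
        n_lines = lengths(membership),
        lines = sapply(membership, paste, collapse = ","),
        n_loci = 1L, best_log2_ratio = 2, distance_to_tss = -100L
      ),
      supporting_loci = tibble(
        line = unlist(membership),
        gene_id = rep(genes, lengths(membership))
      ),
      locus_table = tibble()
    ),
    class = "tf_targets"
  )
  v <- venn_partition(targets, lines = lines)
  # brute-force cell counts
  for (i in seq_len(nrow(v$cells))) {
    subset_lines <- strsplit(v$cells$subset[i], ",")[[1]]
    want <- sum(sapply(membership, function(m) setequal(m, subset_lines)))
    expect_equal(v$cells$n_genes[i], want, info = v$cells$subset[i])
  }
  expect_equal(sum(v$cells$n_genes), length(genes))
  # per-line totals = sum of cells containing that line
  for (ln in lines) {
    has <- sapply(
      strsplit(v$cells$subset, ","), function(s) ln %in% s
    )
    expect_equal(
      v$per_line$n_genes[v$per_line$line == ln],
      sum(v$cells$n_genes[has])
    )
  }
})

test_that("direct-target fractions are exact percentages of up-regulated genes", {
  lines <- "TF1"
  up_genes <- sprintf("u%03d", 1:200)
  direct <- up_genes[1:17]
  degs <- make_deg_stub(tibble(
    gene_id = up_genes, condition = "TF1", direction = "up"
  ))
  targets <- structure(
    list(
      direct_targets = tibble(
        gene_id = direct, n_lines = 1L, lines = "TF1", n_loci = 1L,
        best_log2_ratio = 2, distance_to_tss = -100L
      ),
      supporting_loci = tibble(line = "TF1", gene_id = direct),
      locus_table = tibble()
    ),
    class = "tf_targets"
  )
  f <- direct_target_fraction(targets, degs)
  expect_equal(f$fraction_pct, 8.5)

  # every up gene a target -> 100; no targets -> 0
  targets_all <- targets
  targets_all$supporting_loci <- tibble(line = "TF1", gene_id = up_genes)
  expect_equal(direct_target_fraction(targets_all, degs)$fraction_pct, 100)
  targets_none <- targets
  targets_none$supporting_loci <- tibble(
    line = character(), gene_id = character()
  )
  expect_equal(direct_target_fraction(targets_none, degs)$fraction_pct, 0)

  # zero up-regulated genes -> missing fraction
  degs_none <- make_deg_stub(tibble(
    gene_id = up_genes, condition = "TF1", direction = "none"
  ))
  expect_true(is.na(direct_target_fraction(targets, degs_none)$fraction_pct))
})
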