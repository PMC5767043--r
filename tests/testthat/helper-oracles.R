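# Independent oracles and fixture builders used across the test files.
# Every oracle restates the operation's definition with a different
# mechanism (per-base materialization, naive loops, closed-form sums)
# so that agreement is evidence, not tautology.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# ---- GFF fixture builder -----------------------------------------------
# genes: list of lists with chrom, strand, start (0-based), exons (list of
# c(start, end) 0-based half-open, gene-relative? no: absolute), cds
# (absolute, optional). Writes 1-based inclusive GFF3, returns the path.
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    gid <- g$id %||% sprintf("tg%02d", i)
    tid <- paste0(gid, ".t1")
    span <- c(min(sapply(g$exons, `[`, 1)), max(sapply(g$exons, `[`, 2)))
    row <- function(type, a, b, attrs) {
      sprintf(
        "%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
        g$chrom, type, a + 1L, b, g$strand, attrs
      )
    }
    lines <- c(
      lines,
      row("gene", span[1], span[2], paste0("ID=", gid)),
      row("mRNA", span[1], span[2], paste0("ID=", tid, ";Parent=", gid)),
      unlist(lapply(g$exons, function(e) {
        row("exon", e[1], e[2], paste0("Parent=", tid))
      })),
      if (!is.null(g$cds)) {
        unlist(lapply(g$cds, function(e) {
          row("CDS", e[1], e[2], paste0("Parent=", tid))
        }))
      }
    )
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- per-base feature-classification oracle ----------------------------
# Materializes every feature of every gene base by base, then classifies a
# position by (1) nearest TSS (tie: containing span, then smallest id),
# (2) lookup in the assigned gene's explicit base map.
oracle_classify <- function(ann, chrom, positions,
                            promoter_bp = 2000, tts_bp = 1000) {
  genes <- ann[ann$chrom == chrom, ]
  stopifnot(nrow(genes) > 0)
  base_maps <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    span_len <- g$end - g$start
    body <- rep("intron", span_len) # relative to g$start
    mark <- function(map, ivs, lab) {
      if (nrow(ivs) > 0) {
        for (j in seq_len(nrow(ivs))) {
          map[(ivs$start[j] - g$start + 1):(ivs$end[j] - g$start)] <- lab
        }
      }
      map
    }
    body <- mark(body, g$exons[[1]], "exon")
    body <- mark(body, g$utr5[[1]], "five_prime_utr")
    body <- mark(body, g$utr3[[1]], "three_prime_utr")
    if (g$strand == "+") {
      promoter <- seq(g$tss - promoter_bp, g$tss - 1)
      tts <- seq(g$tes + 1, g$tes + tts_bp)
    } else {
      promoter <- seq(g$tss + 1, g$tss + promoter_bp)
      tts <- seq(g$tes - tts_bp, g$tes - 1)
    }
    list(body = body, promoter = promoter, tts = tts)
  })
  out <- lapply(positions, function(p) {
    d <- abs(p - genes$tss)
    cand <- which(d == min(d))
    if (length(cand) > 1) {
      inside <- cand[genes$start[cand] <= p & p < genes$end[cand]]
      if (length(inside) == 1) {
        cand <- inside
      } else {
        cand <- cand[order(genes$gene_id[cand])]
      }
    }
    gi <- cand[1]
    g <- genes[gi, ]
    bm <- base_maps[[gi]]
    category <- if (p >= g$start && p < g$end) {
      bm$body[p - g$start + 1]
    } else if (p %in% bm$promoter) {
      "promoter"
    } else if (p %in% bm$tts) {
      "tts"
    } else {
      "intergenic"
    }
    signed <- if (g$strand == "+") p - g$tss else g$tss - p
    list(gene_id = g$gene_id, category = category, distance = signed)
  })
  tibble(
    gene_id = sapply(out, `[[`, "gene_id"),
    category = sapply(out, `[[`, "category"),
    distance_to_tss = sapply(out, `[[`, "distance")
  )
}

# ---- naive enrichment oracle -------------------------------------------
# Plain-loop recomputation of per-window ratios, thresholding and
# adjacent-window merging.
oracle_enrich <- function(treatment, control, lib_t, lib_c,
                          min_log2 = 1, pseudocount = 0.5) {
  keep <- integer(0)
  for (i in seq_len(nrow(treatment))) {
    rt <- treatment$count[i] * 1e6 / lib_t
    rc <- control$count[i] * 1e6 / lib_c
    if (log2((rt + pseudocount) / (rc + pseudocount)) >= min_log2) {
      keep <- c(keep, i)
    }
  }
  if (length(keep) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      log2_ratio = numeric()
    ))
  }
  runs <- list()
  cur <- keep[1]
  run <- c(cur)
  for (i in keep[-1]) {
    contiguous <- treatment$chrom[i] == treatment$chrom[cur] &&
      treatment$start[i] == treatment$end[cur]
    if (contiguous) {
      run <- c(run, i)
    } else {
      runs[[length(runs) + 1]] <- run
      run <- c(i)
    }
    cur <- i
  }
  runs[[length(runs) + 1]] <- run
  do.call(rbind, lapply(runs, function(r) {
    ct <- sum(treatment$count[r])
    cc <- sum(control$count[r])
    rt <- ct * 1e6 / lib_t
    rc <- cc * 1e6 / lib_c
    tibble(
      chrom = treatment$chrom[r[1]],
      start = min(treatment$start[r]),
      end = max(treatment$end[r]),
      log2_ratio = log2((rt + pseudocount) / (rc + pseudocount))
    )
  }))
}

# ---- Welch test oracle --------------------------------------------------
# Closed-form Welch t on log2(x + 1), two-sided, Welch-Satterthwaite df.
oracle_welch_p <- function(x, y) {
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  v1 <- var(lx) / length(lx)
  v2 <- var(ly) / length(ly)
  t <- (mean(lx) - mean(ly)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(lx) - 1) + v2^2 / (length(ly) - 1))
  2 * pt(-abs(t), df)
}

# ---- hypergeometric upper-tail oracle ----------------------------------
# Direct summation of the probability mass with choose().
oracle_hyper_upper <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ---- DAG reachability oracle -------------------------------------------
# Transitive closure by repeated boolean squaring of the adjacency matrix.
oracle_closure <- function(edges, nodes) {
  A <- matrix(FALSE, length(nodes), length(nodes),
    dimnames = list(nodes, nodes)
  )
  A[cbind(edges$term_id, edges$parent_id)] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  idx <- which(R, arr.ind = TRUE)
  tibble(
    term_id = nodes[idx[, 1]],
    ancestor_id = nodes[idx[, 2]]
  ) |>
    arrange(term_id, ancestor_id)
}

# ---- small simulation shortcut -----------------------------------------
small_config <- function(...) {
  sim_config(n_genes = 60, n_chromosomes = 2, ...)
}
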