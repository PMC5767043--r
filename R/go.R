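#' Read a two-column gene-to-GO-term annotation table
#'
#' @param path Path to a headerless, tab-separated file with gene id and
#'   term id columns (lines starting with `!` or `#` are skipped).
#' @return Tibble `gene_id`, `term_id`, distinct rows.
#' @export
read_gene2go <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("gene_id", "term_id"),
    col_types = "cc", comment = "!"
  ) |>
    filter(!startsWith(.data$gene_id, "#")) |>
    distinct()
}

#' Read gene-to-term pairs from a GAF 2.x file
#'
#' Uses the standard Gene Association File layout: column 2 (DB object id)
#' and column 5 (GO id). Header lines starting with `!` are skipped.
#'
#' @param path Path to a GAF 2.x file.
#' @return Tibble `gene_id`, `term_id`, distinct rows.
#' @export
read_gaf <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "!"
  )
  if (ncol(raw) < 5) {
    stop_tf("GAF file has fewer than 5 columns")
  }
  tibble(gene_id = raw[[2]], term_id = raw[[5]]) |> distinct()
}

#' Read term metadata and is_a edges from an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a` lines;
#' obsolete terms are dropped.
#'
#' @param path Path to an OBO 1.2 file.
#' @return List with `terms` (tibble `term_id`, `name`, `namespace`) and
#'   `edges` (tibble `term_id`, `parent_id`; one row per is_a edge).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1]] <<- tibble(
        term_id = cur$id,
        name = cur$name %||% NA_character_,
        namespace = cur$namespace %||% NA_character_
      )
      for (p in cur$parents) {
        edges[[length(edges) + 1]] <<- tibble(
          term_id = cur$id, parent_id = p
        )
      }
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- stringr::str_trim(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (startsWith(ln, "[")) {
      flush()
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && !is.null(cur)) {
      if (startsWith(ln, "id: ")) cur$id <- substring(ln, 5)
      if (startsWith(ln, "name: ")) cur$name <- substring(ln, 7)
      if (startsWith(ln, "namespace: ")) cur$namespace <- substring(ln, 12)
      if (startsWith(ln, "is_obsolete: true")) cur$obsolete <- TRUE
      if (startsWith(ln, "is_a: ")) {
        parent <- stringr::str_trim(
          strsplit(substring(ln, 7), "!", fixed = TRUE)[[1]][1]
        )
        cur$parents <- c(cur$parents, parent)
      }
    }
  }
  flush()
  list(
    terms = if (length(terms)) purrr::list_rbind(terms) else
      tibble(term_id = character(), name = character(),
             namespace = character()),
    edges = if (length(edges)) purrr::list_rbind(edges) else
      tibble(term_id = character(), parent_id = character())
  )
}

#' Propagate gene annotations to is_a ancestors
#'
#' Expands each gene's direct terms to the full is_a ancestor closure
#' (the convention of GO term-enrichment tools: a gene annotated to a term
#' is implicitly annotated to every ancestor). Idempotent. The is_a graph
#' must be acyclic; a cycle raises an error naming an edge on the cycle.
#'
#' @param gene2go Tibble `gene_id`, `term_id` of direct annotations.
#' @param edges Tibble `term_id`, `parent_id` of is_a edges (e.g. from
#'   [read_obo()]).
#' @return Tibble `gene_id`, `term_id` including all ancestor
#'   annotations, distinct and sorted.
#' @export
propagate_annotations <- function(gene2go, edges) {
  if (nrow(edges) == 0) {
    return(gene2go |> distinct() |> arrange(.data$gene_id, .data$term_id))
  }
  anc <- ancestor_closure(edges)
  extra <- gene2go |>
    inner_join(anc, by = "term_id", relationship = "many-to-many") |>
    transmute(gene_id = .data$gene_id, term_id = .data$ancestor_id)
  bind_rows(gene2go, extra) |>
    distinct() |>
    arrange(.data$gene_id, .data$term_id)
}

# Transitive closure of is_a edges via Kahn topological order; errors on a
# cycle, naming one edge inside it.
ancestor_closure <- function(edges) {
  nodes <- unique(c(edges$term_id, edges$parent_id))
  parents <- split(edges$parent_id, factor(edges$term_id, levels = nodes))
  # out-degree here = number of is_a parents not yet processed
  remaining <- purrr::map_int(parents, length)
  order <- character(0)
  ready <- nodes[remaining == 0]
  remaining <- setNames(as.integer(remaining), nodes)
  children <- split(edges$term_id, factor(edges$parent_id, levels = nodes))
  while (length(ready) > 0) {
    nd <- ready[1]
    ready <- ready[-1]
    order <- c(order, nd)
    for (ch in children[[nd]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < length(nodes)) {
    stuck <- nodes[remaining[nodes] > 0][1]
    bad <- edges |> filter(.data$term_id == stuck)
    stop_tf(
      "is_a graph contains a cycle through edge ",
      bad$term_id[1], " is_a ", bad$parent_id[1]
    )
  }
  anc <- setNames(vector("list", length(nodes)), nodes)
  for (nd in order) {
    ps <- parents[[nd]]
    anc[[nd]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  tibble(
    term_id = rep(names(anc), lengths(anc)),
    ancestor_id = unlist(anc, use.names = FALSE)
  )
}

#' Singular enrichment analysis (SEA) of a study gene set
#'
#' For every term annotating at least `min_term_size` population genes,
#' tests over-representation in the study set with the hypergeometric
#' upper tail `P(X >= k)` where `k` = study genes with the term, `n` =
#' study size, `K` = population genes with the term, `N` = population
#' size. P-values are Benjamini-Hochberg adjusted within each namespace
#' family (or globally when no namespace metadata is supplied). Genes
#' without annotation still count toward `N` and `n`.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population gene ids (e.g. all
#'   expressed genes).
#' @param gene2go Tibble `gene_id`, `term_id` (after any propagation).
#' @param term_meta Optional tibble `term_id`, `name`, `namespace`.
#' @param alpha FDR significance threshold (default 0.05).
#' @param min_term_size Minimum `K` for a term to be reported (default 1).
#' @return Tibble of class `tf_sea`, sorted by p-value (ties by term id):
#'   `term_id`, `name`, `namespace`, `k`, `n`, `K`, `N`, `p_value`, `fdr`,
#'   `significant`.
#' @examples
#' g2g <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3"), term_id = "GO:1"
#' )
#' sea(c("g1", "g2"), paste0("g", 1:10), g2g)
#' @export
sea <- function(study, population, gene2go, term_meta = NULL,
                alpha = 0.05, min_term_size = 1) {
  study <- unique(study)
  population <- unique(population)
  off <- setdiff(study, population)
  if (length(off) > 0) {
    stop_tf(
      "study genes absent from population: ",
      paste(head(off, 5), collapse = ", ")
    )
  }
  empty <- tibble(
    term_id = character(), name = character(), namespace = character(),
    k = integer(), n = integer(), K = integer(), N = integer(),
    p_value = numeric(), fdr = numeric(), significant = logical()
  )
  if (length(study) == 0) {
    return(new_tf_sea(empty, alpha))
  }
  ann <- gene2go |>
    filter(.data$gene_id %in% population) |>
    distinct(.data$gene_id, .data$term_id)
  if (nrow(ann) == 0) {
    return(new_tf_sea(empty, alpha))
  }
  counts <- ann |>
    group_by(.data$term_id) |>
    summarise(
      K = n(),
      k = sum(.data$gene_id %in% study),
      .groups = "drop"
    ) |>
    filter(.data$K >= min_term_size)
  N <- length(population)
  n <- length(study)
  res <- counts |>
    mutate(
      n = n, N = N,
      p_value = stats::phyper(
        .data$k - 1, .data$K, N - .data$K, n,
        lower.tail = FALSE
      )
    )
  if (!is.null(term_meta)) {
    res <- res |>
      left_join(
        term_meta |> distinct(.data$term_id, .keep_all = TRUE),
        by = "term_id"
      )
    if (!"name" %in% names(res)) res$name <- NA_character_
    if (!"namespace" %in% names(res)) res$namespace <- NA_character_
  } else {
    res$name <- NA_character_
    res$namespace <- NA_character_
  }
  res <- res |>
    mutate(family = ifelse(
      is.na(.data$namespace), "all", .data$namespace
    )) |>
    group_by(.data$family) |>
    mutate(fdr = stats::p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$fdr < alpha) |>
    select(
      "term_id", "name", "namespace", "k", "n", "K", "N",
      "p_value", "fdr", "significant"
    ) |>
    arrange(.data$p_value, .data$term_id)
  new_tf_sea(res, alpha)
}

new_tf_sea <- function(x, alpha) {
  attr(x, "alpha") <- alpha
  class(x) <- c("tf_sea", class(x))
  x
}

#' @export
tidy.tf_sea <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.tf_sea <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}
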