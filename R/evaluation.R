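# Validation statistics: novel gene pairs against size-matched random
# controls (one-sided KS), over-representation comparison, pair-evidence
# handling.

# canonical unordered-pair keys for sorted-unique gene vectors
set_pair_keys <- function(genes) {
  genes <- sort(unique(genes))
  if (length(genes) < 2) return(character(0))
  p <- combn(genes, 2)
  paste(p[1, ], p[2, ], sep = "\x1f")
}

#' Gene pairs connected only by consolidation
#'
#' Unordered gene pairs that co-occur in at least one SuperPath gene union
#' but in no single pathway of the collection — the new gene partnerships
#' created by merging pathways into SuperPaths.
#'
#' @param clustering A [build_superpaths()] result (carries its collection).
#' @return A tibble with columns `gene_a` < `gene_b`, sorted.
#' @export
novel_gene_pairs <- function(clustering) {
  multi <- clustering$superpaths[clustering$superpaths$n_members >= 2, ]
  sp_keys <- unique(unlist(lapply(multi$genes, set_pair_keys)))
  if (length(sp_keys) == 0) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  path_keys <- unique(unlist(lapply(clustering$collection$genes, set_pair_keys)))
  novel <- sort(setdiff(sp_keys, path_keys))
  parts <- strsplit(novel, "\x1f", fixed = TRUE)
  tibble(
    gene_a = vapply(parts, `[[`, character(1), 1),
    gene_b = vapply(parts, `[[`, character(1), 2)
  )
}

#' Size-matched random control clusters (pseudo-SuperPaths)
#'
#' For every real SuperPath, draws a random gene set of the same size from
#' the annotated universe, and mirrors the internal pathway structure by
#' resampling each member pathway's gene count within the pseudo-set. The
#' result supports [novel_gene_pairs()] so that SuperPath-specific pairs can
#' be benchmarked against chance.
#'
#' @param clustering A [build_superpaths()] result.
#' @param universe Genes to sample from; defaults to the collection's
#'   universe (all genes with any pathway annotation). Must be at least as
#'   large as the largest SuperPath gene union.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A `superpath_clustering` whose SuperPath unions and member
#'   pathway gene sets are randomized but exactly size-matched.
#' @export
pseudo_superpaths <- function(clustering, universe = NULL, seed = 1) {
  if (is.null(universe)) universe <- gene_universe(clustering$collection)
  max_size <- max(clustering$superpaths$n_genes)
  if (length(universe) < max_size) {
    abort("universe smaller than the largest SuperPath gene union")
  }
  withr::local_seed(seed)
  coll <- clustering$collection
  sp_of <- setNames(clustering$membership$superpath_id,
                    clustering$membership$pathway_id)
  pseudo_unions <- lapply(clustering$superpaths$n_genes,
                          function(k) sample(universe, k))
  names(pseudo_unions) <- clustering$superpaths$superpath_id
  pseudo_genes <- lapply(seq_len(nrow(coll)), function(i) {
    pool <- pseudo_unions[[sp_of[[coll$pathway_id[i]]]]]
    sample(pool, length(coll$genes[[i]]))
  })
  pseudo_coll <- pathway_collection(tibble(
    pathway_id = coll$pathway_id,
    source = coll$source,
    name = coll$name,
    genes = pseudo_genes
  ))
  out <- clustering
  out$collection <- pseudo_coll
  out$superpaths$genes <- lapply(unname(pseudo_unions), sort)
  out$edge_log <- clustering$edge_log[0, ]
  out
}

#' One-sided comparison of test and control evidence distributions
#'
#' Downsamples the control to the test size (without replacement, seeded),
#' then tests whether the test values are stochastically greater than the
#' control with a one-sided two-sample Kolmogorov-Smirnov test. Also
#' reports per-bin test/control count ratios, with a pseudo-count of 1
#' substituted for empty control bins.
#'
#' @param test,control Non-empty numeric vectors; `control` must be at least
#'   as long as `test`.
#' @param seed Integer seed for the control downsampling.
#' @param breaks Histogram breaks for the fold-ratio readout; defaults to
#'   width-10 bins for count-like data (max > 1) and width-0.1 bins for
#'   score-like data in \[0, 1\].
#' @return An object of class `ks_comparison`: a list with `statistic`,
#'   `p_value` (one-sided, "test greater"), `n`, and `bins` (tibble: `bin`,
#'   `test_count`, `control_count`, `ratio`).
#' @export
ks_compare <- function(test, control, seed = 1, breaks = NULL) {
  if (length(test) == 0 || length(control) == 0) {
    abort("test and control must be non-empty")
  }
  if (length(control) < length(test)) {
    abort("control must be at least as large as the test set")
  }
  withr::local_seed(seed)
  control <- sample(control, length(test))
  # R's convention: alternative = "less" <=> CDF(test) below CDF(control)
  # <=> test stochastically greater (checked by simulation)
  ks <- suppressWarnings(ks.test(test, control, alternative = "less"))
  p <- max(unname(ks$p.value), .Machine$double.xmin)

  if (is.null(breaks)) {
    top <- max(test, control)
    breaks <- if (top > 1) {
      seq(0, 10 * ceiling(top / 10), by = 10)
    } else {
      seq(0, 1, by = 0.1)
    }
  }
  tc <- table(cut(test, breaks, include.lowest = TRUE))
  cc <- table(cut(control, breaks, include.lowest = TRUE))
  bins <- tibble(
    bin = names(tc),
    test_count = as.integer(tc),
    control_count = as.integer(cc),
    ratio = as.integer(tc) / pmax(as.integer(cc), 1L)
  )
  structure(
    list(statistic = unname(ks$statistic), p_value = p,
         n = length(test), bins = bins),
    class = "ks_comparison"
  )
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf(
    "One-sided KS (test > control): D = %.4f, p = %.3g, n = %d per group\n",
    x$statistic, x$p_value, x$n
  ))
  nonzero <- x$bins[x$bins$test_count > 0 | x$bins$control_count > 0, ]
  print(as.data.frame(nonzero), row.names = FALSE)
  invisible(x)
}

#' Over-representation p-value (hypergeometric upper tail)
#'
#' Probability of observing at least the actual query/target overlap when
#' drawing `|query|` genes at random from the universe.
#'
#' @param query,target Non-empty gene sets, both subsets of `universe`.
#' @param universe The annotated gene universe.
#' @return A p-value in (0, 1\].
#' @export
ora_pvalue <- function(query, target, universe) {
  query <- unique(query)
  target <- unique(target)
  universe <- unique(universe)
  if (length(query) == 0 || length(target) == 0 || length(universe) == 0) {
    abort("query, target and universe must be non-empty")
  }
  if (length(setdiff(query, universe)) > 0 || length(setdiff(target, universe)) > 0) {
    abort("query and target must be subsets of the universe")
  }
  k <- length(intersect(query, target))
  phyper(k - 1, length(target), length(universe) - length(target),
         length(query), lower.tail = FALSE)
}

#' SuperPaths with exactly two dissimilar member pathways
#'
#' The comparison cohort for the enrichment analysis: SuperPaths built from
#' exactly two pathways whose pairwise Jaccard similarity is below `j_max`
#' (relatively dissimilar constituents give the union room to outperform).
#'
#' @param clustering A [build_superpaths()] result.
#' @param j_max Upper bound (exclusive) on the member-pair Jaccard.
#' @return Character vector of SuperPath ids.
#' @export
comparison_cohort <- function(clustering, j_max = 0.6) {
  two <- clustering$superpaths[clustering$superpaths$n_members == 2, ]
  if (nrow(two) == 0) return(character(0))
  coll <- clustering$collection
  genes_of <- setNames(coll$genes, coll$pathway_id)
  sp_of <- split(clustering$membership$pathway_id,
                 clustering$membership$superpath_id)
  keep <- vapply(two$superpath_id, function(sid) {
    m <- sp_of[[sid]]
    jaccard(genes_of[[m[1]]], genes_of[[m[2]]]) < j_max
  }, logical(1))
  two$superpath_id[keep]
}

#' Enrichment advantage of SuperPaths over their constituent pathways
#'
#' For each query gene set and each selected SuperPath, scores the SuperPath
#' union and every member pathway by [ora_pvalue()] and reports
#' `delta = (-log10 p_superpath) - mean(-log10 p_member)`: positive when the
#' consolidated gene set is the more significant annotation.
#'
#' @param clustering A [build_superpaths()] result.
#' @param query_sets Query gene sets: a named list of character vectors, or
#'   a tibble with columns `query_id` and `genes` (as produced by
#'   [generate_query_sets()]).
#' @param universe Annotated gene universe; defaults to the collection's.
#'   Queries must be subsets of it.
#' @param superpath_ids SuperPaths to score; defaults to all with at least
#'   two members.
#' @return A tibble with columns `superpath_id`, `query_id`, `p_superpath`,
#'   `mean_neglog10_members`, `delta`.
#' @export
enrichment_delta <- function(clustering, query_sets, universe = NULL,
                             superpath_ids = NULL) {
  if (is.data.frame(query_sets)) {
    query_sets <- setNames(query_sets$genes, query_sets$query_id)
  }
  if (is.null(universe)) universe <- gene_universe(clustering$collection)
  sp <- clustering$superpaths
  if (is.null(superpath_ids)) {
    superpath_ids <- sp$superpath_id[sp$n_members >= 2]
  }
  coll <- clustering$collection
  genes_of <- setNames(coll$genes, coll$pathway_id)
  members_of <- split(clustering$membership$pathway_id,
                      clustering$membership$superpath_id)
  unions <- setNames(sp$genes, sp$superpath_id)
  rows <- list()
  for (sid in superpath_ids) {
    if (length(members_of[[sid]]) < 2) {
      abort(sprintf("SuperPath %s has fewer than 2 members", sid))
    }
    for (q in names(query_sets)) {
      query <- query_sets[[q]]
      p_sp <- ora_pvalue(query, unions[[sid]], universe)
      p_mem <- vapply(members_of[[sid]],
                      function(m) ora_pvalue(query, genes_of[[m]], universe),
                      double(1))
      rows[[length(rows) + 1]] <- tibble(
        superpath_id = sid, query_id = q,
        p_superpath = p_sp,
        mean_neglog10_members = mean(-log10(p_mem)),
        delta = -log10(p_sp) - mean(-log10(p_mem))
      )
    }
  }
  bind_rows(rows)
}

#' Read a pair-evidence table
#'
#' Tab-separated `gene_a`, `gene_b`, `value` with a `# type: <type>` header
#' line declaring whether values are shared-publication counts or PPI
#' scores. Pairs absent from the table score 0.
#'
#' @param path Path to an evidence file.
#' @return A tibble of class `pair_evidence` with attribute `type`.
#' @export
read_pair_evidence <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  type <- if (grepl("^#\\s*type:", first)) {
    trimws(sub("^#\\s*type:", "", first))
  } else {
    "unknown"
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ev <- as_tibble(df[c("gene_a", "gene_b", "value")])
  attr(ev, "type") <- type
  class(ev) <- c("pair_evidence", class(ev))
  ev
}

#' Write a pair-evidence table
#'
#' @param evidence A tibble with columns `gene_a`, `gene_b`, `value`.
#' @param path Output file path.
#' @param type Declared evidence type (e.g. `"publications"`, `"ppi"`);
#'   defaults to the tibble's own `type` attribute.
#' @return `path`, invisibly.
#' @export
write_pair_evidence <- function(evidence, path, type = NULL) {
  if (is.null(type)) type <- attr(evidence, "type") %||% "unknown"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# type: ", type), con)
  utils::write.table(
    as.data.frame(evidence[c("gene_a", "gene_b", "value")]),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Look up evidence values for gene pairs
#'
#' Symmetric access: pair order does not matter, and pairs absent from the
#' evidence table score 0.
#'
#' @param evidence A [read_pair_evidence()] tibble (columns `gene_a`,
#'   `gene_b`, `value`).
#' @param pairs A tibble with columns `gene_a`, `gene_b`.
#' @return Numeric vector of values, one per row of `pairs`.
#' @export
evidence_values <- function(evidence, pairs) {
  ev_key <- paste(pmin(evidence$gene_a, evidence$gene_b),
                  pmax(evidence$gene_a, evidence$gene_b), sep = "\x1f")
  q_key <- paste(pmin(pairs$gene_a, pairs$gene_b),
                 pmax(pairs$gene_a, pairs$gene_b), sep = "\x1f")
  v <- evidence$value[match(q_key, ev_key)]
  v[is.na(v)] <- 0
  v
}

#' Test SuperPath-specific gene pairs against random controls
#'
#' The end-to-end Fig-6-style readout: extracts the gene pairs connected
#' only by consolidation ([novel_gene_pairs()]), builds size-matched
#' pseudo-SuperPath controls ([pseudo_superpaths()]) and their own novel
#' pairs, looks both sets up in a pair-evidence table (absent pairs score
#' 0), and runs the one-sided KS comparison ([ks_compare()]).
#'
#' @param clustering A [build_superpaths()] result.
#' @param evidence A `pair_evidence` tibble.
#' @param seed Integer seed (drives the pseudo-set sampling and the control
#'   downsampling).
#' @param universe Universe for the pseudo-sets; defaults to the
#'   collection's annotated genes.
#' @return A `ks_comparison` object (see [ks_compare()]).
#' @export
evidence_enrichment_test <- function(clustering, evidence, seed = 1,
                                     universe = NULL) {
  test_pairs <- novel_gene_pairs(clustering)
  pseudo <- pseudo_superpaths(clustering, universe = universe, seed = seed)
  control_pairs <- novel_gene_pairs(pseudo)
  if (nrow(test_pairs) == 0 || nrow(control_pairs) == 0) {
    abort("no novel gene pairs in test or control clustering")
  }
  test_vals <- evidence_values(evidence, test_pairs)
  control_vals <- evidence_values(evidence, control_pairs)
  # the KS comparison downsizes the larger set to the smaller; pseudo-sets
  # mirror real sizes closely, so either side may come out larger
  if (length(test_vals) > length(control_vals)) {
    withr::local_seed(seed + 2L)
    test_vals <- sample(test_vals, length(control_vals))
  }
  ks_compare(test_vals, control_vals, seed = seed + 1L)
}
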