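#' Jaccard similarity of two gene sets
#'
#' Size of the intersection divided by the size of the union. Equals 1 iff
#' the sets are equal, 0 iff they are disjoint.
#'
#' @param a,b Non-empty character vectors of gene symbols.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("jaccard is undefined for empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Containment of a small gene set in a larger one
#'
#' Overlap divided by the size of the first (smaller) set; drives the
#' small-pathway absorption preprocessing.
#'
#' @param small Non-empty character vector (the reference set).
#' @param large Character vector.
#' @return Fraction of `small` contained in `large`, in \[0, 1\].
#' @export
containment <- function(small, large) {
  small <- unique(small)
  if (length(small) == 0) abort("containment is undefined for an empty reference set")
  length(intersect(small, large)) / length(small)
}

# Overlapping pathway pairs via an inverted gene -> pathway index; disjoint
# pairs are never enumerated. Returns row indices i < j plus intersection
# size n_common.
pair_overlaps <- function(collection) {
  long <- tibble(
    i = rep.int(seq_len(nrow(collection)), lengths(collection$genes)),
    gene = unlist(collection$genes, use.names = FALSE)
  )
  inner_join(long, long, by = "gene", relationship = "many-to-many") %>%
    filter(.data$i.x < .data$i.y) %>%
    count(i = .data$i.x, j = .data$i.y, name = "n_common")
}

#' Sparse pathway-pathway Jaccard similarity graph
#'
#' Edges for exactly the pathway pairs with Jaccard similarity at or above
#' `j_min`, built via an inverted gene-to-pathway index so that disjoint
#' pairs are never enumerated.
#'
#' @param collection A [pathway_collection()].
#' @param j_min Storage threshold in (0, 1].
#' @return A tibble of class `similarity_graph` with columns `from`, `to`
#'   (pathway ids, `from` < `to`) and `jaccard`, sorted lexicographically;
#'   attributes `j_min` and `nodes` (all pathway ids, including isolated
#'   ones).
#' @export
pairwise_graph <- function(collection, j_min = 0.05) {
  if (!is.numeric(j_min) || j_min <= 0 || j_min > 1) {
    abort("j_min must be in (0, 1]")
  }
  sizes <- lengths(collection$genes)
  ids <- collection$pathway_id
  ov <- pair_overlaps(collection)
  jac <- ov$n_common / (sizes[ov$i] + sizes[ov$j] - ov$n_common)
  keep <- jac >= j_min
  # row order i < j does not imply id order; canonicalize to from < to
  ia <- ids[ov$i[keep]]
  ib <- ids[ov$j[keep]]
  edges <- tibble(
    from = pmin(ia, ib),
    to = pmax(ia, ib),
    jaccard = jac[keep]
  ) %>%
    arrange(.data$from, .data$to)
  attr(edges, "j_min") <- j_min
  attr(edges, "nodes") <- ids
  class(edges) <- c("similarity_graph", class(edges))
  edges
}

#' Write a similarity graph as a tab-separated edge list
#'
#' Columns `from`, `to`, `jaccard` with a header row, rows in deterministic
#' lexicographic pair order.
#'
#' @param graph A [pairwise_graph()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  utils::write.table(
    as.data.frame(graph[order(graph$from, graph$to), c("from", "to", "jaccard")]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Name-versus-gene-content concordance over all pathway pairs
#'
#' Classifies every unordered pathway pair by whether its stemmed-name
#' Jaccard similarity and its gene-content Jaccard similarity reach the
#' respective cutoffs, and tabulates the 2x2 contingency, mirroring the
#' observation that similarly named pathways frequently differ in content
#' and vice versa.
#'
#' @param collection A [pathway_collection()].
#' @param name_cutoff,gene_cutoff Similarity cutoffs in (0, 1] (default 0.5).
#' @param stopwords Passed to [tokenize_name()].
#' @return An object of class `contingency_2x2`: a list with `counts`
#'   (2x2 matrix), `rates` (the two concordance percentages, see
#'   [concordance_rates()]), `n_pairs` and the cutoffs used.
#' @export
name_content_contingency <- function(collection,
                                     name_cutoff = 0.5,
                                     gene_cutoff = 0.5,
                                     stopwords = default_stopwords()) {
  if (name_cutoff <= 0 || name_cutoff > 1 || gene_cutoff <= 0 || gene_cutoff > 1) {
    abort("cutoffs must be in (0, 1]")
  }
  n <- nrow(collection)
  n_pairs <- n * (n - 1) / 2
  gene_pairs <- pairwise_graph(collection, j_min = gene_cutoff)
  gene_keys <- paste(gene_pairs$from, gene_pairs$to, sep = "\x1f")

  tokens <- lapply(collection$name, tokenize_name, stopwords = stopwords)
  tok_coll <- tibble(
    pathway_id = collection$pathway_id, source = collection$source,
    name = collection$name, genes = tokens
  )
  nonempty <- tok_coll[lengths(tokens) > 0, ]
  name_keys <- character(0)
  if (nrow(nonempty) > 1) {
    # reuse the sparse inverted-index machinery on token sets
    sizes <- lengths(nonempty$genes)
    ov <- pair_overlaps(nonempty)
    jac <- ov$n_common / (sizes[ov$i] + sizes[ov$j] - ov$n_common)
    keep <- jac >= name_cutoff
    ia <- nonempty$pathway_id[ov$i[keep]]
    ib <- nonempty$pathway_id[ov$j[keep]]
    name_keys <- paste(pmin(ia, ib), pmax(ia, ib), sep = "\x1f")
  }

  both <- sum(name_keys %in% gene_keys)
  counts <- matrix(
    c(both, length(name_keys) - both,
      length(gene_keys) - both,
      n_pairs - length(name_keys) - length(gene_keys) + both),
    nrow = 2,
    dimnames = list(
      name = c("similar_name", "non_similar_name"),
      genes = c("similar_genes", "non_similar_genes")
    )
  )
  structure(
    list(
      counts = counts,
      rates = concordance_rates(
        n_both = counts["similar_name", "similar_genes"],
        n_name_only = counts["similar_name", "non_similar_genes"],
        n_genes_only = counts["non_similar_name", "similar_genes"]
      ),
      n_pairs = n_pairs,
      name_cutoff = name_cutoff,
      gene_cutoff = gene_cutoff
    ),
    class = "contingency_2x2"
  )
}

#' Concordance percentages from 2x2 name/content counts
#'
#' From the counts of pathway pairs that are similar in both name and gene
#' content, similar in name only, and similar in gene content only, computes
#' the percentage of similar-name pairs that also have similar gene content
#' and the percentage of similar-gene pairs that also have similar names.
#'
#' @param n_both Pairs similar in both name and gene content.
#' @param n_name_only Pairs similar in name but not gene content.
#' @param n_genes_only Pairs similar in gene content but not name.
#' @return A tibble with columns `pct_similar_name_with_similar_genes` and
#'   `pct_similar_genes_with_similar_name` (percentages; `NA` when the
#'   corresponding margin is empty).
#' @export
#' @examples
#' concordance_rates(n_both = 414, n_name_only = 3991, n_genes_only = 3782)
concordance_rates <- function(n_both, n_name_only, n_genes_only) {
  name_margin <- n_both + n_name_only
  gene_margin <- n_both + n_genes_only
  tibble(
    pct_similar_name_with_similar_genes =
      if (name_margin > 0) 100 * n_both / name_margin else NA_real_,
    pct_similar_genes_with_similar_name =
      if (gene_margin > 0) 100 * n_both / gene_margin else NA_real_
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf(
    "Name/content concordance over %d pathway pairs (name >= %.2f, genes >= %.2f)\n",
    x$n_pairs, x$name_cutoff, x$gene_cutoff
  ))
  print(x$counts)
  cat(sprintf(
    "similar-name pairs with similar genes: %.1f%%\nsimilar-gene pairs with similar name: %.1f%%\n",
    x$rates$pct_similar_name_with_similar_genes,
    x$rates$pct_similar_genes_with_similar_name
  ))
  invisible(x)
}
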