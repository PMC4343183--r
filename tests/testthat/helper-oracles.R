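# Fixture builders and independent brute-force oracles used across the suite.

g_ids <- function(i) sprintf("g%03d", i)

# collection from a named list of gene vectors
make_coll <- function(sets, sources = NULL, names = NULL) {
  ids <- names(sets) %||% character(0)
  pathway_collection(tibble::tibble(
    pathway_id = ids,
    source = sources %||% rep("S1", length(sets)),
    name = names %||% (if (length(ids)) paste("pathway", ids) else character(0)),
    genes = unname(sets)
  ))
}

random_collection <- function(n, universe_size = 60, size_range = c(3, 12),
                              seed = 1) {
  withr::local_seed(seed)
  universe <- g_ids(seq_len(universe_size))
  sets <- lapply(seq_len(n), function(i) {
    sample(universe, sample(size_range[1]:size_range[2], 1))
  })
  names(sets) <- sprintf("P%02d", seq_len(n))
  make_coll(sets, sources = sample(c("A", "B", "C"), n, replace = TRUE))
}

# O(n^2) all-pairs Jaccard edge list
bf_jaccard_edges <- function(coll, j_min) {
  out <- list()
  n <- nrow(coll)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jc <- length(intersect(coll$genes[[i]], coll$genes[[j]])) /
        length(union(coll$genes[[i]], coll$genes[[j]]))
      if (jc >= j_min) {
        a <- sort(c(coll$pathway_id[i], coll$pathway_id[j]))
        out[[length(out) + 1]] <- tibble::tibble(from = a[1], to = a[2], jaccard = jc)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(from = character(), to = character(), jaccard = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), from, to)
}

# hand-written union-find over an edge list; returns a canonical partition
# (sorted list of sorted member vectors)
bf_union_find <- function(ids, from, to) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k])
    rb <- find(to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  canon_partition(split(ids, roots))
}

canon_partition <- function(groups) {
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, `[[`, character(1), 1))]
}

partition_of <- function(clustering) {
  canon_partition(split(clustering$membership$pathway_id,
                        clustering$membership$superpath_id))
}

# the full edge list build_superpaths is defined over, assembled from the
# exported stage functions (used to feed the union-find oracle)
staged_edges <- function(coll, t1, t2) {
  gr <- pairwise_graph(coll, j_min = min(t1, 0.999))
  ab <- preprocess_absorption(coll)
  idg <- identical_groups(coll)
  id_edges <- do.call(rbind, lapply(idg[lengths(idg) >= 2], function(g) {
    cbind(g[-length(g)], g[-1])
  }))
  core <- core_edges(gr, t2)
  best <- best_neighbor_edges(gr, t1)
  list(
    from = c(ab$small, id_edges[, 1], core$from, best$from),
    to = c(ab$large, id_edges[, 2], core$to, best$to)
  )
}

# direct-summation evaluation of uniqueness/informativeness from cluster
# gene unions (explicit loops, no shared code with the implementation)
bf_u_i <- function(unions) {
  all_genes <- unique(unlist(unions))
  n_sp <- vapply(all_genes, function(g) {
    sum(vapply(unions, function(u) g %in% u, logical(1)))
  }, double(1))
  u <- vapply(unions, function(u) {
    log10(sum(1 / n_sp[u]) / length(u))
  }, double(1))
  i <- vapply(all_genes, function(g) {
    sizes <- lengths(unions)[vapply(unions, function(u) g %in% u, logical(1))]
    log10(sum(1 / sizes) / length(sizes))
  }, double(1))
  list(u = u, i = i, u_s = mean(u), i_s = mean(i))
}

# minimal clustering object from a collection plus a label vector (named by
# pathway id), for exercising the scoring functions on hand-made partitions
fake_clustering <- function(coll, labels) {
  members <- split(coll$pathway_id, labels[coll$pathway_id])
  unions <- lapply(members, function(m) {
    sort(unique(unlist(coll$genes[match(m, coll$pathway_id)])))
  })
  sp_ids <- sprintf("SP%04d", seq_along(members))
  structure(
    list(
      superpaths = tibble::tibble(
        superpath_id = sp_ids,
        n_members = lengths(members),
        n_genes = lengths(unions),
        genes = unname(unions)
      ),
      membership = tibble::tibble(
        pathway_id = unlist(members, use.names = FALSE),
        superpath_id = rep(sp_ids, lengths(members))
      ),
      edge_log = tibble::tibble(from = character(), to = character(),
                                weight = double(), type = character()),
      t1 = NA_real_, t2 = NA_real_,
      params = list(),
      collection = coll
    ),
    class = "superpath_clustering"
  )
}

# adjusted Rand index between a clustering and the planted truth (noise
# pathways count as their own singleton classes)
planted_ari <- function(clustering, truth) {
  lab <- truth$pathway_parent$module
  lab[is.na(lab)] <- 10000L + seq_len(sum(is.na(lab)))
  pred <- clustering$membership$superpath_id[
    match(truth$pathway_parent$pathway_id, clustering$membership$pathway_id)
  ]
  mclust::adjustedRandIndex(lab, pred)
}
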