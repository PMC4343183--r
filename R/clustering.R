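# SuperPath construction: two-threshold similarity clustering.
#
# Edges come from four sources and their union's connected components are the
# SuperPaths:
#   - preprocessing: small pathways (< small_max genes) absorbed into larger
#     ones (< large_max genes) that contain >= c_min of them;
#   - identical: pathways with exactly equal gene sets, chained;
#   - core (T2): single-linkage edges for every pair with J >= t2;
#   - best (T1): each pathway joined to its best-scoring non-identical
#     neighbor(s) when that best score is >= t1 (ties all kept).
# The construction is independent of input order.

#' Small-pathway absorption edges
#'
#' Connects each pathway with fewer than `small_max` genes to every larger
#' pathway (at least as many genes, but fewer than `large_max`) that contains
#' at least `c_min` of its genes. Both pathways remain cluster members;
#' absorption adds connectivity, it deletes nothing.
#'
#' @param collection A [pathway_collection()].
#' @param small_max Strict upper size bound for the absorbed pathway.
#' @param large_max Strict upper size bound for the absorbing pathway.
#' @param c_min Minimum containment of the small pathway in the large one.
#' @return A tibble with columns `small`, `large` (pathway ids) and
#'   `containment`.
#' @export
preprocess_absorption <- function(collection, small_max = 20, large_max = 200,
                                  c_min = 0.9) {
  if (c_min <= 0 || c_min > 1) abort("c_min must be in (0, 1]")
  sizes <- lengths(collection$genes)
  ids <- collection$pathway_id
  ov <- pair_overlaps(collection)
  if (nrow(ov) == 0) {
    return(tibble(small = character(), large = character(), containment = double()))
  }
  # orient each overlapping pair as (small, large); equal sizes keep i as small
  swap <- sizes[ov$j] < sizes[ov$i]
  s <- ifelse(swap, ov$j, ov$i)
  l <- ifelse(swap, ov$i, ov$j)
  cont <- ov$n_common / sizes[s]
  keep <- sizes[s] < small_max & sizes[l] < large_max & cont >= c_min
  tibble(small = ids[s[keep]], large = ids[l[keep]], containment = cont[keep]) %>%
    arrange(.data$small, .data$large)
}

#' Group pathways with identical gene sets
#'
#' Partition of pathway ids by exact gene-set equality. Groups of two or more
#' are joined directly during clustering, and their members never count each
#' other as nearest neighbors.
#'
#' @param collection A [pathway_collection()].
#' @return A list of character vectors (each sorted; list ordered by first
#'   id), jointly covering all pathway ids.
#' @export
identical_groups <- function(collection) {
  key <- vapply(
    collection$genes,
    function(g) paste(sort(g), collapse = "\x1f"),
    character(1)
  )
  groups <- split(collection$pathway_id, key)
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, `[[`, character(1), 1))]
}

# spanning chain over each multi-member identical group
identical_edges <- function(groups) {
  multi <- groups[lengths(groups) >= 2]
  if (length(multi) == 0) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  bind_rows(lapply(multi, function(g) {
    tibble(from = g[-length(g)], to = g[-1], weight = 1)
  }))
}

#' Cluster-core edges at the upper threshold
#'
#' All similarity-graph edges with Jaccard weight at or above `t2`
#' (single-linkage style cores).
#'
#' @param graph A [pairwise_graph()] result.
#' @param t2 Upper threshold in (0, 1].
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
core_edges <- function(graph, t2) {
  if (t2 <= 0 || t2 > 1) abort("t2 must be in (0, 1]")
  keep <- graph$jaccard >= t2
  tibble(from = graph$from[keep], to = graph$to[keep], weight = graph$jaccard[keep])
}

#' Best-neighbor edges at the lower threshold
#'
#' For each pathway, finds the maximum Jaccard weight among neighbors whose
#' gene set differs from its own (weight < 1; identical sets are joined
#' separately and never count as nearest neighbors). If that best score is at
#' least `t1`, an edge is emitted to every neighbor achieving it (ties all
#' kept). The result does not depend on pathway order.
#'
#' @param graph A [pairwise_graph()] result; its storage threshold must not
#'   exceed `t1`, or best neighbors could be missed.
#' @param t1 Lower threshold in (0, 1].
#' @return A tibble with columns `from`, `to`, `weight` (unordered pairs,
#'   deduplicated).
#' @export
best_neighbor_edges <- function(graph, t1) {
  if (t1 <= 0 || t1 > 1) abort("t1 must be in (0, 1]")
  jm <- attr(graph, "j_min")
  if (!is.null(jm) && jm > t1) {
    abort("graph storage threshold j_min exceeds t1; rebuild the graph")
  }
  if (nrow(graph) == 0) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  dir <- tibble(
    p = c(graph$from, graph$to),
    q = c(graph$to, graph$from),
    w = rep(graph$jaccard, 2)
  ) %>%
    filter(.data$w < 1)  # J = 1 iff equal gene sets
  if (nrow(dir) == 0) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  dir %>%
    group_by(.data$p) %>%
    filter(.data$w == max(.data$w)) %>%
    ungroup() %>%
    filter(.data$w >= t1) %>%
    mutate(from = pmin(.data$p, .data$q), to = pmax(.data$p, .data$q)) %>%
    distinct(.data$from, .data$to, .keep_all = TRUE) %>%
    select("from", "to", weight = "w") %>%
    arrange(.data$from, .data$to)
}

# Precomputed ingredients shared across many (t1, t2) evaluations of the
# same collection: the similarity graph at the lowest t1 that will be used,
# absorption edges and identical groups.
cluster_parts <- function(collection, j_min, small_max = 20, large_max = 200,
                          c_min = 0.9, absorption = TRUE, graph = NULL) {
  if (is.null(graph)) graph <- pairwise_graph(collection, j_min = j_min)
  list(
    collection = collection,
    ids = collection$pathway_id,
    graph = graph,
    absorption = if (absorption) {
      preprocess_absorption(collection, small_max, large_max, c_min)
    } else {
      tibble(small = character(), large = character(), containment = double())
    },
    identical = identical_edges(identical_groups(collection))
  )
}

# Assemble the full edge log for thresholds (t1, t2), optionally restricted
# to a subset of pathway ids (used by dilution resampling).
assemble_edges <- function(parts, t1, t2, ids_subset = NULL) {
  g <- parts$graph
  ab <- parts$absorption
  idn <- parts$identical
  if (!is.null(ids_subset)) {
    keep_g <- g$from %in% ids_subset & g$to %in% ids_subset
    g <- g[keep_g, , drop = FALSE]
    attr(g, "j_min") <- attr(parts$graph, "j_min")
    ab <- ab[ab$small %in% ids_subset & ab$large %in% ids_subset, , drop = FALSE]
    idn <- idn[idn$from %in% ids_subset & idn$to %in% ids_subset, , drop = FALSE]
  }
  bind_rows(
    if (nrow(ab) > 0) {
      tibble(from = pmin(ab$small, ab$large), to = pmax(ab$small, ab$large),
             weight = ab$containment, type = "preprocessing")
    },
    mutate(idn, type = "identical"),
    mutate(core_edges(g, t2), type = "core"),
    mutate(best_neighbor_edges(g, t1), type = "best")
  )
}

# Connected components over all ids (isolated pathways become singletons);
# returns an integer membership vector named by pathway id.
edge_components <- function(ids, edges) {
  pairs <- distinct(edges[c("from", "to")])
  gr <- igraph::graph_from_data_frame(
    as.data.frame(pairs), directed = FALSE,
    vertices = data.frame(name = ids)
  )
  igraph::components(gr)$membership[ids]
}

# membership vector -> deterministic cluster labels SP0001, SP0002, ...
# ordered by the lexicographically smallest member id
superpath_labels <- function(membership) {
  ids <- names(membership)
  first <- vapply(split(ids, membership), min, character(1))
  rank <- setNames(seq_along(first), names(first)[order(first)])
  lab <- sprintf("SP%04d", rank[as.character(membership)])
  setNames(lab, ids)
}

#' Build SuperPaths from a pathway collection
#'
#' Runs the full two-threshold consolidation: small-pathway absorption,
#' identical-set joining, core edges at `t2`, best-neighbor edges at `t1`,
#' then takes connected components as SuperPaths and names each after its
#' hub (most intra-cluster-connected) pathway. The result is independent of
#' the order of pathways in the input.
#'
#' @param collection A [pathway_collection()].
#' @param t1 Lower (best-neighbor) threshold; must satisfy
#'   `0 < t1 <= t2 <= 1`.
#' @param t2 Upper (core) threshold.
#' @param small_max,large_max,c_min Absorption parameters, see
#'   [preprocess_absorption()].
#' @param absorption Apply the absorption preprocessing?
#' @param hub_edges Which edge types count toward hub degree: `"all"`
#'   (default; preprocessing and identical edges are real co-membership
#'   evidence) or `"similarity"` (core and best edges only).
#' @param graph Optional precomputed [pairwise_graph()] with
#'   `j_min <= t1`; computed from the collection when `NULL`.
#' @return An object of class `superpath_clustering`: a list with
#'   `superpaths` (tibble: `superpath_id`, `hub`, `name`, `n_members`,
#'   `n_genes`, `genes` list-column), `membership` (tibble: `pathway_id`,
#'   `superpath_id`), `edge_log` (tibble: `from`, `to`, `weight`, `type`),
#'   the thresholds, parameters and the input collection.
#' @export
#' @examples
#' coll <- pathway_collection(tibble::tibble(
#'   pathway_id = c("P1", "P2", "P3"),
#'   source = c("A", "B", "C"),
#'   name = c("Glycolysis", "Glycolysis core", "Unrelated"),
#'   genes = list(c("G1", "G2", "G3"), c("G1", "G2", "G4"), c("X1", "X2"))
#' ))
#' build_superpaths(coll, t1 = 0.3, t2 = 0.7)
build_superpaths <- function(collection, t1 = 0.3, t2 = 0.7,
                             small_max = 20, large_max = 200, c_min = 0.9,
                             absorption = TRUE,
                             hub_edges = c("all", "similarity"),
                             graph = NULL) {
  hub_edges <- match.arg(hub_edges)
  if (!is.numeric(t1) || !is.numeric(t2) || t1 <= 0 || t2 > 1 || t1 > t2) {
    abort("thresholds must satisfy 0 < t1 <= t2 <= 1")
  }
  if (nrow(collection) == 0) abort("empty collection")
  if (!is.null(graph) && !is.null(attr(graph, "j_min")) &&
      attr(graph, "j_min") > t1) {
    abort("supplied graph was stored at j_min > t1; rebuild it")
  }
  parts <- cluster_parts(collection, j_min = t1, small_max = small_max,
                         large_max = large_max, c_min = c_min,
                         absorption = absorption, graph = graph)
  edges <- assemble_edges(parts, t1, t2)
  membership <- edge_components(parts$ids, edges)
  labels <- superpath_labels(membership)

  member_split <- split(collection$pathway_id, labels[collection$pathway_id])
  gene_split <- lapply(
    split(collection$genes, labels[collection$pathway_id]),
    function(gs) sort(unique(unlist(gs, use.names = FALSE)))
  )
  sp_ids <- sort(names(member_split))
  superpaths <- tibble(
    superpath_id = sp_ids,
    n_members = unname(lengths(member_split)[sp_ids]),
    n_genes = unname(lengths(gene_split)[sp_ids]),
    genes = unname(gene_split[sp_ids])
  )
  out <- structure(
    list(
      superpaths = superpaths,
      membership = tibble(
        pathway_id = collection$pathway_id,
        superpath_id = unname(labels[collection$pathway_id])
      ),
      edge_log = edges,
      t1 = t1,
      t2 = t2,
      params = list(small_max = small_max, large_max = large_max,
                    c_min = c_min, absorption = absorption,
                    hub_edges = hub_edges),
      collection = collection
    ),
    class = "superpath_clustering"
  )
  assign_hubs(out, hub_edges = hub_edges)
}

#' Assign hub pathways and names to SuperPaths
#'
#' The hub is the member with the highest degree over intra-cluster edges;
#' ties go to the pathway with more genes, then to the lexicographically
#' smallest id. A singleton's hub is its only member. The SuperPath is named
#' after its hub.
#'
#' @param clustering A [build_superpaths()] result.
#' @param hub_edges `"all"` to count preprocessing/identical edges toward
#'   degree, `"similarity"` for core/best edges only.
#' @return The clustering with `hub` and `name` columns (re)computed.
#' @export
assign_hubs <- function(clustering, hub_edges = c("all", "similarity")) {
  hub_edges <- match.arg(hub_edges)
  coll <- clustering$collection
  sizes <- setNames(lengths(coll$genes), coll$pathway_id)
  names_by_id <- setNames(coll$name, coll$pathway_id)
  sp_of <- setNames(clustering$membership$superpath_id,
                    clustering$membership$pathway_id)

  edges <- clustering$edge_log
  if (hub_edges == "similarity") edges <- edges[edges$type %in% c("core", "best"), ]
  pairs <- distinct(edges[c("from", "to")])
  # all logged edges are intra-cluster by construction
  deg <- table(c(pairs$from, pairs$to))

  pick_hub <- function(members) {
    if (length(members) == 1) return(members)
    d <- as.integer(deg[members])
    d[is.na(d)] <- 0L
    cand <- members[d == max(d)]
    cand <- cand[sizes[cand] == max(sizes[cand])]
    min(cand)
  }
  hubs <- vapply(
    split(clustering$membership$pathway_id, sp_of[clustering$membership$pathway_id]),
    pick_hub, character(1)
  )
  clustering$superpaths$hub <- unname(hubs[clustering$superpaths$superpath_id])
  clustering$superpaths$name <- unname(names_by_id[clustering$superpaths$hub])
  clustering$params$hub_edges <- hub_edges
  clustering
}

#' Per-gene support within each SuperPath
#'
#' For every gene of every SuperPath, the number and fraction of member
#' pathways that contain it (the graded evidence used to rank genes within a
#' consolidated cluster).
#'
#' @param clustering A [build_superpaths()] result.
#' @return A tibble with columns `superpath_id`, `gene`, `n_pathways`,
#'   `fraction`.
#' @export
superpath_support <- function(clustering) {
  coll <- clustering$collection
  sp_of <- setNames(clustering$membership$superpath_id,
                    clustering$membership$pathway_id)
  long <- tibble(
    superpath_id = rep.int(unname(sp_of[coll$pathway_id]), lengths(coll$genes)),
    gene = unlist(coll$genes, use.names = FALSE)
  ) %>%
    count(.data$superpath_id, .data$gene, name = "n_pathways")
  n_members <- setNames(clustering$superpaths$n_members,
                        clustering$superpaths$superpath_id)
  long$fraction <- long$n_pathways / as.integer(n_members[long$superpath_id])
  arrange(long, .data$superpath_id, dplyr::desc(.data$n_pathways), .data$gene)
}

#' Write SuperPaths as a consolidated GMT file
#'
#' One line per SuperPath: cluster id, `"SuperPath|<hub name>"`, union genes.
#'
#' @param clustering A [build_superpaths()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_superpath_gmt <- function(clustering, path) {
  sp <- clustering$superpaths
  name <- gsub("\t", " ", sp$name, fixed = TRUE)
  writeLines(paste(
    sp$superpath_id,
    paste("SuperPath", name, sep = "|"),
    vapply(sp$genes, paste, character(1), collapse = "\t"),
    sep = "\t"
  ), path)
  invisible(path)
}

#' @export
print.superpath_clustering <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("SuperPath clustering (t1 = %.2f, t2 = %.2f)\n",
           "  %d pathways -> %d SuperPaths (%d singletons, largest %d)\n",
           "  U_S = %.4f  I_S = %.4f  objective = %.4f\n"),
    x$t1, x$t2, g$n_pathways, g$n_superpaths, g$n_singletons, g$largest,
    g$u_s, g$i_s, g$objective
  ))
  invisible(x)
}

#' Tidy a SuperPath clustering into a membership table
#'
#' @param x A [build_superpaths()] result.
#' @param ... Unused.
#' @return A tibble with one row per pathway: `pathway_id`, `source`,
#'   `name`, `superpath_id`, `superpath_name`, `role` (`"hub"` or
#'   `"member"`).
#' @export
tidy.superpath_clustering <- function(x, ...) {
  hubs <- setNames(x$superpaths$hub, x$superpaths$superpath_id)
  sp_names <- setNames(x$superpaths$name, x$superpaths$superpath_id)
  x$membership %>%
    left_join(
      select(x$collection, "pathway_id", "source", "name"),
      by = "pathway_id"
    ) %>%
    mutate(
      superpath_name = unname(sp_names[.data$superpath_id]),
      role = ifelse(.data$pathway_id == unname(hubs[.data$superpath_id]),
                    "hub", "member")
    ) %>%
    select("pathway_id", "source", "name", "superpath_id",
           "superpath_name", "role") %>%
    arrange(.data$superpath_id, dplyr::desc(.data$role == "hub"),
            .data$pathway_id)
}

#' One-row summary of a SuperPath clustering
#'
#' @param x A [build_superpaths()] result.
#' @param ... Unused.
#' @return A tibble with `n_pathways`, `n_superpaths`, `n_singletons`,
#'   `largest`, `t1`, `t2`, `u_s`, `i_s`, `objective`.
#' @export
glance.superpath_clustering <- function(x, ...) {
  obj <- clustering_objective(x)
  tibble(
    n_pathways = nrow(x$collection),
    n_superpaths = nrow(x$superpaths),
    n_singletons = sum(x$superpaths$n_members == 1),
    largest = max(x$superpaths$n_members),
    t1 = x$t1,
    t2 = x$t2,
    u_s = obj$u_s,
    i_s = obj$i_s,
    objective = obj$objective
  )
}

#' Plot the SuperPath size distribution
#'
#' @param object A [build_superpaths()] result.
#' @param ... Unused.
#' @return A ggplot: histogram of member counts per SuperPath.
#' @export
autoplot.superpath_clustering <- function(object, ...) {
  ggplot2::ggplot(object$superpaths, ggplot2::aes(x = .data$n_members)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "pathways per SuperPath", y = "SuperPaths",
      title = sprintf("SuperPath sizes (t1 = %.2f, t2 = %.2f)",
                      object$t1, object$t2)
    )
}
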