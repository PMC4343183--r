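# Threshold selection: the uniqueness/informativeness objective and
# dilution-resampling stability.
#
# Uniqueness U(s) of a SuperPath with gene union G_s is
#   log10( mean over g in G_s of 1 / N_sp(g) ),
# where N_sp(g) counts SuperPaths whose union contains g; it is 0 when every
# gene of s is exclusive to s and falls as genes recur across SuperPaths.
# Informativeness I(g) of a gene is symmetrically
#   log10( mean over containing SuperPaths s of 1 / |G_s| );
# it falls as clusters grow, reaching log10(1/universe) for one giant
# cluster. U_S and I_S are the unweighted means; U_S + I_S is the
# model-selection objective, maximized over (t1, t2).

# gene unions per cluster from a membership label vector (named by id)
cluster_unions <- function(collection, labels) {
  lapply(
    split(collection$genes, labels[collection$pathway_id]),
    function(gs) unique(unlist(gs, use.names = FALSE))
  )
}

# per-cluster uniqueness and per-gene informativeness from the unions
union_scores <- function(unions) {
  genes <- unlist(unions, use.names = FALSE)
  n_sp <- table(genes)  # each union holds unique genes
  u <- vapply(
    unions,
    function(g) log10(mean(1 / as.numeric(n_sp[g]))),
    double(1)
  )
  inv_size <- rep.int(1 / lengths(unions), lengths(unions))
  mean_inv <- rowsum(inv_size, genes)  # sums, grouped and sorted by gene
  cnt <- as.numeric(n_sp[rownames(mean_inv)])
  i <- log10(mean_inv[, 1] / cnt)
  list(
    u = u,
    i = setNames(i, rownames(mean_inv)),
    n_sp = n_sp
  )
}

#' Per-SuperPath uniqueness
#'
#' How exclusively a SuperPath's genes belong to it alone: 0 when no gene is
#' shared with another SuperPath, increasingly negative as genes recur
#' elsewhere.
#'
#' @param clustering A [build_superpaths()] result.
#' @return A tibble with columns `superpath_id`, `n_genes`, `uniqueness`
#'   (log10 scale, always <= 0).
#' @export
superpath_uniqueness <- function(clustering) {
  sc <- union_scores(setNames(clustering$superpaths$genes,
                              clustering$superpaths$superpath_id))
  tibble(
    superpath_id = clustering$superpaths$superpath_id,
    n_genes = clustering$superpaths$n_genes,
    uniqueness = unname(sc$u[clustering$superpaths$superpath_id])
  )
}

#' Per-gene informativeness
#'
#' How specific SuperPath membership is for each annotated gene: close to 0
#' for genes in small exclusive SuperPaths, very negative for genes of huge
#' clusters. Genes absent from all pathways are not scored.
#'
#' @param clustering A [build_superpaths()] result.
#' @return A tibble with columns `gene`, `n_superpaths`, `informativeness`
#'   (log10 scale, always <= 0).
#' @export
gene_informativeness <- function(clustering) {
  sc <- union_scores(setNames(clustering$superpaths$genes,
                              clustering$superpaths$superpath_id))
  tibble(
    gene = names(sc$i),
    n_superpaths = as.integer(sc$n_sp[names(sc$i)]),
    informativeness = unname(sc$i)
  )
}

#' Clustering objective U_S + I_S
#'
#' Unweighted mean uniqueness over SuperPaths plus unweighted mean
#' informativeness over genes. The two are antagonistic — merging raises
#' U_S and lowers I_S — so their sum trades redundancy removal against
#' annotation specificity.
#'
#' @param clustering A [build_superpaths()] result.
#' @return A one-row tibble with `u_s`, `i_s`, `objective`.
#' @export
clustering_objective <- function(clustering) {
  sc <- union_scores(setNames(clustering$superpaths$genes,
                              clustering$superpaths$superpath_id))
  tibble(u_s = mean(sc$u), i_s = mean(sc$i), objective = mean(sc$u) + mean(sc$i))
}

#' Grid search over threshold pairs
#'
#' Clusters the collection at every admissible `(t1, t2)` pair (`t1 <= t2`)
#' and scores each with U_S + I_S. The diagonal `t1 = t2` corresponds to
#' pure single-linkage (hierarchical) merging.
#'
#' @param collection A [pathway_collection()].
#' @param t1_values,t2_values Candidate thresholds in (0, 1]; default grid
#'   step 0.1.
#' @param ... Absorption parameters passed on to [build_superpaths()]
#'   (`small_max`, `large_max`, `c_min`, `absorption`).
#' @return An object of class `threshold_grid`: a list with `grid` (tibble:
#'   `t1`, `t2`, `n_superpaths`, `u_s`, `i_s`, `objective`) and `best` (the
#'   argmax row; ties broken toward the largest `t1`, then largest `t2`,
#'   favoring the least-merged optimum).
#' @export
grid_search <- function(collection,
                        t1_values = seq(0.1, 1, by = 0.1),
                        t2_values = seq(0.1, 1, by = 0.1),
                        ...) {
  vals <- c(t1_values, t2_values)
  if (length(t1_values) == 0 || length(t2_values) == 0) abort("empty threshold grid")
  if (any(vals <= 0 | vals > 1)) abort("threshold values must be in (0, 1]")
  dots <- list(...)
  parts <- do.call(cluster_parts, c(
    list(collection = collection, j_min = min(t1_values)), dots
  ))
  cells <- expand.grid(t1 = sort(t1_values), t2 = sort(t2_values))
  cells <- cells[cells$t1 <= cells$t2, , drop = FALSE]
  if (nrow(cells) == 0) abort("no admissible (t1, t2) pair with t1 <= t2")
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    t1 <- cells$t1[k]
    t2 <- cells$t2[k]
    labels <- edge_components(parts$ids, assemble_edges(parts, t1, t2))
    sc <- union_scores(cluster_unions(collection, labels))
    tibble(
      t1 = t1, t2 = t2, n_superpaths = length(sc$u),
      u_s = mean(sc$u), i_s = mean(unname(sc$i)),
      objective = mean(sc$u) + mean(unname(sc$i))
    )
  })
  grid <- bind_rows(rows)
  ord <- order(-grid$objective, -grid$t1, -grid$t2)
  structure(
    list(grid = grid, best = grid[ord[1], ]),
    class = "threshold_grid"
  )
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("Threshold grid: %d (t1, t2) pairs\n", nrow(x$grid)))
  cat(sprintf(
    "best: t1 = %.2f, t2 = %.2f (U_S = %.4f, I_S = %.4f, U_S + I_S = %.4f)\n",
    x$best$t1, x$best$t2, x$best$u_s, x$best$i_s, x$best$objective
  ))
  invisible(x)
}

#' @export
tidy.threshold_grid <- function(x, ...) x$grid

#' @export
glance.threshold_grid <- function(x, ...) x$best

#' Heat map of the threshold objective surface
#'
#' @param object A [grid_search()] result.
#' @param ... Unused.
#' @return A ggplot: t1 x t2 tiles filled by U_S + I_S.
#' @export
autoplot.threshold_grid <- function(object, ...) {
  ggplot2::ggplot(
    object$grid,
    ggplot2::aes(x = factor(.data$t1), y = factor(.data$t2),
                 fill = .data$objective)
  ) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "t1 (best-neighbor cutoff)", y = "t2 (core cutoff)",
                  fill = "U_S + I_S")
}

#' Dilution-resampling stability of the clustering
#'
#' For each candidate `t2` (at fixed `t1`), clusters the full collection,
#' then repeatedly reclusters random pathway subsets and measures the
#' fraction of full-data co-cluster pairs (restricted to the sampled
#' pathways) that are recovered. High recovery means the clustering does not
#' hinge on individual pathways.
#'
#' @param collection A [pathway_collection()].
#' @param t1 Lower threshold (fixed during the scan).
#' @param t2_values Candidate upper thresholds (each >= `t1`).
#' @param dilutions Sampling fractions in (0, 1].
#' @param reps Replicates per (t2, dilution).
#' @param seed Integer seed; the whole scan is reproducible given the seed.
#' @param ... Absorption parameters passed on (see [build_superpaths()]).
#' @return An object of class `stability_result`: a tibble with one row per
#'   (t2, dilution): `n_reps` (replicates contributing an observation),
#'   `n_skipped` (replicates with no restricted full-data pairs),
#'   `recoveries` (list-column), `mean_recovery`, `sd_recovery` (sample sd).
#' @export
stability_scan <- function(collection, t1 = 0.3,
                           t2_values = seq(0.3, 0.9, by = 0.1),
                           dilutions = c(0.75, 0.9),
                           reps = 100, seed = 1, ...) {
  if (any(dilutions <= 0 | dilutions > 1)) abort("dilutions must be in (0, 1]")
  if (reps < 1) abort("reps must be >= 1")
  if (any(t2_values < t1)) abort("every t2 must be >= t1")
  parts <- cluster_parts(collection, j_min = t1, ...)
  ids <- parts$ids
  n <- length(ids)

  co_pairs <- function(labels) {
    members <- split(names(labels), labels)
    members <- members[lengths(members) >= 2]
    if (length(members) == 0) {
      return(tibble(a = character(), b = character()))
    }
    bind_rows(lapply(members, function(m) {
      m <- sort(m)
      p <- combn(m, 2)
      tibble(a = p[1, ], b = p[2, ])
    }))
  }

  withr::local_seed(seed)
  rows <- list()
  for (t2 in t2_values) {
    full <- co_pairs(edge_components(ids, assemble_edges(parts, t1, t2)))
    for (d in dilutions) {
      rec <- rep(NA_real_, reps)
      for (r in seq_len(reps)) {
        samp <- sample(ids, floor(d * n))
        restricted <- full[full$a %in% samp & full$b %in% samp, ]
        if (nrow(restricted) == 0) next  # no observable pairs; skip replicate
        sub_labels <- edge_components(
          samp, assemble_edges(parts, t1, t2, ids_subset = samp)
        )
        sub_keys <- with(co_pairs(sub_labels), paste(a, b, sep = "\x1f"))
        rec[r] <- mean(paste(restricted$a, restricted$b, sep = "\x1f") %in% sub_keys)
      }
      obs <- rec[!is.na(rec)]
      rows[[length(rows) + 1]] <- tibble(
        t2 = t2, dilution = d,
        n_reps = length(obs), n_skipped = reps - length(obs),
        recoveries = list(obs),
        mean_recovery = if (length(obs) > 0) mean(obs) else NA_real_,
        sd_recovery = if (length(obs) > 1) sd(obs) else NA_real_
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "t1") <- t1
  attr(out, "seed") <- seed
  class(out) <- c("stability_result", class(out))
  out
}

#' Plot a stability scan
#'
#' @param object A [stability_scan()] result.
#' @param ... Unused.
#' @return A ggplot: mean recovery against t2, one line per dilution.
#' @export
autoplot.stability_result <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$t2, y = .data$mean_recovery,
                 colour = factor(.data$dilution))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "t2 (core cutoff)", y = "mean co-cluster pair recovery",
                  colour = "dilution")
}
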