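# Synthetic multi-source pathway corpora with planted module structure.
#
# Each planted module is a base gene set; pseudo-sources ship overlapping
# variants of it (each module gene kept with keep_rate, background genes
# added at noise_rate), with names drawn from a module-specific word pool
# plus source-specific decorations so that name similarity correlates only
# imperfectly with gene content. Pair-evidence tables carry elevated signal
# for within-module gene pairs.

# draw one element of v; immune to R's scalar-sample quirk when the range
# collapses to a single value (sample(2:2, 1) would sample from 1:2)
sample_one <- function(v) v[sample.int(length(v), 1L)]

synthetic_vocab <- function() {
  c("glycolysis", "meiosis", "apoptosis", "autophagy", "proteolysis",
    "oxidative", "phosphorylation", "transcription", "translation",
    "replication", "repair", "checkpoint", "cycle", "adhesion", "migration",
    "junction", "transport", "secretion", "folding", "degradation",
    "lipid", "sterol", "glucose", "insulin", "calcium", "potassium",
    "receptor", "kinase", "phosphatase", "ligase", "protease", "channel",
    "immune", "inflammatory", "interferon", "cytokine", "chemokine",
    "axon", "synaptic", "cardiac", "hepatic", "renal", "muscle",
    "mitochondrial", "ribosomal", "nuclear", "membrane", "cytoskeleton")
}

#' Named parameter presets for the corpus generator
#'
#' `"clean"` emulates a well-curated multi-source corpus: tight variants
#' (keep rate 0.8, background rate 0.05) of disjoint modules — the regime
#' where consolidation should recover the planted structure almost exactly.
#' `"heterogeneous"` emulates a messier corpus whose pairwise similarities
#' straddle both clustering cutoffs: looser variants (keep rate 0.65, noise
#' 0.1) of chained, half-overlapping modules with more variants per module —
#' the regime where threshold choice genuinely matters.
#' `"power"` is the evidence-power design: exactly two moderately overlapping
#' variants per module (keep rate 0.7) with minimal background admixture, so
#' that the gene pairs created by consolidation are overwhelmingly
#' module-internal — the pairs for which planted pair evidence is elevated.
#'
#' @param name Preset name.
#' @return A named list of [generate_collection()] arguments.
#' @export
synthetic_preset <- function(name = c("clean", "heterogeneous", "power")) {
  name <- match.arg(name)
  switch(name,
    clean = list(
      n_modules = 10, module_size_range = c(25, 60), n_sources = 4,
      variants_per_module = c(2, 4), keep_rate = 0.8, noise_rate = 0.05,
      n_noise_pathways = 15, module_overlap = 0, n_genes = 1000
    ),
    heterogeneous = list(
      n_modules = 8, module_size_range = c(20, 60), n_sources = 5,
      variants_per_module = c(3, 6), keep_rate = 0.65, noise_rate = 0.1,
      n_noise_pathways = 10, module_overlap = 0.5, n_genes = 800
    ),
    power = list(
      n_modules = 14, module_size_range = c(30, 60), n_sources = 4,
      variants_per_module = c(2, 2), keep_rate = 0.7, noise_rate = 0.02,
      n_noise_pathways = 10, module_overlap = 0, n_genes = 1200
    )
  )
}

#' Generate a synthetic multi-source pathway collection
#'
#' @param n_modules Number of planted base modules.
#' @param module_size_range Inclusive bounds on module gene count (each >= 2).
#' @param n_sources Number of pseudo-sources.
#' @param variants_per_module Inclusive bounds on the number of variants per
#'   module.
#' @param keep_rate Probability that a variant keeps each module gene.
#' @param noise_rate Expected background genes per variant, as a fraction of
#'   module size.
#' @param n_noise_pathways Unplanted random pathways added to the corpus.
#' @param module_overlap Fraction of each module's genes shared with the
#'   previous module (chained overlap; 0 = disjoint modules).
#' @param n_genes Gene universe size.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   full argument list.
#' @return A list with `collection` (a [pathway_collection()]) and `truth`
#'   (class `synthetic_truth`: `modules` — list of base gene sets,
#'   `pathway_parent` — tibble mapping `pathway_id` to `module` (`NA` for
#'   noise pathways), `universe` — annotated genes, and `config` — the full
#'   argument echo, sufficient to regenerate the corpus bit-for-bit).
#' @export
generate_collection <- function(n_modules = 10,
                                module_size_range = c(25, 60),
                                n_sources = 4,
                                variants_per_module = c(2, 4),
                                keep_rate = 0.8,
                                noise_rate = 0.05,
                                n_noise_pathways = 15,
                                module_overlap = 0,
                                n_genes = 1000,
                                seed = 1) {
  config <- list(
    n_modules = n_modules, module_size_range = module_size_range,
    n_sources = n_sources, variants_per_module = variants_per_module,
    keep_rate = keep_rate, noise_rate = noise_rate,
    n_noise_pathways = n_noise_pathways, module_overlap = module_overlap,
    n_genes = n_genes, seed = seed
  )
  if (keep_rate < 0 || keep_rate > 1 || noise_rate < 0 || noise_rate > 1 ||
      module_overlap < 0 || module_overlap > 1) {
    abort("rates must be in [0, 1]")
  }
  if (min(module_size_range) < 2) abort("module sizes must be >= 2")
  if (n_modules * max(module_size_range) > n_genes) {
    abort("infeasible: modules cannot be drawn from a universe this small")
  }
  withr::local_seed(seed)

  universe <- sprintf("G%05d", seq_len(n_genes))
  pool <- sample(universe)
  taken <- 0L

  draw_fresh <- function(k) {
    if (taken + k > length(pool)) abort("infeasible: gene universe exhausted")
    out <- pool[(taken + 1L):(taken + k)]
    taken <<- taken + k
    out
  }

  modules <- vector("list", n_modules)
  for (i in seq_len(n_modules)) {
    m <- sample_one(module_size_range[1]:module_size_range[2])
    n_shared <- if (i > 1) min(round(module_overlap * m), length(modules[[i - 1]])) else 0L
    shared <- if (n_shared > 0) sample(modules[[i - 1]], n_shared) else character(0)
    modules[[i]] <- c(shared, draw_fresh(m - n_shared))
  }

  vocab <- sample(synthetic_vocab())
  module_words <- lapply(seq_len(n_modules), function(i) {
    if (3 * n_modules <= length(vocab)) {
      vocab[(3 * (i - 1) + 1):(3 * i)]
    } else {
      sample(vocab, 3)
    }
  })
  sources <- sprintf("SRC%d", seq_len(n_sources))
  decorations <- rep_len(
    c("signaling", "regulation", "response", "homeostasis", "cascade",
      "network", "process", "activity"),
    n_sources
  )

  rows <- list()
  parent <- integer(0)
  for (i in seq_len(n_modules)) {
    k <- sample_one(variants_per_module[1]:variants_per_module[2])
    src <- sample(sources, k, replace = k > n_sources)
    for (v in seq_len(k)) {
      kept <- modules[[i]][stats::runif(length(modules[[i]])) < keep_rate]
      if (length(kept) < 2) kept <- sample(modules[[i]], 2)
      n_bg <- rbinom(1, length(modules[[i]]), noise_rate)
      bg <- if (n_bg > 0) sample(setdiff(universe, modules[[i]]), n_bg) else character(0)
      w <- sample(module_words[[i]], sample_one(2:3))
      name <- paste(
        c(w, if (stats::runif(1) < 0.7) decorations[match(src[v], sources)]),
        collapse = " "
      )
      rows[[length(rows) + 1]] <- list(
        source = src[v], name = name, genes = unique(c(kept, bg))
      )
      parent <- c(parent, i)
    }
  }
  for (j in seq_len(n_noise_pathways)) {
    size <- sample_one(8:30)
    rows[[length(rows) + 1]] <- list(
      source = sample(sources, 1),
      name = paste(
        c(sample(vocab, 2), if (stats::runif(1) < 0.5) sample(decorations, 1)),
        collapse = " "
      ),
      genes = sample(universe, size)
    )
    parent <- c(parent, NA_integer_)
  }

  src <- vapply(rows, `[[`, character(1), "source")
  collection <- pathway_collection(tibble(
    pathway_id = sprintf("%s:%04d", src, seq_along(rows)),
    source = src,
    name = vapply(rows, `[[`, character(1), "name"),
    genes = lapply(rows, `[[`, "genes")
  ))
  truth <- structure(
    list(
      modules = modules,
      pathway_parent = tibble(pathway_id = collection$pathway_id, module = parent),
      universe = gene_universe(collection),
      config = config
    ),
    class = "synthetic_truth"
  )
  list(collection = collection, truth = truth)
}

#' Regenerate a synthetic corpus from its config echo
#'
#' @param truth A `synthetic_truth` object.
#' @return The output of [generate_collection()] with the recorded
#'   arguments — bit-identical to the original.
#' @export
regenerate_collection <- function(truth) {
  do.call(generate_collection, truth$config)
}

# all unordered pair keys lying inside at least one planted module
module_pair_keys <- function(truth) {
  unique(unlist(lapply(truth$modules, set_pair_keys)))
}

#' Generate synthetic pair-evidence tables
#'
#' Shared-publication counts follow an over-dispersed (negative-binomial)
#' distribution with mean `background_rate`, multiplied by
#' `signal_multiplier` for gene pairs lying within a planted module; PPI
#' scores are Beta-distributed in \[0, 1\] with a within-module upward
#' shift. With `signal_multiplier = 1` within-module pairs are
#' indistinguishable from background. Pairs with zero publications or
#' negligible PPI score are omitted from the tables (absent pairs score 0).
#'
#' @param truth A `synthetic_truth` object.
#' @param background_rate Mean publication count for background pairs.
#' @param signal_multiplier Evidence multiplier for within-module pairs
#'   (>= 1).
#' @param dispersion Negative-binomial size parameter (smaller = heavier
#'   tail).
#' @param seed Integer seed.
#' @return A list with `publications` and `ppi`, each a `pair_evidence`
#'   tibble (`gene_a`, `gene_b`, `value`).
#' @export
generate_pair_evidence <- function(truth, background_rate = 1,
                                   signal_multiplier = 5,
                                   dispersion = 0.3, seed = 1) {
  if (signal_multiplier < 1) abort("signal_multiplier must be >= 1")
  withr::local_seed(seed)
  genes <- sort(truth$universe)
  n <- length(genes)
  first <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  second <- sequence(rev(seq_len(n - 1L)), from = seq_len(n - 1L) + 1L)
  a <- genes[first]
  b <- genes[second]
  within <- paste(a, b, sep = "\x1f") %in% module_pair_keys(truth)

  mu <- background_rate * ifelse(within, signal_multiplier, 1)
  pubs <- rnbinom(length(mu), size = dispersion, mu = mu)
  keep_p <- pubs > 0
  publications <- tibble(gene_a = a[keep_p], gene_b = b[keep_p],
                         value = as.numeric(pubs[keep_p]))
  attr(publications, "type") <- "publications"
  class(publications) <- c("pair_evidence", class(publications))

  ppi <- rbeta(length(mu), shape1 = ifelse(within, signal_multiplier, 1),
               shape2 = 9)
  keep_s <- ppi > 0.05
  ppi_tbl <- tibble(gene_a = a[keep_s], gene_b = b[keep_s],
                    value = round(ppi[keep_s], 4))
  attr(ppi_tbl, "type") <- "ppi"
  class(ppi_tbl) <- c("pair_evidence", class(ppi_tbl))

  list(publications = publications, ppi = ppi_tbl)
}

#' Generate synthetic differential-expression query sets
#'
#' Each query mixes genes from one planted module (with probability
#' `from_module_fraction` per gene) with background genes from the annotated
#' universe, emulating tissue-specific differentially expressed gene sets.
#'
#' @param truth A `synthetic_truth` object.
#' @param n_sets Number of query sets.
#' @param from_module_fraction Per-gene probability of drawing from the
#'   query's module rather than from the background.
#' @param size_range Inclusive bounds on query size.
#' @param seed Integer seed.
#' @return A tibble with columns `query_id`, `module`, `genes`
#'   (list-column).
#' @export
generate_query_sets <- function(truth, n_sets = 50,
                                from_module_fraction = 0.8,
                                size_range = c(15, 40), seed = 1) {
  withr::local_seed(seed)
  universe <- truth$universe
  rows <- lapply(seq_len(n_sets), function(k) {
    m <- sample_one(seq_along(truth$modules))
    module <- intersect(truth$modules[[m]], universe)
    size <- sample_one(size_range[1]:size_range[2])
    size <- min(size, length(module))
    from_mod <- stats::runif(size) < from_module_fraction
    g <- character(size)
    g[from_mod] <- sample(module, sum(from_mod))
    g[!from_mod] <- sample(setdiff(universe, module), sum(!from_mod))
    tibble(query_id = sprintf("Q%03d", k), module = m, genes = list(unique(g)))
  })
  bind_rows(rows)
}
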