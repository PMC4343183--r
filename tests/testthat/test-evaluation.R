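test_that("novel pairs are SuperPath pairs absent from every single pathway", {
  coll <- make_coll(list(P1 = c("A", "B"), P2 = c("B", "C")))
  cl <- fake_clustering(coll, stats::setNames(c("x", "x"), c("P1", "P2")))
  np <- novel_gene_pairs(cl)
  expect_equal(np, tibble::tibble(gene_a = "A", gene_b = "C"))

  singletons <- fake_clustering(coll, stats::setNames(c("x", "y"), c("P1", "P2")))
  expect_equal(nrow(novel_gene_pairs(singletons)), 0)

  # brute-force double-loop oracle
  coll2 <- random_collection(10, universe_size = 15, size_range = c(3, 6), seed = 44)
  cl2 <- build_superpaths(coll2, t1 = 0.2, t2 = 0.5)
  np2 <- novel_gene_pairs(cl2)
  genes <- gene_universe(coll2)
  expected <- list()
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1):length(genes)) {
      in_sp <- any(vapply(cl2$superpaths$genes, function(u) {
        genes[i] %in% u && genes[j] %in% u
      }, logical(1)))
      in_path <- any(vapply(coll2$genes, function(s) {
        genes[i] %in% s && genes[j] %in% s
      }, logical(1)))
      if (in_sp && !in_path) {
        expected[[length(expected) + 1]] <- c(genes[i], genes[j])
      }
    }
  }
  got <- sprintf("%s|%s", np2$gene_a, np2$gene_b)
  want <- vapply(expected, function(p) sprintf("%s|%s", p[1], p[2]), character(1))
  expect_setequal(got, want)
})

test_that("pseudo-SuperPaths preserve size profiles exactly and are seeded", {
  coll <- random_collection(12, universe_size = 40, size_range = c(3, 9), seed = 12)
  cl <- build_superpaths(coll, t1 = 0.2, t2 = 0.5)
  ps1 <- pseudo_superpaths(cl, seed = 1)
  ps2 <- pseudo_superpaths(cl, seed = 2)
  expect_equal(ps1$superpaths$n_genes, cl$superpaths$n_genes)
  expect_equal(lengths(ps1$superpaths$genes), cl$superpaths$n_genes)
  expect_equal(lengths(ps1$collection$genes), lengths(cl$collection$genes))
  # member sets stay inside their pseudo-union
  sp_of <- stats::setNames(ps1$membership$superpath_id, ps1$membership$pathway_id)
  unions <- stats::setNames(ps1$superpaths$genes, ps1$superpaths$superpath_id)
  for (i in seq_len(nrow(ps1$collection))) {
    expect_length(
      setdiff(ps1$collection$genes[[i]],
              unions[[sp_of[[ps1$collection$pathway_id[i]]]]]),
      0
    )
  }
  expect_false(identical(ps1$superpaths$genes, ps2$superpaths$genes))
  expect_identical(pseudo_superpaths(cl, seed = 1)$superpaths$genes,
                   ps1$superpaths$genes)
  expect_error(pseudo_superpaths(cl, universe = g_ids(1:3)), "universe")
})

test_that("within-pseudo-set evidence reflects the background pair population", {
  sim <- generate_collection(
    n_modules = 4, module_size_range = c(12, 20), n_sources = 3,
    variants_per_module = c(2, 3), keep_rate = 0.8, noise_rate = 0.05,
    n_noise_pathways = 3, n_genes = 150, seed = 77
  )
  ev <- generate_pair_evidence(sim$truth, background_rate = 1,
                               signal_multiplier = 5, seed = 78)$publications
  cl <- build_superpaths(sim$collection, t1 = 0.3, t2 = 0.7)
  # population mean over all annotated gene pairs (absent pairs score 0)
  genes <- sim$truth$universe
  n_pairs <- choose(length(genes), 2)
  pop_mean <- sum(ev$value) / n_pairs
  mc <- vapply(1:100, function(s) {
    ps <- pseudo_superpaths(cl, seed = s)
    mean(evidence_values(ev, novel_gene_pairs(ps)))
  }, double(1))
  expect_lt(abs(mean(mc) - pop_mean), 0.2)
})

test_that("ks_compare is one-sided toward larger test values and seeded", {
  withr::with_seed(2, {
    null_test <- rnorm(400)
    null_ctrl <- rnorm(600)
    shifted <- rnorm(500) + 1
    big_ctrl <- rnorm(800)
  })
  null_res <- ks_compare(null_test, null_ctrl, seed = 1)
  expect_gt(null_res$p_value, 0.05)
  shift_res <- ks_compare(shifted, big_ctrl, seed = 1)
  expect_lt(shift_res$p_value, 0.05)
  expect_true(shift_res$p_value > 0)
  expect_identical(ks_compare(shifted, big_ctrl, seed = 1)$p_value,
                   shift_res$p_value)
  expect_error(ks_compare(shifted, big_ctrl[1:10]), "control")
  expect_error(ks_compare(numeric(0), big_ctrl), "non-empty")
})

test_that("empty control bins get a pseudo-count of one in fold ratios", {
  test <- c(85, 84, 86, 88, rep(5, 50))
  control <- rep(5, 60)
  res <- ks_compare(test, control, seed = 1, breaks = seq(0, 90, 10))
  high <- res$bins[res$bins$bin == "(80,90]", ]
  expect_equal(high$test_count, 4)
  expect_equal(high$control_count, 0)
  expect_equal(high$ratio, 4)  # 4 test observations over an empty control bin
})

test_that("ora_pvalue equals direct hypergeometric tail summation", {
  expect_equal(ora_pvalue(g_ids(1:10), g_ids(1:10), g_ids(1:10)), 1)

  universe <- g_ids(1:100)
  target <- g_ids(1:10)
  query <- c(g_ids(6:10), g_ids(50:54))  # overlap 5
  manual <- sum(stats::dhyper(5:10, 10, 90, 10))
  expect_equal(ora_pvalue(query, target, universe), manual)

  # random instances vs direct summation
  withr::with_seed(9, {
    for (k in 1:10) {
      u <- g_ids(1:sample(50:200, 1))
      t <- sample(u, sample(3:20, 1))
      q <- sample(u, sample(3:20, 1))
      ov <- length(intersect(q, t))
      manual <- sum(stats::dhyper(ov:length(q), length(t),
                                  length(u) - length(t), length(q)))
      p <- ora_pvalue(q, t, u)
      expect_equal(p, manual)
      expect_true(p > 0 && p <= 1)
    }
  })

  disjoint <- ora_pvalue(g_ids(1:5), g_ids(6:10), g_ids(1:20))
  expect_equal(disjoint, 1)
  expect_error(ora_pvalue(g_ids(1:5), g_ids(1:5), g_ids(2:10)), "subsets")
})

test_that("enrichment deltas vanish for degenerate cases and favor planted queries", {
  # constituents identical to their union: delta = 0
  coll <- make_coll(list(P1 = g_ids(1:20), P2 = g_ids(1:20)))
  cl <- fake_clustering(coll, stats::setNames(c("x", "x"), c("P1", "P2")))
  d <- enrichment_delta(cl, list(q = g_ids(1:5)), universe = g_ids(1:100))
  expect_equal(d$delta, 0)

  # disjoint query: all p = 1, delta = 0
  d0 <- enrichment_delta(cl, list(q = g_ids(50:60)), universe = g_ids(1:100))
  expect_equal(d0$p_superpath, 1)
  expect_equal(d0$delta, 0)

  # queries drawn from a planted module that two variants partially sample
  sim <- generate_collection(
    n_modules = 5, module_size_range = c(25, 40), n_sources = 3,
    variants_per_module = c(2, 2), keep_rate = 0.7, noise_rate = 0.05,
    n_noise_pathways = 0, n_genes = 400, seed = 55
  )
  cls <- build_superpaths(sim$collection, t1 = 0.3, t2 = 0.7)
  queries <- generate_query_sets(sim$truth, n_sets = 30,
                                 from_module_fraction = 1, seed = 56)
  cohort <- comparison_cohort(cls, j_max = 0.95)
  expect_gt(length(cohort), 0)
  dd <- enrichment_delta(cls, queries, superpath_ids = cohort)
  informative <- dd[dd$p_superpath < 0.5, ]
  expect_gt(mean(informative$delta > 0), 0.5)
})

test_that("comparison_cohort selects two-member SuperPaths below the J cutoff", {
  coll <- make_coll(list(
    A1 = g_ids(1:20), A2 = c(g_ids(1:12), g_ids(30:37)),  # J = 12/28 ~ 0.43
    B1 = g_ids(51:70), B2 = c(g_ids(51:68), g_ids(80:81)) # J = 18/22 ~ 0.82
  ))
  cl <- build_superpaths(coll, t1 = 0.3, t2 = 0.8)
  cohort <- comparison_cohort(cl, j_max = 0.6)
  sp_of <- stats::setNames(cl$membership$superpath_id, cl$membership$pathway_id)
  expect_equal(cohort, unname(sp_of["A1"]))
})

test_that("pair evidence round trips and lookup is symmetric with 0 default", {
  ev <- tibble::tibble(
    gene_a = c("G1", "G2"), gene_b = c("G2", "G3"), value = c(5, 2)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_evidence(ev, path, type = "publications")
  back <- read_pair_evidence(path)
  expect_equal(attr(back, "type"), "publications")
  expect_equal(as.data.frame(back), as.data.frame(ev), ignore_attr = TRUE)
  lookup <- evidence_values(back, tibble::tibble(
    gene_a = c("G2", "G1", "G9"), gene_b = c("G1", "G9", "G10")
  ))
  expect_equal(lookup, c(5, 0, 0))
})

test_that("name/content concordance reproduces hand-computed percentages", {
  rates <- concordance_rates(n_both = 414, n_name_only = 3991, n_genes_only = 3782)
  expect_equal(rates$pct_similar_name_with_similar_genes, 100 * 414 / 4405)
  expect_equal(rates$pct_similar_genes_with_similar_name, 100 * 414 / 4196)

  # names equal iff gene sets equal: off-diagonal cells are empty
  coll <- make_coll(
    list(P1 = g_ids(1:10), P2 = g_ids(1:10), P3 = g_ids(20:29)),
    names = c("alpha beta", "alpha beta", "gamma delta")
  )
  ct <- name_content_contingency(coll)
  expect_equal(ct$counts["similar_name", "non_similar_genes"], 0)
  expect_equal(ct$counts["non_similar_name", "similar_genes"], 0)
  expect_equal(sum(ct$counts), choose(3, 2))
  expect_equal(ct$counts["similar_name", "similar_genes"], 1)
})
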