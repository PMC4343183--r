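test_that("absorption links small pathways to containing mid-size pathways only", {
  small <- g_ids(1:10)
  mid <- g_ids(1:150)
  big <- g_ids(1:250)
  coll <- make_coll(list(S = small, M = mid, B = big))
  ab <- preprocess_absorption(coll)
  # S (10 genes) fully inside M (150) -> edge; B has 250 genes, too large;
  # M inside B but M has 150 >= 20 genes, never a small partner
  expect_equal(nrow(ab), 1)
  expect_equal(ab$small, "S")
  expect_equal(ab$large, "M")
  expect_equal(ab$containment, 1)

  at_gate <- make_coll(list(S = g_ids(1:25), M = g_ids(1:150)))
  expect_equal(nrow(preprocess_absorption(at_gate)), 0)  # 25 >= small_max

  partial <- make_coll(list(S = g_ids(1:19), M = c(g_ids(1:18), g_ids(300:400))))
  expect_equal(preprocess_absorption(partial)$containment, 18 / 19)  # >= 0.9 passes
  weak <- make_coll(list(S = g_ids(1:10), M = c(g_ids(1:8), g_ids(300:400))))
  expect_equal(nrow(preprocess_absorption(weak)), 0)  # containment 0.8 < 0.9
})

test_that("identical_groups partitions by exact gene-set equality", {
  coll <- make_coll(list(
    P1 = g_ids(1:30), P2 = g_ids(1:30), P3 = g_ids(5:40)
  ), sources = c("A", "B", "C"))
  groups <- identical_groups(coll)
  expect_equal(sort(lengths(groups)), c(1, 2))
  expect_true(list(c("P1", "P2")) %in% groups)

  distinct_coll <- make_coll(list(P1 = c("A"), P2 = c("B"), P3 = c("A", "B")))
  expect_true(all(lengths(identical_groups(distinct_coll)) == 1))

  # hash-style grouping equals the O(n^2) equality scan
  coll2 <- random_collection(20, universe_size = 8, size_range = c(2, 4), seed = 2)
  groups2 <- identical_groups(coll2)
  pair_in_same <- function(a, b, groups) {
    any(vapply(groups, function(g) a %in% g && b %in% g, logical(1)))
  }
  ids <- coll2$pathway_id
  sets <- lapply(coll2$genes, sort)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      expect_equal(pair_in_same(ids[i], ids[j], groups2),
                   identical(sets[[i]], sets[[j]]))
    }
  }
})

test_that("core_edges filters the graph at t2", {
  coll <- make_coll(list(
    A = g_ids(1:10), B = c(g_ids(1:10), g_ids(11:14)) ,  # J = 10/14 = 0.714
    C = c(g_ids(1:9), g_ids(20:23))                      # J(A,C) = 9/13 = 0.69
  ))
  gr <- pairwise_graph(coll, j_min = 0.05)
  ce <- core_edges(gr, 0.7)
  expect_equal(nrow(ce), 1)
  expect_equal(sort(c(ce$from, ce$to)), c("A", "B"))
  expect_equal(nrow(core_edges(gr, 0.05)), nrow(gr))  # t2 at j_min keeps all
})

test_that("best-neighbor edges keep all tied maxima and skip identical sets", {
  # single best above t1
  coll <- make_coll(list(
    P = g_ids(1:10),
    N1 = c(g_ids(1:6), g_ids(40:44)),   # J(P,N1) = 6/15 = 0.4
    N2 = c(g_ids(7:10), g_ids(50:58))   # J(P,N2) = 4/19 ~ 0.21
  ))
  be <- best_neighbor_edges(pairwise_graph(coll, j_min = 0.01), t1 = 0.3)
  expect_true(any(be$from == "N1" & be$to == "P"))
  expect_false(any(be$from == "N2" | be$to == "N2"))

  # exact tie: both best edges emitted
  tie <- make_coll(list(
    P = g_ids(1:10),
    N1 = c(g_ids(1:6), g_ids(40:44)),   # J = 6/15 = 0.4
    N2 = c(g_ids(5:10), g_ids(50:54))   # J = 6/15 = 0.4
  ))
  bt <- best_neighbor_edges(pairwise_graph(tie, j_min = 0.01), t1 = 0.3)
  expect_true(any((bt$from == "N1" & bt$to == "P") | (bt$from == "P" & bt$to == "N1")))
  expect_true(any((bt$from == "N2" & bt$to == "P") | (bt$from == "P" & bt$to == "N2")))

  # an identical copy (J = 1) is never the nearest neighbor
  idn <- make_coll(list(
    P = g_ids(1:10),
    Q = g_ids(1:10),
    R = c(g_ids(1:7), g_ids(60:69))     # J(P,R) = 7/20 = 0.35
  ))
  bi <- best_neighbor_edges(pairwise_graph(idn, j_min = 0.01), t1 = 0.3)
  expect_false(any(bi$from == "P" & bi$to == "Q"))
  expect_true(any(bi$to == "R" | bi$from == "R"))
})

test_that("a best-edge chain merges through connected components", {
  coll <- make_coll(list(
    A = c(g_ids(1:15), g_ids(16:18)),   # J(A,B) = 15/20 = 0.75 (core at 0.7)
    B = c(g_ids(1:15), g_ids(19:20)),
    C = c(g_ids(1:7), g_ids(30:32))     # J(B,C) = 7/20 = 0.35, C's best
  ))
  cl <- build_superpaths(coll, t1 = 0.3, t2 = 0.7)
  expect_equal(nrow(cl$superpaths), 1)
  expect_equal(cl$superpaths$n_members, 3)
})

test_that("disjoint pathways stay singletons and the result is a partition", {
  sets <- lapply(0:19, function(k) g_ids((10 * k + 1):(10 * k + 10)))
  names(sets) <- sprintf("P%02d", 1:20)
  cl <- build_superpaths(make_coll(sets), t1 = 0.3, t2 = 0.7)
  expect_equal(nrow(cl$superpaths), 20)
  expect_true(all(cl$superpaths$n_members == 1))
  expect_setequal(cl$membership$pathway_id, names(sets))
  expect_equal(anyDuplicated(cl$membership$pathway_id), 0)

  expect_error(build_superpaths(make_coll(sets), t1 = 0.8, t2 = 0.3), "t1 <= t2")
})

test_that("components equal a brute-force union-find oracle on small corpora", {
  for (seed in 1:6) {
    n <- 5 + (seed * 7) %% 8  # 5..12 pathways
    coll <- random_collection(n, universe_size = 20, size_range = c(2, 8),
                              seed = 100 + seed)
    for (th in list(c(0.2, 0.5), c(0.3, 0.7), c(0.5, 0.5))) {
      cl <- build_superpaths(coll, t1 = th[1], t2 = th[2])
      ed <- staged_edges(coll, th[1], th[2])
      expect_equal(
        partition_of(cl),
        bf_union_find(coll$pathway_id, ed$from, ed$to),
        info = sprintf("seed %d t1 %.1f t2 %.1f", seed, th[1], th[2])
      )
    }
  }
})

test_that("clustering is independent of input pathway order", {
  for (seed in 1:3) {
    coll <- random_collection(15, universe_size = 25, size_range = c(3, 9),
                              seed = 200 + seed)
    cl <- build_superpaths(coll, t1 = 0.3, t2 = 0.7)
    perm <- withr::with_seed(seed, sample(nrow(coll)))
    cl_p <- build_superpaths(as_tibble(coll)[perm, ] |> pathway_collection(),
                             t1 = 0.3, t2 = 0.7)
    expect_equal(tidy(cl), tidy(cl_p))
  }
})

test_that("t1 = t2 reduces to single-linkage merging plus absorption/identity", {
  for (seed in 4:6) {
    coll <- random_collection(14, universe_size = 22, size_range = c(3, 8),
                              seed = 300 + seed)
    for (T in c(0.3, 0.5, 0.7)) {
      cl <- build_superpaths(coll, t1 = T, t2 = T)
      bf <- bf_jaccard_edges(coll, T)
      ab <- preprocess_absorption(coll)
      idg <- identical_groups(coll)
      idg <- idg[lengths(idg) >= 2]
      id_from <- unlist(lapply(idg, function(g) g[-length(g)]))
      id_to <- unlist(lapply(idg, function(g) g[-1]))
      expect_equal(
        partition_of(cl),
        bf_union_find(coll$pathway_id,
                      c(bf$from, ab$small, id_from),
                      c(bf$to, ab$large, id_to)),
        info = sprintf("seed %d T %.1f", seed, T)
      )
    }
  }
})

test_that("lowering either threshold never increases the cluster count", {
  coll <- random_collection(20, universe_size = 30, size_range = c(3, 10), seed = 11)
  n_at <- function(t1, t2) nrow(build_superpaths(coll, t1, t2)$superpaths)
  counts_t2 <- vapply(seq(0.3, 0.9, 0.2), function(t2) n_at(0.3, t2), double(1))
  expect_true(all(diff(counts_t2) >= 0))
  counts_t1 <- vapply(seq(0.3, 0.7, 0.2), function(t1) n_at(t1, 0.7), double(1))
  expect_true(all(diff(counts_t1) >= 0))
})

test_that("hubs are the most connected members, larger pathway breaking ties", {
  star <- make_coll(list(
    HUB = g_ids(1:12),
    L1 = c(g_ids(1:6), g_ids(31:32)),
    L2 = c(g_ids(4:9), g_ids(41:42)),
    L3 = c(g_ids(7:12), g_ids(51:52))
  ))
  cl <- build_superpaths(star, t1 = 0.3, t2 = 0.9)
  expect_equal(nrow(cl$superpaths), 1)
  expect_equal(cl$superpaths$hub, "HUB")
  expect_equal(cl$superpaths$name, "pathway HUB")

  pair <- make_coll(list(BIG = g_ids(1:40), SMALL = g_ids(1:25)))
  cl2 <- build_superpaths(pair, t1 = 0.3, t2 = 0.9)
  expect_equal(cl2$superpaths$hub, "BIG")  # equal degree, more genes wins

  lone <- build_superpaths(make_coll(list(ONLY = g_ids(1:5))), 0.3, 0.7)
  expect_equal(lone$superpaths$hub, "ONLY")
})

test_that("superpath unions, support counts and exports are consistent", {
  coll <- random_collection(15, universe_size = 25, size_range = c(3, 9), seed = 21)
  cl <- build_superpaths(coll, t1 = 0.3, t2 = 0.6)
  # genes = union of member sets
  for (k in seq_len(nrow(cl$superpaths))) {
    sid <- cl$superpaths$superpath_id[k]
    members <- cl$membership$pathway_id[cl$membership$superpath_id == sid]
    expect_setequal(
      cl$superpaths$genes[[k]],
      unique(unlist(coll$genes[match(members, coll$pathway_id)]))
    )
  }
  sup <- superpath_support(cl)
  expect_true(all(sup$n_pathways >= 1))
  n_members <- stats::setNames(cl$superpaths$n_members, cl$superpaths$superpath_id)
  expect_true(all(sup$n_pathways <= n_members[sup$superpath_id]))
  expect_true(all(sup$fraction > 0 & sup$fraction <= 1))

  path <- withr::local_tempfile(fileext = ".gmt")
  write_superpath_gmt(cl, path)
  back <- read_gmt(path)
  expect_equal(back$pathway_id, cl$superpaths$superpath_id)
  expect_true(all(back$source == "SuperPath"))
  expect_equal(back$genes, unname(cl$superpaths$genes))

  td <- tidy(cl)
  expect_setequal(td$pathway_id, coll$pathway_id)
  expect_equal(sum(td$role == "hub"), nrow(cl$superpaths))
  gl <- glance(cl)
  expect_equal(gl$n_superpaths, nrow(cl$superpaths))
  expect_equal(gl$n_singletons, sum(cl$superpaths$n_members == 1))
})
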