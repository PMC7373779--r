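example_edges <- function() {
  data.frame(biomarker_id = c("B1", "B1", "B2"),
             target_id = c("T1", "T2", "T1"),
             pkd = c(6.0, 7.0, 5.6), stringsAsFactors = FALSE)
}

test_that("dswmp_score matches the worked example in every mode", {
  e <- example_edges()
  s <- dswmp_score(e, c("T1", "T2"), "contributing_biomarkers")
  expect_equal(as.numeric(s), (6.0 + 7.0 + 5.6) / 2)  # 9.3
  expect_identical(nrow(attr(s, "contributing_edges")), 3L)
  # untouched pathway scores a legal zero
  s0 <- dswmp_score(e, "T9", "contributing_biomarkers")
  expect_equal(as.numeric(s0), 0)
  expect_identical(nrow(attr(s0, "contributing_edges")), 0L)
  # empty member set is an error, distinct from zero
  expect_error(dswmp_score(e, character(0)), "empty member set")
  # the other denominators
  expect_equal(as.numeric(dswmp_score(e, c("T1", "T2"), "n_biomarkers")),
               18.6 / 2)
  expect_equal(as.numeric(dswmp_score(e, c("T1", "T2"), "n_biomarkers",
                                      n_biomarkers = 36)), 18.6 / 36)
  expect_equal(
    as.numeric(dswmp_score(e, c("T1", "T2"), "per_biomarker_edge_count")),
    (6.0 + 7.0) / 2 + 5.6 / 1)
})

test_that("score is linear in edge weights and recomputable from provenance", {
  e <- example_edges()
  for (mode in c("contributing_biomarkers", "n_biomarkers",
                 "per_biomarker_edge_count")) {
    s1 <- dswmp_score(e, c("T1", "T2"), mode)
    e2 <- e; e2$pkd <- e$pkd * 2
    expect_equal(as.numeric(dswmp_score(e2, c("T1", "T2"), mode)),
                 2 * as.numeric(s1))
    ce <- attr(s1, "contributing_edges")
    expect_equal(as.numeric(dswmp_score(ce, c("T1", "T2"), mode)),
                 as.numeric(s1))
  }
})

test_that("dswmp_score equals the brute-force double loop on random studies", {
  for (i in 1:25) {
    m <- random_edge_set(i, n_bio = sample(3:12, 1), n_tar = sample(5:25, 1))
    edges <- threshold_edges(m)
    if (nrow(edges) == 0) next
    members <- sample(colnames(m), sample(2:ncol(m), 1))
    for (mode in c("contributing_biomarkers", "n_biomarkers",
                   "per_biomarker_edge_count")) {
      expect_equal(as.numeric(dswmp_score(edges, members, mode)),
                   brute_dswmp(edges, members, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("n_biomarkers mode is additive over disjoint member sets and monotone", {
  set.seed(31)
  m <- random_edge_set(31, n_bio = 10, n_tar = 20)
  edges <- threshold_edges(m)
  tp_a <- colnames(m)[1:8]; tp_b <- colnames(m)[9:20]
  sa <- as.numeric(dswmp_score(edges, tp_a, "n_biomarkers", n_biomarkers = 10))
  sb <- as.numeric(dswmp_score(edges, tp_b, "n_biomarkers", n_biomarkers = 10))
  sab <- as.numeric(dswmp_score(edges, c(tp_a, tp_b), "n_biomarkers",
                                n_biomarkers = 10))
  expect_equal(sab, sa + sb)
  # removing any edge never increases the score (fixed denominator)
  for (k in sample(nrow(edges), min(10, nrow(edges)))) {
    s_drop <- as.numeric(dswmp_score(edges[-k, ], c(tp_a, tp_b),
                                     "n_biomarkers", n_biomarkers = 10))
    expect_lte(s_drop, sab)
  }
})

test_that("permuting edge row order changes no score or ranking", {
  b <- toy_bundle()
  edges <- threshold_edges(b$scores)
  shuffled <- edges[sample(nrow(edges)), ]
  per_sys <- list(nervous = edges, immune = edges, endocrine = edges)
  per_sys_shuf <- list(nervous = shuffled, immune = shuffled,
                       endocrine = shuffled)
  s1 <- score_all_pathways(per_sys, b$pathways)
  s2 <- score_all_pathways(per_sys_shuf, b$pathways)
  expect_equal(s1, s2)
})

test_that("score_all_pathways orders deterministically, ties broken by id", {
  edges <- data.frame(biomarker_id = c("B1", "B1"),
                      target_id = c("T1", "T2"),
                      pkd = c(6.0, 6.0), stringsAsFactors = FALSE)
  pw <- data.frame(
    pathway_id = c("hsa00002", "hsa00001"),
    pathway_name = c("later id", "earlier id"),
    target_id = c("T2", "T1"), stringsAsFactors = FALSE)
  s <- score_all_pathways(list(nervous = edges), pw)
  expect_equal(s$score[1], s$score[2])          # identical scores
  expect_identical(s$pathway_id, c("hsa00001", "hsa00002"))  # id ascending
  expect_error(score_all_pathways(list(nervous = edges), pw[0, ]),
               "empty")
})

test_that("top_k_pathways truncates per system", {
  b <- gen_study(simulation_spec(seed = 6))
  edges <- threshold_edges(b$scores)
  nets <- lapply(setNames(SYSTEMS, SYSTEMS),
                 function(s) build_mti_network(edges, s, b$targets))
  per_sys <- lapply(nets, function(n) {
    data.frame(biomarker_id = n$edges$left, target_id = n$edges$right,
               pkd = n$edges$weight, stringsAsFactors = FALSE)
  })
  scores <- score_all_pathways(per_sys, b$pathways)
  top <- top_k_pathways(scores, 10)
  counts <- table(top$system)
  positive <- tapply(scores$score > 0, scores$system, sum)
  for (sys in SYSTEMS) {
    expect_identical(unname(counts[sys]),
                     as.integer(min(10, sum(scores$system == sys))))
    if (positive[sys] >= 10) expect_true(all(top$score[top$system == sys] > 0))
  }
  expect_identical(nrow(top_k_pathways(scores[1:3, ], 10)), 3L)
  t1 <- top_k_pathways(scores, 1)
  for (sys in SYSTEMS) {
    expect_equal(t1$score[t1$system == sys],
                 max(scores$score[scores$system == sys]))
  }
  expect_error(top_k_pathways(scores, 0), ">= 1")
})

test_that("cross_system_overlap classifies by top-list membership", {
  mk_top <- function(sys, ids) {
    data.frame(system = sys, pathway_id = ids,
               pathway_name = paste("pw", ids),
               score = rev(seq_along(ids)), rank = seq_along(ids),
               stringsAsFactors = FALSE)
  }
  same <- do.call(rbind, lapply(SYSTEMS, mk_top,
                                ids = c("hsa00001", "hsa00002")))
  ov <- cross_system_overlap(same)
  expect_true(all(ov$classes$n_systems == 3L))

  disjoint <- rbind(mk_top("nervous", "hsa00001"),
                    mk_top("immune", "hsa00002"),
                    mk_top("endocrine", "hsa00003"))
  expect_true(all(cross_system_overlap(disjoint)$classes$n_systems == 1L))

  # three lists sharing exactly two pathways -> class-3 set of size 2
  shared2 <- rbind(
    mk_top("nervous", c("hsa04151", "hsa04150", "hsa00010")),
    mk_top("immune", c("hsa04151", "hsa04150", "hsa00020")),
    mk_top("endocrine", c("hsa04150", "hsa04151", "hsa00030")))
  cls <- cross_system_overlap(shared2)$classes
  expect_setequal(cls$pathway_id[cls$n_systems == 3L],
                  c("hsa04150", "hsa04151"))
  # alluvial table has one row per (system, pathway) presence
  expect_identical(nrow(cross_system_overlap(shared2)$alluvial), 9L)
})
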