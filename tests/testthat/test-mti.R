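test_that("threshold_edges applies the strict boundary exactly", {
  m <- matrix(5.53, 1, 1, dimnames = list("B1", "T1"))
  expect_identical(nrow(threshold_edges(m, threshold_rule(5.52))), 1L)
  m[1, 1] <- 5.52
  expect_identical(nrow(threshold_edges(m, threshold_rule(5.52))), 0L)
  expect_identical(
    nrow(threshold_edges(m, threshold_rule(5.52, "greater_equal"))), 1L)
  m[1, 1] <- NA  # missing never passes, under either comparator
  expect_identical(nrow(threshold_edges(m, threshold_rule(5.52))), 0L)
  expect_identical(
    nrow(threshold_edges(m, threshold_rule(5.52, "greater_equal"))), 0L)
})

test_that("thresholds outside the calibrated range warn", {
  expect_warning(threshold_rule(7.0), "calibrated range")
  expect_warning(threshold_rule(4.0), "calibrated range")
  expect_no_warning(threshold_rule(5.52))
  expect_no_warning(threshold_rule(4.82))
})

test_that("threshold monotonicity and comparator consistency hold", {
  for (i in 1:30) {
    m <- random_edge_set(i)
    lo <- suppressWarnings(threshold_edges(m, threshold_rule(3.0)))
    hi <- threshold_edges(m, threshold_rule(6.0))
    key <- function(e) paste(e$biomarker_id, e$target_id)
    expect_true(all(key(hi) %in% key(lo)))
    ge <- threshold_edges(m, threshold_rule(5.52, "greater_equal"))
    gt <- threshold_edges(m, threshold_rule(5.52, "greater"))
    expect_true(all(key(gt) %in% key(ge)))
  }
})

test_that("build_mti_network restricts to the system and drops isolates", {
  b <- toy_bundle()
  edges <- threshold_edges(b$scores)  # (B1,T1,6.0) (B1,T2,7.0) (B2,T1,5.6) (B2,T3,6.1)
  nerv <- build_mti_network(edges, "nervous", b$targets)
  expect_identical(nrow(nerv$edges), 4L)  # all targets are in nervous
  imm <- build_mti_network(edges, "immune", b$targets)
  # only T2 (nervous+immune) and T3 (all three) are immune
  expect_setequal(imm$right_nodes, c("T00002", "T00003"))
  endo <- build_mti_network(edges, "endocrine", b$targets)
  expect_setequal(endo$right_nodes, "T00003")
  expect_setequal(endo$left_nodes, "HMDB0000002")  # B1 dropped: no endocrine edge
  # a target in all three systems appears in all three networks
  expect_true(all(vapply(list(nerv, imm, endo),
                         function(n) "T00003" %in% n$right_nodes,
                         logical(1))))
  expect_error(build_mti_network(edges, "digestive", b$targets),
               "unknown system")
  # edge weights preserved
  expect_equal(nerv$edges$weight[nerv$edges$left == "HMDB0000001" &
                                   nerv$edges$right == "T00001"], 6.0)
})

test_that("summarize_network reproduces printed fixture means", {
  n1 <- gen_fixture_network(fixture_spec(13, 78, 232, seed = 7))
  s1 <- summarize_network(n1)
  expect_equal(s1$mean_right_per_left_rounded, 17.85)
  expect_equal(s1$mean_left_per_right_rounded, 2.97)
  expect_equal(s1$mean_right_per_left * s1$n_left, s1$n_edges)
  expect_equal(s1$mean_left_per_right * s1$n_right, s1$n_edges)

  s2 <- summarize_network(gen_fixture_network(fixture_spec(13, 37, 107,
                                                           seed = 7)))
  expect_equal(s2$mean_right_per_left_rounded, 8.23)
  expect_equal(s2$mean_left_per_right_rounded, 2.89)

  s3 <- summarize_network(gen_fixture_network(fixture_spec(2, 3, 6)))
  expect_equal(s3$mean_right_per_left_rounded, 3.00)
  expect_equal(s3$mean_left_per_right_rounded, 2.00)
})

test_that("summarizing an empty network reports flagged zeros", {
  s <- summarize_network(bipartite_network(NULL, right_role = "target"))
  expect_true(s$empty)
  expect_identical(s$n_edges, 0L)
  expect_equal(s$mean_right_per_left, 0)
  expect_equal(s$mean_left_per_right, 0)
})

test_that("system_membership_classes partitions targets correctly", {
  b <- toy_bundle()
  cls <- system_membership_classes(b$targets)
  expect_identical(cls$n_systems[cls$target_id == "T00001"], 1L)
  expect_identical(cls$class_color[cls$target_id == "T00001"], "blue")
  expect_identical(cls$n_systems[cls$target_id == "T00002"], 2L)
  expect_identical(cls$class_color[cls$target_id == "T00002"], "yellow")
  expect_identical(cls$n_systems[cls$target_id == "T00003"], 3L)
  expect_identical(cls$class_color[cls$target_id == "T00003"], "red")
  expect_identical(unname(attr(cls, "counts")), c(1L, 1L, 1L))
  bad <- b$targets; bad$systems[[2]] <- character(0)
  expect_error(system_membership_classes(bad), "empty systems set")
})

test_that("shared_targets is the exact three-way intersection", {
  mk <- function(rights) {
    bipartite_network(data.frame(left = "B001", right = rights),
                      right_role = "target")
  }
  expect_identical(
    shared_targets(list(mk(c("T1", "T2")), mk(c("T3")), mk(c("T4")))),
    character(0))
  full <- list(mk(c("T1", "T2")), mk(c("T1", "T2")), mk(c("T2", "T1")))
  expect_identical(shared_targets(full), c("T1", "T2"))
  expect_error(shared_targets(full[1:2]), "three networks")
})

test_that("a study built with all-system all-passing targets shares them", {
  # nine targets in all three systems, each with a passing edge: the
  # generator contract behind the printed nine-shared-targets intersection
  b <- gen_study(simulation_spec(seed = 5))
  cls <- system_membership_classes(b$targets)
  triple <- cls$target_id[cls$n_systems == 3]
  expect_identical(length(triple), 9L)
  b$scores[1, triple] <- 6.5  # biomarker 1 binds all nine
  edges <- threshold_edges(b$scores)
  nets <- lapply(setNames(SYSTEMS, SYSTEMS),
                 function(s) build_mti_network(edges, s, b$targets))
  expect_true(all(triple %in% shared_targets(nets)))
})
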