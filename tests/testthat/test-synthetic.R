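test_that("default synthetic study has the stated shape", {
  b <- gen_study(simulation_spec(seed = 1))
  expect_identical(nrow(b$biomarkers), 36L)
  expect_identical(nrow(b$enzymes), 350L)
  sys_count <- function(sys) {
    sum(vapply(b$targets$systems, function(s) sys %in% s, logical(1)))
  }
  expect_identical(sys_count("nervous"), 155L)
  expect_identical(sys_count("immune"), 60L)
  expect_identical(sys_count("endocrine"), 125L)
  cls <- system_membership_classes(b$targets)
  expect_identical(unname(attr(cls, "counts")[["3"]]), 9L)
  iss <- validate_study(b)
  expect_identical(nrow(iss[iss$severity == "error", ]), 0L)
})

test_that("gen_study is deterministic in the seed", {
  a <- gen_study(simulation_spec(seed = 7))
  b <- gen_study(simulation_spec(seed = 7))
  expect_identical(a, b)
  c <- gen_study(simulation_spec(seed = 8))
  expect_false(identical(a$scores, c$scores))
  expect_false(identical(a$relations, c$relations))
})

test_that("writing the same simulated study twice is byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_bundle(gen_study(simulation_spec(seed = 3)), d1)
  write_study_bundle(gen_study(simulation_spec(seed = 3)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
})

test_that("pass_fraction 0 yields empty MTI networks downstream", {
  b <- gen_study(simulation_spec(scores = score_model(pass_fraction = 0),
                                 seed = 2))
  edges <- threshold_edges(b$scores)
  expect_identical(nrow(edges), 0L)
  net <- build_mti_network(edges, "nervous", b$targets)
  expect_identical(nrow(net$edges), 0L)
  expect_true(summarize_network(net)$empty)
})

test_that("infeasible system overlaps fail before any sampling", {
  expect_error(
    simulation_spec(system_sizes = c(nervous = 10, immune = 60,
                                     endocrine = 125),
                    triple_overlap = 9),
    "infeasible system overlaps")
})

test_that("gen_fixture_network hits exact node and edge counts", {
  net <- gen_fixture_network(fixture_spec(13, 78, 232, seed = 7))
  expect_identical(length(net$left_nodes), 13L)
  expect_identical(length(net$right_nodes), 78L)
  expect_identical(nrow(net$edges), 232L)
  # saturated case is the complete bipartite graph whatever the seed
  for (s in 1:3) {
    k22 <- gen_fixture_network(fixture_spec(2, 2, 4, seed = s))
    expect_identical(nrow(k22$edges), 4L)
    expect_setequal(paste(k22$edges$left, k22$edges$right),
                    c("B001 T001", "B001 T002", "B002 T001", "B002 T002"))
  }
  expect_error(gen_fixture_network(fixture_spec(5, 3, 2)),
               "max\\(n_left, n_right\\)")
  expect_error(gen_fixture_network(fixture_spec(2, 2, 5)), "n_left \\* n_right")
})

test_that("fixture networks satisfy degree sums and have no isolated node", {
  set.seed(99)
  for (i in 1:25) {
    nl <- sample(2:15, 1); nr <- sample(2:15, 1)
    ne <- sample(max(nl, nr):(nl * nr), 1)
    net <- gen_fixture_network(fixture_spec(nl, nr, ne, seed = i))
    degL <- node_degrees(net, "biomarker")$degree
    degR <- node_degrees(net, "target")$degree
    expect_identical(sum(degL), ne)
    expect_identical(sum(degR), ne)
    expect_true(all(degL >= 1) && all(degR >= 1))
  }
})

test_that("attach_scores + threshold_edges round-trips the edge set", {
  net <- gen_fixture_network(fixture_spec(13, 78, 232, seed = 7))
  m <- attach_scores(net, score_model(), seed = 7)
  edges <- threshold_edges(m, threshold_rule(5.52, "greater"))
  expect_identical(nrow(edges), 232L)
  expect_setequal(paste(edges$biomarker_id, edges$target_id),
                  paste(net$edges$left, net$edges$right))
})

test_that("attach_scores rejects degenerate models and empty networks", {
  expect_error(score_model(sd_above = -1), "standard deviations")
  empty <- bipartite_network(NULL, right_role = "target")
  expect_error(attach_scores(empty, score_model(), seed = 1),
               "empty network")
})

test_that("empirical pass fraction tracks the configured one", {
  spec <- simulation_spec(n_biomarkers = 13,
                          system_sizes = c(nervous = 80, immune = 40,
                                           endocrine = 60),
                          triple_overlap = 5,
                          pair_overlaps = c(nervous.immune = 3,
                                            nervous.endocrine = 5,
                                            immune.endocrine = 3),
                          scores = score_model(pass_fraction = 0.3),
                          seed = 1)
  pass <- 0; cells <- 0
  for (s in 1:50) {
    sp <- spec; sp$seed <- s
    b <- gen_study(sp)
    pass <- pass + sum(b$scores > 5.52, na.rm = TRUE)
    cells <- cells + sum(!is.na(b$scores))
  }
  se <- sqrt(0.3 * 0.7 / cells)
  expect_lt(abs(pass / cells - 0.3), 3 * se)
})
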