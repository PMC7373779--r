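# Deterministic substream derivation: one global seed, a fixed offset per
# generator component, so adding a component never perturbs earlier draws.
seed_stream <- function(seed, component) {
  offsets <- c(biomarkers = 1L, enzymes = 2L, relations = 3L, targets = 4L,
               pathways = 5L, scores = 6L, fixture = 7L, attach = 8L)
  off <- offsets[[component]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

# truncated normal sampler via inverse-CDF; bounds may be +-Inf
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Docking-score model for the synthetic generator
#'
#' A two-component truncated-normal mixture around the retention threshold:
#' a biomarker-target pair passes with probability `pass_fraction`, in which
#' case its pKd is drawn from N(`mu_above`, `sd_above`) truncated to values
#' strictly above `threshold`; otherwise from N(`mu_below`, `sd_below`)
#' truncated to [0, `threshold`]. The simplest model with a directly
#' controllable pass fraction. The default pass fraction 0.05 reproduces the
#' sparsity regime of the depression study (232 retained edges out of a
#' 36 x 155 nervous-system matrix is ~4%).
#'
#' @param pass_fraction probability a pair scores above threshold.
#' @param threshold retention threshold in pKd (default 5.52).
#' @param mu_above,sd_above above-threshold component (default N(6.5, 0.5)).
#' @param mu_below,sd_below below-threshold component (default N(4.0, 1.0)).
#' @param missing_fraction probability a below-threshold cell is recorded as
#'   missing (NA) instead of a value (default 0).
#' @return object of class `score_model`.
#' @export
score_model <- function(pass_fraction = 0.05, threshold = 5.52,
                        mu_above = 6.5, sd_above = 0.5,
                        mu_below = 4.0, sd_below = 1.0,
                        missing_fraction = 0) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1)
  if (sd_above < 0 || sd_below < 0) {
    stop("score model standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(pass_fraction = pass_fraction, threshold = threshold,
                 mu_above = mu_above, sd_above = sd_above,
                 mu_below = mu_below, sd_below = sd_below,
                 missing_fraction = missing_fraction),
            class = "score_model")
}

#' Specification of a synthetic study
#'
#' Defaults emulate the shape of the depression plasma-metabolomics study:
#' 36 biomarkers, 350 enzymes with a skewed biomarker-degree distribution,
#' three overlapping target systems of sizes 155 (nervous), 60 (immune) and
#' 125 (endocrine) with nine targets shared by all three, and a docking
#' matrix in which ~5% of pairs clear the 5.52 pKd threshold.
#'
#' @param n_biomarkers biomarker count (default 36).
#' @param n_enzymes enzyme count (default 350).
#' @param enzyme_degree_law `"powerlaw"` (default) or `"uniform"` law for
#'   the number of biomarkers each enzyme relates to.
#' @param degree_exponent power-law exponent (default 2).
#' @param max_enzyme_degree cap on biomarkers per enzyme (default 8).
#' @param up_fraction probability a biomarker trends up (default 0.4;
#'   most biomarkers in the motivating study were down-regulated).
#' @param system_sizes named triple of target-set sizes
#'   (default nervous 155, immune 60, endocrine 125).
#' @param triple_overlap targets in all three systems (default 9).
#' @param pair_overlaps targets in exactly two systems, named
#'   `nervous.immune`, `nervous.endocrine`, `immune.endocrine`.
#' @param n_pathways pathway count (default 30).
#' @param pathway_size_range min/max member targets per pathway.
#' @param scores a [score_model()].
#' @param seed global integer seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_biomarkers = 36L, n_enzymes = 350L,
                            enzyme_degree_law = c("powerlaw", "uniform"),
                            degree_exponent = 2,
                            max_enzyme_degree = 8L,
                            up_fraction = 0.4,
                            system_sizes = c(nervous = 155L, immune = 60L,
                                             endocrine = 125L),
                            triple_overlap = 9L,
                            pair_overlaps = c(nervous.immune = 6L,
                                              nervous.endocrine = 15L,
                                              immune.endocrine = 5L),
                            n_pathways = 30L,
                            pathway_size_range = c(5L, 40L),
                            scores = score_model(),
                            seed = 1L) {
  enzyme_degree_law <- match.arg(enzyme_degree_law)
  stopifnot(n_biomarkers >= 1, n_enzymes >= 1, n_pathways >= 1,
            up_fraction >= 0, up_fraction <= 1,
            length(system_sizes) == 3, length(pair_overlaps) == 3,
            triple_overlap >= 0, all(pair_overlaps >= 0),
            pathway_size_range[1] >= 1,
            pathway_size_range[2] >= pathway_size_range[1])
  names(system_sizes) <- SYSTEMS
  names(pair_overlaps) <- c("nervous.immune", "nervous.endocrine",
                            "immune.endocrine")
  only <- c(
    nervous = system_sizes[["nervous"]] - triple_overlap -
      pair_overlaps[["nervous.immune"]] - pair_overlaps[["nervous.endocrine"]],
    immune = system_sizes[["immune"]] - triple_overlap -
      pair_overlaps[["nervous.immune"]] - pair_overlaps[["immune.endocrine"]],
    endocrine = system_sizes[["endocrine"]] - triple_overlap -
      pair_overlaps[["nervous.endocrine"]] - pair_overlaps[["immune.endocrine"]]
  )
  if (any(only < 0)) {
    stop(sprintf(
      "infeasible system overlaps: single-system residuals (%s) are negative",
      paste(sprintf("%s=%d", names(only), only), collapse = ", ")),
      call. = FALSE)
  }
  structure(
    list(n_biomarkers = as.integer(n_biomarkers),
         n_enzymes = as.integer(n_enzymes),
         enzyme_degree_law = enzyme_degree_law,
         degree_exponent = degree_exponent,
         max_enzyme_degree = as.integer(max_enzyme_degree),
         up_fraction = up_fraction,
         system_sizes = system_sizes,
         triple_overlap = as.integer(triple_overlap),
         pair_overlaps = pair_overlaps,
         single_only = only,
         n_pathways = as.integer(n_pathways),
         pathway_size_range = as.integer(pathway_size_range),
         scores = scores,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Generate a synthetic study bundle
#'
#' Draws a complete study (biomarker catalog, enzyme catalog with skewed
#' relation degrees, overlapping per-system target sets, multi-pathway
#' memberships, docking-score matrix) from a [simulation_spec()]. The output
#' passes [validate_study()] with zero errors, is byte-identical for a fixed
#' spec and seed, and its empirical above-threshold score fraction converges
#' to the model's `pass_fraction`.
#'
#' @param spec a `simulation_spec`
#' @return a `study_bundle`.
#' @export
gen_study <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- spec$seed

  # biomarkers
  set.seed(seed_stream(seed, "biomarkers"))
  bio <- data.frame(
    id = sprintf("HMDB9%06d", seq_len(spec$n_biomarkers)),
    name = sprintf("synthetic metabolite %02d", seq_len(spec$n_biomarkers)),
    platform = sample(PLATFORMS[1:3], spec$n_biomarkers, replace = TRUE),
    trend = ifelse(stats::runif(spec$n_biomarkers) < spec$up_fraction,
                   "up", "down"),
    stringsAsFactors = FALSE
  )

  # enzymes with function categories
  set.seed(seed_stream(seed, "enzymes"))
  cat_pool <- c("Hydrolase", "Transferase", "Acyltransferase",
                "Oxidoreductase", "Lyase", "Ligase", "Isomerase",
                "Aminotransferase")
  cat_w <- c(8, 6, 5, 3, 2, 1, 1, 1)
  enz <- data.frame(
    id = sprintf("E%05d", seq_len(spec$n_enzymes)),
    name = sprintf("synthetic enzyme %03d", seq_len(spec$n_enzymes)),
    stringsAsFactors = FALSE
  )
  enz$functions <- lapply(seq_len(spec$n_enzymes), function(i) {
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    sort(sample(cat_pool, k, prob = cat_w))
  })

  # relations: enzyme degrees from the chosen law; biomarker attachment
  # weights Zipf-skewed so a few biomarkers become hubs
  set.seed(seed_stream(seed, "relations"))
  kmax <- min(spec$max_enzyme_degree, spec$n_biomarkers)
  deg <- if (spec$enzyme_degree_law == "powerlaw") {
    sample(seq_len(kmax), spec$n_enzymes, replace = TRUE,
           prob = seq_len(kmax)^(-spec$degree_exponent))
  } else {
    sample(seq_len(kmax), spec$n_enzymes, replace = TRUE)
  }
  bio_w <- (seq_len(spec$n_biomarkers))^(-1)  # Zipf attachment weights
  bs <- lapply(deg, function(d) sample(bio$id, d, prob = bio_w))
  rel <- data.frame(biomarker_id = unlist(bs, use.names = FALSE),
                    enzyme_id = rep(enz$id, deg),
                    stringsAsFactors = FALSE)
  rel <- rel[order(rel$biomarker_id, rel$enzyme_id), , drop = FALSE]
  rownames(rel) <- NULL

  # targets: membership regions laid out deterministically, then shuffled ids
  set.seed(seed_stream(seed, "targets"))
  region_sys <- c(
    rep(list(SYSTEMS), spec$triple_overlap),
    rep(list(c("nervous", "immune")), spec$pair_overlaps[["nervous.immune"]]),
    rep(list(c("nervous", "endocrine")),
        spec$pair_overlaps[["nervous.endocrine"]]),
    rep(list(c("immune", "endocrine")),
        spec$pair_overlaps[["immune.endocrine"]]),
    rep(list("nervous"), spec$single_only[["nervous"]]),
    rep(list("immune"), spec$single_only[["immune"]]),
    rep(list("endocrine"), spec$single_only[["endocrine"]])
  )
  n_targets <- length(region_sys)
  tar <- data.frame(
    id = sprintf("T%05d", seq_len(n_targets)),
    name = sprintf("synthetic target %03d", seq_len(n_targets)),
    stringsAsFactors = FALSE
  )
  tar$systems <- region_sys

  # pathways: each target can serve in many pathways (many-to-many)
  set.seed(seed_stream(seed, "pathways"))
  pw_ids <- sprintf("hsa%05d", 4000L + seq_len(spec$n_pathways))
  pw_rows <- lapply(seq_len(spec$n_pathways), function(i) {
    size <- sample(seq(spec$pathway_size_range[1],
                       min(spec$pathway_size_range[2], n_targets)), 1)
    members <- sort(sample(tar$id, size))
    data.frame(pathway_id = pw_ids[i],
               pathway_name = sprintf("synthetic pathway %02d", i),
               target_id = members, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw_rows)
  rownames(pw) <- NULL

  # docking scores: Bernoulli(pass) mixture of truncated normals
  set.seed(seed_stream(seed, "scores"))
  sm <- spec$scores
  ncell <- spec$n_biomarkers * n_targets
  pass <- stats::runif(ncell) < sm$pass_fraction
  vals <- numeric(ncell)
  n_above <- sum(pass)
  if (n_above > 0) {
    vals[pass] <- pmax(rtnorm(n_above, sm$mu_above, sm$sd_above,
                              lower = sm$threshold),
                       sm$threshold + 1e-9)
  }
  n_below <- sum(!pass)
  if (n_below > 0) {
    vals[!pass] <- pmin(pmax(rtnorm(n_below, sm$mu_below, sm$sd_below,
                                    lower = 0, upper = sm$threshold), 0),
                        sm$threshold)
  }
  if (sm$missing_fraction > 0) {
    drop <- !pass & stats::runif(ncell) < sm$missing_fraction
    vals[drop] <- NA_real_
  }
  scores <- matrix(vals, nrow = spec$n_biomarkers, ncol = n_targets,
                   dimnames = list(bio$id, tar$id))

  new_study_bundle(bio, enz, rel, tar, scores, pw)
}

#' Exact-shape bipartite fixture specification
#'
#' @param n_left,n_right partition sizes.
#' @param n_edges exact edge count; feasible iff
#'   `max(n_left, n_right) <= n_edges <= n_left * n_right` (every node must
#'   carry at least one edge and edges are distinct pairs).
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_left, n_right, n_edges, seed = 1L) {
  n_left <- as.integer(n_left); n_right <- as.integer(n_right)
  n_edges <- as.integer(n_edges)
  stopifnot(n_left >= 1, n_right >= 1)
  lo <- max(n_left, n_right); hi <- n_left * n_right
  if (n_edges < lo || n_edges > hi) {
    stop(sprintf(
      "infeasible fixture: need max(n_left, n_right) = %d <= n_edges <= n_left * n_right = %d, got n_edges = %d",
      lo, hi, n_edges), call. = FALSE)
  }
  structure(list(n_left = n_left, n_right = n_right, n_edges = n_edges,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a bipartite network with exact node and edge counts
#'
#' Produces a network with exactly `n_left` biomarker nodes, `n_right`
#' right-partition nodes and `n_edges` distinct edges, none isolated: a
#' cyclic spanning assignment first gives every node one edge, then the
#' remaining edges are sampled uniformly without replacement from the unused
#' pairs. Enables exact reproduction of printed network dimensions, e.g. the
#' 13-biomarker / 78-target / 232-edge nervous-system MTI network.
#'
#' @param spec a [fixture_spec()]
#' @param right_role `"target"` (default) or `"enzyme"`.
#' @return a `bipartite_network`.
#' @export
gen_fixture_network <- function(spec, right_role = "target") {
  stopifnot(inherits(spec, "fixture_spec"))
  nl <- spec$n_left; nr <- spec$n_right; ne <- spec$n_edges
  left_ids <- sprintf("B%03d", seq_len(nl))
  right_ids <- sprintf("%s%03d", if (right_role == "target") "T" else "E",
                       seq_len(nr))
  # cyclic spanning assignment: pairs (k mod nl, k mod nr) are distinct for
  # k < lcm(nl, nr) >= max(nl, nr), and cover every node on both sides
  k <- seq_len(max(nl, nr)) - 1L
  span <- cbind((k %% nl) + 1L, (k %% nr) + 1L)
  span_idx <- (span[, 1] - 1L) * nr + span[, 2]
  remaining <- ne - nrow(span)
  extra_idx <- integer(0)
  if (remaining > 0) {
    set.seed(seed_stream(spec$seed, "fixture"))
    pool <- setdiff(seq_len(nl * nr), span_idx)
    extra_idx <- sample(pool, remaining)
  }
  all_idx <- c(span_idx, extra_idx)
  edges <- data.frame(
    left = left_ids[((all_idx - 1L) %/% nr) + 1L],
    right = right_ids[((all_idx - 1L) %% nr) + 1L],
    stringsAsFactors = FALSE
  )
  net <- bipartite_network(edges, right_role = right_role)
  assert_handshake(net)
  stopifnot(length(net$left_nodes) == nl, length(net$right_nodes) == nr,
            nrow(net$edges) == ne)
  net
}

#' Attach docking scores to a fixture network
#'
#' Builds the biomarker x partner score matrix in which every network edge
#' receives a pKd strictly above the model threshold and every non-edge pair
#' a pKd at or below it (or NA). Thresholding the result with the strict
#' rule reconstructs the input network's edge set exactly.
#'
#' @param network a `bipartite_network`
#' @param model a [score_model()]
#' @param seed integer seed.
#' @return numeric matrix (rownames = left ids, colnames = right ids).
#' @export
attach_scores <- function(network, model = score_model(), seed = 1L) {
  stopifnot(inherits(network, "bipartite_network"))
  if (nrow(network$edges) == 0) {
    stop("cannot attach scores to an empty network", call. = FALSE)
  }
  set.seed(seed_stream(seed, "attach"))
  nl <- length(network$left_nodes); nr <- length(network$right_nodes)
  m <- matrix(pmin(pmax(rtnorm(nl * nr, model$mu_below, model$sd_below,
                               lower = 0, upper = model$threshold), 0),
                   model$threshold),
              nrow = nl, ncol = nr,
              dimnames = list(network$left_nodes, network$right_nodes))
  if (model$missing_fraction > 0) {
    drop <- matrix(stats::runif(nl * nr) < model$missing_fraction, nl, nr)
    m[drop] <- NA_real_
  }
  e <- network$edges
  m[cbind(e$left, e$right)] <- pmax(
    rtnorm(nrow(e), model$mu_above, model$sd_above, lower = model$threshold),
    model$threshold + 1e-9)
  m
}
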