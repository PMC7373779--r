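# shared fixtures and independent oracles, built in code at test time

# tiny hand-written study: 3 biomarkers, 2 enzymes, 3 targets, 2 pathways
toy_bundle <- function() {
  bio <- data.frame(
    id = c("HMDB0000001", "HMDB0000002", "HMDB0000003"),
    name = c("met one", "met two", "met three"),
    platform = c("GC-MS", "LC-MS", "1H-NMR"),
    trend = c("up", "down", "down"),
    stringsAsFactors = FALSE
  )
  enz <- data.frame(id = c("P11111", "P22222"),
                    name = c("enz one", "enz two"),
                    stringsAsFactors = FALSE)
  enz$functions <- list(c("Hydrolase"), c("Acyltransferase", "Transferase"))
  rel <- data.frame(
    biomarker_id = c("HMDB0000001", "HMDB0000001", "HMDB0000002"),
    enzyme_id = c("P11111", "P22222", "P11111"),
    stringsAsFactors = FALSE
  )
  tar <- data.frame(id = c("T00001", "T00002", "T00003"),
                    name = c("tar one", "tar two", "tar three"),
                    stringsAsFactors = FALSE)
  tar$systems <- list("nervous", c("nervous", "immune"),
                      c("nervous", "immune", "endocrine"))
  scores <- matrix(
    c(6.00, 7.00, 2.0,
      5.60, 1.00, 6.1,
      3.00, 2.00, 1.0),
    nrow = 3, byrow = TRUE,
    dimnames = list(bio$id, tar$id)
  )
  pw <- data.frame(
    pathway_id = c("hsa00001", "hsa00001", "hsa00002"),
    pathway_name = c("toy pathway A", "toy pathway A", "toy pathway B"),
    target_id = c("T00001", "T00002", "T00003"),
    stringsAsFactors = FALSE
  )
  dswmpnet:::new_study_bundle(bio, enz, rel, tar, scores, pw)
}

# independent brute-force DSWMP oracle: explicit double loop over all
# (biomarker, target) pairs, kept structurally unlike the implementation
brute_dswmp <- function(edges, members, count_mode, n_biomarkers = NULL) {
  bs <- unique(edges$biomarker_id)
  total <- 0
  contributing <- character(0)
  per_bio <- numeric(0)
  for (b in bs) {
    b_sum <- 0
    b_cnt <- 0
    for (t in unique(edges$target_id)) {
      hit <- edges$biomarker_id == b & edges$target_id == t
      if (any(hit) && t %in% members) {
        b_sum <- b_sum + sum(edges$pkd[hit])
        b_cnt <- b_cnt + sum(hit)
      }
    }
    if (b_cnt > 0) {
      contributing <- c(contributing, b)
      total <- total + b_sum
      per_bio[b] <- b_sum / b_cnt
    }
  }
  if (length(contributing) == 0) return(0)
  switch(count_mode,
         contributing_biomarkers = total / length(contributing),
         n_biomarkers = total /
           (if (is.null(n_biomarkers)) length(bs) else n_biomarkers),
         per_biomarker_edge_count = sum(per_bio))
}

# random thresholded edge list drawn from a random pKd matrix
random_edge_set <- function(seed, n_bio = 8, n_tar = 12, p_edge = 0.3,
                            threshold = 5.52) {
  set.seed(seed)
  m <- matrix(runif(n_bio * n_tar, 0, 9), n_bio, n_tar,
              dimnames = list(sprintf("B%02d", seq_len(n_bio)),
                              sprintf("T%02d", seq_len(n_tar))))
  # push a controlled fraction above threshold, rest below
  keep <- matrix(runif(n_bio * n_tar) < p_edge, n_bio, n_tar)
  m[keep] <- threshold + runif(sum(keep), 0.01, 3)
  m[!keep] <- runif(sum(!keep), 0, threshold)
  m
}
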