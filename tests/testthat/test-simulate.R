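test_that("Yule trees have the right shape and are seed-reproducible", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)  # a single cherry
  tr <- simulate_yule_tree(25, 1.5, seed = 9)
  expect_equal(ape::Ntip(tr), 25)
  expect_equal(tr$Nnode, 24)  # n - 1 internal nodes
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(ape::write.tree(simulate_yule_tree(25, 1.5, seed = 9)),
                   ape::write.tree(tr))
})

test_that("mean Yule depth matches the analytic expectation", {
  n <- 15; lambda <- 2
  depths <- vapply(1:400, function(i) {
    tr <- simulate_yule_tree(n, lambda, seed = 10000 + i)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  expected <- sum(1 / (lambda * (2:n)))
  expect_equal(mean(depths), expected, tolerance = 0.05)
})

test_that("sequence evolution respects rate zero and increases with depth", {
  tr <- simulate_yule_tree(10, 1, seed = 21)
  frozen <- evolve_sequences(tr, 120, substitution_rate = 0, seed = 3)
  expect_equal(length(unique(frozen$rows)), 1)
  mean_p <- vapply(c(0.02, 0.08, 0.2), function(rate) {
    al <- evolve_sequences(tr, 400, substitution_rate = rate, seed = 5)
    D <- seq_distance_matrix(al, "p")
    mean(D[upper.tri(D)])
  }, 0)
  expect_true(all(diff(mean_p) > 0))
})

test_that("JC-corrected distances are consistent with patristic distances", {
  tr <- ape::read.tree(text = "(a:0.08,b:0.07);")
  d_hat <- vapply(1:200, function(i) {
    al <- evolve_sequences(tr, 658, substitution_rate = 1, seed = 400 + i)
    seq_distance_matrix(al, "JC69")["a", "b"]
  }, 0)
  expect_equal(mean(d_hat), 0.15, tolerance = 0.1)
})

test_that("make_bins plants recoverable centroids and unique BINs", {
  tr <- simulate_yule_tree(60, 1, seed = 33)
  al <- evolve_sequences(tr, 658, substitution_rate = 0.05, seed = 34)
  bins <- make_bins(al, n_per_bin = 8, intrabin_divergence = 0.005, seed = 35)
  expect_equal(nrow(bins), 60 * 8)
  expect_equal(length(unique(bins$bin_id)), 60)
  expect_length(attr(bins, "planted_centroids"), 60)
  # recover the planted centroid per BIN
  recovered <- vapply(split(bins, bins$bin_id), function(b) {
    as.character(centroid(dna_alignment(b$record_id, b$sequence)))
  }, "")
  planted <- attr(bins, "planted_centroids")[names(recovered)]
  expect_gte(mean(recovered == planted), 0.95)
})

test_that("zero intra-BIN divergence gives identical copies and tie-breaks", {
  al <- dna_alignment(c("t1", "t2"), c(strrep("ACGT", 30), strrep("GTCA", 30)))
  bins <- make_bins(al, n_per_bin = 4, intrabin_divergence = 0, seed = 1)
  for (b in split(bins, bins$bin_id)) {
    expect_equal(length(unique(b$sequence)), 1)
    # all copies tie; lexicographically smallest record id wins = planted copy
    expect_equal(as.character(centroid(dna_alignment(b$record_id, b$sequence))),
                 min(b$record_id))
  }
})

test_that("lambda = 0 assembly is distributionally uniform in every mode", {
  tr <- simulate_yule_tree(20, 1, seed = 55)
  richness <- 5
  for (mode in c("neutral", "filtering", "repulsion")) {
    counts <- stats::setNames(numeric(20), tr$tip.label)
    n_draws <- 3000
    for (i in seq_len(n_draws)) {
      comm <- assemble_community(tr, richness, mode, lambda = 0,
                                 seed = 7000 + i)
      counts[comm] <- counts[comm] + 1
    }
    p0 <- richness / 20
    half <- 3.9 * sqrt(p0 * (1 - p0) / n_draws)  # ~99.99% band, 20 tips
    expect_true(all(abs(counts / n_draws - p0) <= half),
                label = paste("uniform inclusion under", mode))
  }
})

test_that("filtering assembly clusters communities increasingly with lambda", {
  tr <- simulate_yule_tree(60, 1, seed = 77)
  D <- tree_distance_matrix(tr)
  mean_ses <- vapply(c(1, 5), function(lam) {
    mean(vapply(1:200, function(i) {
      comm <- assemble_community(tr, 10, "filtering", lambda = lam,
                                 seed = 900 * lam + i)
      nri(D, comm, n_iter = 200, seed = 10000 + 900 * lam + i)$ses
    }, 0))
  }, 0)
  expect_gt(mean_ses[1], 0)
  expect_gt(mean_ses[2], mean_ses[1])
})

test_that("repulsion assembly overdisperses nearest-neighbor distances", {
  tr <- simulate_yule_tree(64, 1, seed = 88)
  D <- tree_distance_matrix(tr)
  ses_vals <- vapply(1:100, function(i) {
    comm <- assemble_community(tr, 12, "repulsion", lambda = 20,
                               seed = 20000 + i)
    nti(D, comm, n_iter = 200, seed = 30000 + i)$ses
  }, 0)
  # mean NTI significantly negative
  expect_lt(mean(ses_vals) + 2 * stats::sd(ses_vals) / 10, 0)
})

test_that("emit_bold_dataset plants faults with exact counts", {
  cfg <- sim_config(n_pool_tips = 30, community_richness = 8, n_per_bin = 4,
                    n_missing_bin = 5, n_missing_gps = 3, n_wrong_marker = 2,
                    n_short = 4, n_gappy = 2, seed = 61)
  sim <- emit_bold_dataset(cfg, tempfile(fileext = ".tsv"),
                           tempfile(fileext = ".fa"))
  out <- filter_records(read_records(sim$paths$metadata, sim$paths$fasta))
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep[c("no_bin", "no_coordinates", "wrong_marker",
                            "too_short", "too_ambiguous")]),
               c(5L, 3L, 2L, 4L, 2L))
  expect_equal(unname(rep["retained"]), 30L * 4L - 16L)
})

test_that("an all-clean synthetic dataset passes the filters untouched", {
  cfg <- sim_config(n_pool_tips = 20, community_richness = 6, n_per_bin = 3,
                    seed = 62)
  sim <- emit_bold_dataset(cfg, tempfile(fileext = ".tsv"),
                           tempfile(fileext = ".fa"))
  ds <- read_records(sim$paths$metadata, sim$paths$fasta)
  out <- filter_records(ds)
  expect_equal(nrow(out), nrow(ds))
  expect_equal(unname(attr(out, "filter_report")["retained"]), nrow(ds))
  # round trip: emitted files reproduce the in-memory dataset
  expect_equal(records_frame(ds)[order(ds$record_id), ],
               records_frame(sim$dataset)[order(sim$dataset$record_id), ])
})

test_that("local records fall inside the local box, others outside it", {
  cfg <- sim_config(n_pool_tips = 25, community_richness = 7, n_per_bin = 3,
                    seed = 63)
  sim <- emit_bold_dataset(cfg, tempfile(fileext = ".tsv"),
                           tempfile(fileext = ".fa"))
  ds <- sim$dataset
  box <- cfg$local_box
  in_box <- ds$lat >= box$lat_min & ds$lat <= box$lat_max &
    ds$lon >= box$lon_min & ds$lon <= box$lon_max
  is_comm <- ds$bin_id %in% sim$community_bins
  expect_equal(in_box, is_comm)
  expect_equal(sum(is_comm), 7 * 3)
})

test_that("simulation config validates its invariants", {
  expect_error(sim_config(n_pool_tips = 10, community_richness = 11),
               "community_richness")
  expect_error(sim_config(lambda = -1))
  cfg <- sim_config()
  expect_equal(cfg$seq_length, 658)
  expect_equal(cfg$assembly_mode, "neutral")
})
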