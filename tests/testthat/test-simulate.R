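test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_zcd_proteins(3, mu_c = 0.1, mu_u = 0.2, seed = 7)
  s2 <- simulate_zcd_proteins(3, mu_c = 0.1, mu_u = 0.2, seed = 7)
  expect_identical(s1, s2)
  expect_identical(simulate_decoys(5, 100, seed = 3), simulate_decoys(5, 100, seed = 3))
  tr <- balanced_tree6(0.2)
  expect_identical(evolve_along_tree(tr, 50, seed = 2),
                   evolve_along_tree(tr, 50, seed = 2))
  expect_identical(simulate_neighborhoods(3, seed = 4),
                   simulate_neighborhoods(3, seed = 4))
})

test_that("planted coordinates in the truth record match detection exactly", {
  sim <- simulate_zcd_proteins(5, mu_c = 0, mu_u = 0, seed = 19,
                               include_anchor = "full")
  hits <- detect_zcd(sim$sequences)
  expect_equal(nrow(hits), 5L)
  truth_zcd <- sim$truth[sim$truth$feature == "zcd", ]
  joined <- dplyr::left_join(truth_zcd, hits, by = "seq_id")
  expect_equal(joined$start.y, joined$start.x)
  expect_equal(joined$end.y, joined$end.x)
  anchors <- detect_ccys_anchor(sim$sequences, hits)
  expect_true(all(anchors$anchor_class == "full_mammal"))
  truth_anchor <- sim$truth[sim$truth$feature == "anchor_full", ]
  expect_equal(anchors$start, truth_anchor$start)
})

test_that("anchor variants plant the class the annotator reports", {
  for (spec in list(c("core", "sxxcc_core"), c("teleost", "single_cys"))) {
    sim <- simulate_zcd_proteins(3, seed = 23, include_anchor = spec[1])
    a <- detect_ccys_anchor(sim$sequences, detect_zcd(sim$sequences))
    expect_true(all(a$anchor_class == spec[2]), info = spec[1])
  }
})

test_that("fully randomizing constrained sites destroys detectability", {
  sim <- simulate_zcd_proteins(100, mu_c = 1, mu_u = 0, seed = 37)
  hits <- detect_zcd(sim$sequences)
  expect_lt(length(unique(hits$seq_id)) / 100, 0.02)
})

test_that("degenerate generator parameters are rejected", {
  expect_error(simulate_zcd_proteins(1, spacer_range1 = c(10L, 5L)), "ranges")
  expect_error(simulate_zcd_proteins(1, spacer_range2 = c(10L, 12L)), "spacer_range2")
  expect_error(simulate_decoys(0), ">= 1")
  expect_error(simulate_neighborhoods(1), "at least 2")
  expect_error(simulate_neighborhoods(2, shared_groups = paste0("OG", 1:11), k = 5),
               "window")
})

test_that("zero branch lengths copy the root to every leaf", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- random_aa(80)
  leaves <- evolve_along_tree(tr, root = root, seed = 5)
  expect_true(all(leaves$residues == root))
})

test_that("long branches drive divergence to the JTT stationary limit", {
  tr <- ape::read.tree(text = "(a:6,b:6);")
  leaves <- evolve_along_tree(tr, root = 3000, seed = 13)
  av <- strsplit(leaves$residues[1], "")[[1]]
  bv <- strsplit(leaves$residues[2], "")[[1]]
  p_obs <- mean(av != bv)
  p_expected <- 1 - sum(jtt_frequencies()^2)
  expect_equal(p_obs, p_expected, tolerance = 0.02)
})

test_that("only the JTT model and valid roots are accepted", {
  tr <- balanced_tree6(0.1)
  expect_error(evolve_along_tree(tr, 50, model = "WAG"), "JTT")
  expect_error(evolve_along_tree(tr, "MKXQ"), "standard residues")
  neg <- tr; neg$edge.length[1] <- -0.1
  expect_error(evolve_along_tree(neg, 50), "non-negative")
})

test_that("neighborhood plants stay within the requested window", {
  sim <- simulate_neighborhoods(4, shared_groups = c("A", "B"),
                                k_private = 8, k = 3, seed = 21)
  nb <- read_neighborhoods({
    f <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(sim$neighborhoods, f, progress = FALSE)
    f
  })
  for (i in seq_len(nrow(nb))) {
    w <- synteny_window(nb[i, ], k = 3)
    expect_true(all(c("A", "B") %in% w$ortholog_group))
  }
})
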