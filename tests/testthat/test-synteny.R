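write_nbhd_tsv <- function(tbl) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(tbl, f, progress = FALSE)
  f
}

minimal_nbhd <- function() {
  tibble::tibble(
    species = "sp1", scaffold = "s1",
    gene_id = c("g1", "g2", "g3"),
    ortholog_group = c("OG1", "OG_FOCAL", "OG2"),
    position = 1:3,
    focal_flag = c(FALSE, TRUE, FALSE)
  )
}

test_that("a minimal neighborhood file loads with its focal gene", {
  nb <- read_neighborhoods(write_nbhd_tsv(minimal_nbhd()))
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$focal_gene_id, "g2")
  expect_equal(nrow(nb$markers[[1]]), 3L)
})

test_that("focal-flag violations are reported by gene, unsorted rows warned", {
  dup <- minimal_nbhd()
  dup$focal_flag <- c(TRUE, TRUE, FALSE)
  expect_error(read_neighborhoods(write_nbhd_tsv(dup)), "g1, g2")
  none <- minimal_nbhd()
  none$focal_flag <- FALSE
  expect_error(read_neighborhoods(write_nbhd_tsv(none)), "no focal")
  shuf <- minimal_nbhd()[c(3, 1, 2), ]
  expect_warning(nb <- read_neighborhoods(write_nbhd_tsv(shuf)), "sorting")
  expect_identical(nb$markers[[1]],
                   read_neighborhoods(write_nbhd_tsv(minimal_nbhd()))$markers[[1]])
})

test_that("windows truncate at scaffold ends and never exceed 2k", {
  centered <- tibble::tibble(
    species = "sp1", scaffold = "s1",
    gene_id = paste0("g", 1:11),
    ortholog_group = paste0("OG", 1:11),
    position = 1:11,
    focal_flag = c(rep(FALSE, 5), TRUE, rep(FALSE, 5))
  )
  nb <- read_neighborhoods(write_nbhd_tsv(centered))
  w <- synteny_window(nb[1, ], k = 5)
  expect_equal(nrow(w), 10L)
  expect_false("g6" %in% w$gene_id)
  expect_equal(sum(w$side == "upstream"), 5L)
  # focal at the scaffold edge
  edge <- centered
  edge$focal_flag <- c(TRUE, rep(FALSE, 10))
  nb2 <- read_neighborhoods(write_nbhd_tsv(edge))
  w2 <- synteny_window(nb2[1, ], k = 5)
  expect_equal(nrow(w2), 5L)
  expect_true(all(w2$side == "downstream"))
  # property: window size bounded by 2k for random neighborhoods
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(3:25, 1)
    fi <- sample(n, 1)
    tb <- tibble::tibble(species = "sp", scaffold = "s",
                         gene_id = paste0("g", 1:n),
                         ortholog_group = paste0("OG", 1:n),
                         position = 1:n,
                         focal_flag = seq_len(n) == fi)
    k <- sample(1:6, 1)
    wr <- synteny_window(read_neighborhoods(write_nbhd_tsv(tb))[1, ], k = k)
    expect_lte(nrow(wr), 2 * k)
  }
})

test_that("shared-marker reports are symmetric and exclude the focal groups", {
  sim <- simulate_neighborhoods(2, shared_groups = c("OG_a", "OG_b"), seed = 11)
  nb <- read_neighborhoods(write_nbhd_tsv(sim$neighborhoods))
  wa <- synteny_window(nb[1, ]); wb <- synteny_window(nb[2, ])
  rep_ab <- shared_markers(wa, wb)
  rep_ba <- shared_markers(wb, wa)
  expect_equal(rep_ab$n_shared, 2L)
  expect_setequal(rep_ab$shared_groups[[1]], c("OG_a", "OG_b"))
  expect_identical(rep_ab$shared_groups, rep_ba$shared_groups)
  expect_identical(rep_ab$n_shared, rep_ba$n_shared)
  # the focal genes share OG_ZCD by construction, but it is excluded
  expect_false("OG_ZCD" %in% rep_ab$shared_groups[[1]])
  # disjoint windows
  sim0 <- simulate_neighborhoods(2, shared_groups = character(0), seed = 12)
  nb0 <- read_neighborhoods(write_nbhd_tsv(sim0$neighborhoods))
  rep0 <- shared_markers(synteny_window(nb0[1, ]), synteny_window(nb0[2, ]))
  expect_equal(rep0$n_shared, 0L)
  expect_false(rep0$conserved)
})

test_that("planted sharing yields a complete weight-2 graph, none an empty one", {
  sim <- simulate_neighborhoods(4, shared_groups = c("OG_a", "OG_b"), seed = 42)
  nb <- read_neighborhoods(write_nbhd_tsv(sim$neighborhoods))
  g <- synteny_graph(nb, k = 5, threshold = 1)
  expect_equal(nrow(g$edges), choose(4, 2))
  expect_true(all(g$edges$weight == 2L))
  expect_equal(max(g$components$component), 1L)
  g0 <- synteny_graph(
    read_neighborhoods(write_nbhd_tsv(
      simulate_neighborhoods(4, shared_groups = character(0), seed = 43)$neighborhoods)))
  expect_equal(nrow(g0$edges), 0L)
  expect_equal(max(g0$components$component), 4L)
  # threshold above the planted weight empties the graph
  g3 <- synteny_graph(nb, k = 5, threshold = 3)
  expect_equal(nrow(g3$edges), 0L)
})

test_that("adding an unrelated neighborhood never removes existing edges", {
  sim <- simulate_neighborhoods(3, shared_groups = c("OG_a", "OG_b"), seed = 5)
  lone <- simulate_neighborhoods(2, shared_groups = character(0), seed = 6)$neighborhoods
  lone <- lone[lone$species == "species_01", ]
  lone$species <- "species_99"; lone$scaffold <- "scaf_99"
  lone$gene_id <- sub("species_01", "species_99", lone$gene_id)
  lone$ortholog_group <- sub("species_01", "species_99", lone$ortholog_group)
  nb_small <- read_neighborhoods(write_nbhd_tsv(sim$neighborhoods))
  nb_big <- read_neighborhoods(write_nbhd_tsv(dplyr::bind_rows(sim$neighborhoods, lone)))
  e_small <- synteny_graph(nb_small)$edges
  e_big <- synteny_graph(nb_big)$edges
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to), e$weight)
  expect_true(all(key(e_small) %in% key(e_big)))
})

test_that("marker gene ids do not matter, only ortholog groups do", {
  sim <- simulate_neighborhoods(2, shared_groups = c("OG_a", "OG_b"), seed = 9)
  renamed <- sim$neighborhoods
  renamed$gene_id <- paste0(renamed$gene_id, "_v2")
  g1 <- synteny_graph(read_neighborhoods(write_nbhd_tsv(sim$neighborhoods)))
  g2 <- synteny_graph(read_neighborhoods(write_nbhd_tsv(renamed)))
  expect_identical(g1$edges$weight, g2$edges$weight)
  expect_identical(g1$edges$shared_groups, g2$edges$shared_groups)
})

test_that("long ordinal gaps are flagged when a bound is set", {
  tb <- minimal_nbhd()
  tb$position <- c(1L, 5L, 50L)
  nb <- read_neighborhoods(write_nbhd_tsv(tb))
  w <- synteny_window(nb[1, ], k = 5, gap_bound = 10)
  expect_true(any(w$long_gap))
})
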