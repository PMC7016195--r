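test_that("identical ZCD regions align gap-free with pinned anchors", {
  recs <- perfect_zcd_records(c("a", "b"))
  hits <- detect_zcd(recs)
  aln <- anchored_alignment(hits, recs)
  expect_identical(aln$matrix["a", ], aln$matrix["b", ])
  expect_false(any(aln$matrix == "-"))
  expect_equal(ncol(aln$matrix), 9L + 14L + 22L + 20L + 40L)
})

test_that("spacer length differences become gap columns in the shorter row", {
  r1 <- sequence_records("s5", perfect_zcd(sp1 = 5)$seq)
  r2 <- sequence_records("s9", perfect_zcd(sp1 = 9)$seq)
  recs <- dplyr::bind_rows(r1, r2)
  aln <- anchored_alignment(detect_zcd(recs), recs)
  expect_equal(sum(aln$matrix["s5", ] == "-"), 4L)
  expect_equal(sum(aln$matrix["s9", ] == "-"), 0L)
  # ungapped content of each row equals the extracted ZCD region
  hits <- detect_zcd(recs)
  for (id in recs$id) {
    row <- aln$matrix[id, ]
    h <- hits[hits$seq_id == id, ]
    expect_equal(paste(row[row != "-"], collapse = ""),
                 substring(recs$residues[recs$id == id], h$start, h$end))
  }
  # anchor columns are never gapped (spacer padding stays outside them)
  expect_false(any(aln$matrix[, aln$anchor_columns] == "-"))
})

test_that("alignment requires at least two hits and import checks row lengths", {
  recs <- perfect_zcd_records("solo")
  expect_error(anchored_alignment(detect_zcd(recs), recs), "at least 2")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK-V", ">b", "MKV"), f)
  expect_error(read_alignment(f), "differ in length")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK-V", ">b", "MKVV"), f2)
  m <- read_alignment(f2)
  expect_equal(dim(m), c(2L, 4L))
})

test_that("JTT distance is zero for identical rows and symmetric", {
  set.seed(12)
  a <- strsplit(random_aa(200), "")[[1]]
  expect_equal(as.numeric(jtt_distance(a, a)), 0)
  b <- a
  b[sample(200, 40)] <- sample(aa20, 40, replace = TRUE)
  expect_equal(as.numeric(jtt_distance(a, b)), as.numeric(jtt_distance(b, a)))
})

test_that("JTT distance increases with the number of differing columns", {
  set.seed(13)
  a <- strsplit(random_aa(300), "")[[1]]
  ds <- vapply(c(10, 40, 80, 140), function(k) {
    b <- a
    idx <- seq_len(k)
    b[idx] <- vapply(a[idx], function(ch) sample(setdiff(aa20, ch), 1), "")
    as.numeric(jtt_distance(a, b))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("ML optimum matches a brute-force grid search within 1e-3", {
  for (s in 1:3) {
    two <- evolve_along_tree(ape::read.tree(text = "(a:0.25,b:0.25);"),
                             root = 300, seed = 40 + s)
    av <- strsplit(two$residues[1], "")[[1]]
    bv <- strsplit(two$residues[2], "")[[1]]
    d_ml <- as.numeric(jtt_distance(av, bv))
    ts <- seq(1e-3, 4, by = 1e-4)
    N <- table(factor(av, levels = aa20), factor(bv, levels = aa20))
    ll <- vapply(ts, function(t) {
      sum(N * log(jtt_frequencies() * jtt_prob_matrix(t)))
    }, numeric(1))
    expect_lt(abs(d_ml - ts[which.max(ll)]), 1e-3)
  }
})

test_that("JTT distances agree with an established ML implementation", {
  skip_if_not_installed("phangorn")
  two <- evolve_along_tree(ape::read.tree(text = "(a:0.4,b:0.4);"),
                           root = 400, seed = 71)
  m <- records_to_matrix(two)
  mine <- jtt_distance_matrix(m)["a", "b"]
  pd <- phangorn::phyDat(m, type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))["a", "b"]
  expect_equal(mine, ref, tolerance = 1e-3)
})

test_that("gap handling: pairwise deletion keeps pairs complete deletion drops", {
  a <- c("M", "K", "V", "-", "L")
  b <- c("M", "R", "-", "A", "L")
  m <- rbind(a = a, b = b, c = c("M", "K", "V", "A", "L"))
  Dp <- jtt_distance_matrix(m, deletion = "pairwise")
  Dc <- jtt_distance_matrix(m, deletion = "complete")
  expect_equal(diag(Dp), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(unclass(Dp)))
  # complete deletion leaves only columns 1, 2, 5 for every pair
  expect_gte(Dc["a", "c"], Dp["a", "c"])
  expect_error(jtt_distance(c("-", "A"), c("A", "-")), "no shared")
})

test_that("saturated distances are capped and flagged", {
  set.seed(99)
  a <- strsplit(random_aa(60), "")[[1]]
  b <- vapply(a, function(ch) sample(setdiff(aa20, ch), 1), "")
  d <- jtt_distance(a, b, cap = 2)
  expect_true(attr(d, "saturated"))
  expect_equal(as.numeric(d), 2)
})
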