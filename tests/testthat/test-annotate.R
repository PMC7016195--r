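test_that("a constructed perfect ZCD yields exactly one full-score hit", {
  fx <- perfect_zcd(cs = "C")
  recs <- sequence_records("zcd1", fx$seq)
  hits <- detect_zcd(recs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$c1_start, fx$c1_start)
  expect_equal(hits$c2_start, fx$c2_start)
  expect_equal(hits$c3_start, fx$c3_start)
  expect_equal(hits$end, fx$end)
  expect_equal(hits$score, hits$n_constrained)  # 5 + 10 + 12 satisfied
  expect_equal(hits$n_constrained, 27L)
  expect_true(hits$optional_c_present)
  hits_s <- detect_zcd(sequence_records("zcd2", perfect_zcd(cs = "S")$seq))
  expect_false(hits_s$optional_c_present)
})

test_that("breaking an obligate position kills the hit at zero mismatch budget", {
  fx <- perfect_zcd(break_cluster2_g = TRUE)
  recs <- sequence_records("broken", fx$seq)
  strict <- zcd_config(max_mismatch = c(cluster1 = 0L, cluster2 = 0L, cluster3 = 0L))
  expect_equal(nrow(detect_zcd(recs, strict)), 0L)
  # the default budget of one non-cysteine mismatch per cluster tolerates it
  expect_equal(nrow(detect_zcd(recs)), 1L)
  # but a mutated obligate cysteine is never tolerated
  fx2 <- perfect_zcd()
  res <- fx2$seq
  substr(res, fx2$c1_start + 3L, fx2$c1_start + 3L) <- "A"  # first cluster1 C
  expect_equal(nrow(detect_zcd(sequence_records("nocys", res))), 0L)
})

test_that("out-of-range spacers are not assembled into hits", {
  wide <- perfect_zcd(sp1 = 20, sp2 = 40)
  expect_equal(nrow(detect_zcd(sequence_records("ok", wide$seq))), 1L)
  tight <- zcd_config(spacer_range1 = c(5L, 10L))
  expect_equal(nrow(detect_zcd(sequence_records("ok", wide$seq), tight)), 0L)
})

test_that("anchor detection is tiered: full 18-mer, SxxCC core, teleost context", {
  full <- sequence_records("f", paste0(strrep("A", 10), "SNCCRSHIYPWCKCCQPC", strrep("A", 10)))
  af <- detect_ccys_anchor(full)
  expect_equal(af$anchor_class, "full_mammal")
  expect_equal(af$end - af$start + 1L, 18L)
  core <- sequence_records("c", paste0(strrep("A", 10), "SAACC", strrep("G", 10)))
  expect_equal(detect_ccys_anchor(core)$anchor_class, "sxxcc_core")
  tele <- sequence_records("t", paste0(strrep("A", 10), "LIGTGCYSK", strrep("A", 10)))
  expect_equal(detect_ccys_anchor(tele)$anchor_class, "single_cys")
  none <- sequence_records("n", strrep("AGKV", 10))
  expect_equal(detect_ccys_anchor(none)$anchor_class, "absent")
})

test_that("anchor search is restricted upstream of a ZCD hit", {
  fx <- perfect_zcd(nterm = 40, anchor = "SNCCRSHIYPWCKCCQPC")
  recs <- sequence_records("a", fx$seq)
  hits <- detect_zcd(recs)
  a <- detect_ccys_anchor(recs, hits)
  expect_equal(a$anchor_class, "full_mammal")
  expect_lt(a$end, min(hits$start))
  # a core motif planted only inside the ZCD region is not reported:
  # cluster3's (L/I/V)PSC(C/S) can realize SxxCC-like content downstream
  only_down <- perfect_zcd(nterm = 10)
  h2 <- detect_zcd(sequence_records("b", only_down$seq))
  a2 <- detect_ccys_anchor(sequence_records("b", only_down$seq), h2)
  expect_true(is.na(a2$start) || a2$end < min(h2$start))
})

test_that("GDP-site report covers planted residues and the H-to-Y substitution", {
  fx <- perfect_zcd(plant_gdp = TRUE)
  recs <- sequence_records("g", fx$seq)
  hits <- detect_zcd(recs)
  rep5 <- detect_gdp_site(recs, hits)
  canon <- rep5[rep5$site %in% c("R546", "H547", "R574", "R578", "K583"), ]
  expect_equal(sum(canon$status == "present"), 5L)
  expect_equal(rep5$status[rep5$site == "WRF"], "present")
  # Y at the H547 offset is reported as a substitution, not a miss
  res <- fx$seq
  h_pos <- rep5$position[rep5$site == "H547"]
  substr(res, h_pos, h_pos) <- "Y"
  rep_y <- detect_gdp_site(sequence_records("g", res), detect_zcd(sequence_records("g", res)))
  expect_equal(rep_y$status[rep_y$site == "H547"], "substituted")
  expect_equal(rep_y$observed[rep_y$site == "H547"], "Y")
  # precondition: no hit, no report
  decoy <- sequence_records("d", strrep("AGKV", 50))
  expect_error(detect_gdp_site(decoy, detect_zcd(decoy)), "no ZCD hit")
})

test_that("perfect hits carry 8 or 7 zinc-cysteine annotations by C/S slot", {
  for (cs in c("C", "S")) {
    fx <- perfect_zcd(cs = cs)
    recs <- sequence_records("z", fx$seq)
    hits <- detect_zcd(recs)
    ann <- annotate_residues(recs, hits)
    n_zn <- sum(ann$label == "ZN_CYS")
    expect_equal(n_zn, if (cs == "C") 8L else 7L)
    # all ZN_CYS annotations sit on cysteines
    expect_true(all(ann$residue[ann$label == "ZN_CYS"] == "C"))
  }
})

test_that("full anchor annotates its six cysteines plus the initial serine", {
  fx <- perfect_zcd(nterm = 40, anchor = "SNCCRSHIYPWCKCCQPC")
  recs <- sequence_records("a", fx$seq)
  hits <- detect_zcd(recs)
  anchors <- detect_ccys_anchor(recs, hits)
  ann <- annotate_residues(recs, hits, anchors)
  anchor_ann <- ann[ann$label == "CCYS_ANCHOR", ]
  expect_equal(nrow(anchor_ann), 7L)   # 6 C + initial S
  expect_equal(sum(anchor_ann$residue == "C"), 6L)
  expect_equal(sum(anchor_ann$residue == "S"), 1L)
})

test_that("human-equivalent numbering is attached from the printed anchors", {
  fx <- perfect_zcd(plant_gdp = TRUE)
  recs <- sequence_records("h", fx$seq)
  hits <- detect_zcd(recs)
  gdp <- detect_gdp_site(recs, hits)
  ann <- annotate_residues(recs, hits, gdp = gdp)
  itts <- ann[ann$label == "ARRB_ITTS", ]
  expect_equal(itts$human_equiv, 507:510)
  expect_equal(itts$position, (hits$c2_start + 10L):(hits$c2_start + 13L))
  poly <- ann[ann$label == "POLY_I568", ]
  expect_equal(poly$position, hits$c3_start - 1L)
  fy <- ann[ann$label == "F581P582", ]
  expect_equal(fy$human_equiv, c(581L, 582L))
  # cluster1 has no printed human anchor, so its cysteines carry none
  c1_zn <- ann[ann$label == "ZN_CYS" & ann$motif_source == "cluster1", ]
  expect_true(all(is.na(c1_zn$human_equiv)))
  # cluster3's obligate C maps to C572
  expect_true(572L %in% ann$human_equiv[ann$label == "ZN_CYS"])
})

test_that("P2X-domain heuristic scores planted signatures and honors the sidecar", {
  sim <- simulate_zcd_proteins(1, include_p2x_signatures = TRUE, seed = 31,
                               n_term_range = c(120L, 160L))
  p <- detect_p2x_domain(sim$sequences)
  expect_equal(p$p2x_score, 1.0)
  expect_true(p$has_p2x)
  bare <- sequence_records("bare", perfect_zcd(nterm = 12)$seq)
  expect_false(detect_p2x_domain(bare)$has_p2x)
  side <- detect_p2x_domain(bare, sidecar = tibble::tibble(seq_id = "bare", has_p2x = TRUE))
  expect_true(side$has_p2x)
  expect_equal(side$source, "sidecar")
})

test_that("architecture classes follow the P2X/ZCD decision table", {
  p2x7 <- simulate_zcd_proteins(1, include_p2x_signatures = TRUE, seed = 8,
                                n_term_range = c(120L, 160L))$sequences
  nanor <- sequence_records("nanor", perfect_zcd(nterm = 40)$seq)
  other <- sequence_records("zcd_other", perfect_zcd(nterm = 200)$seq)
  decoy <- simulate_decoys(1, 300, seed = 77)
  cls <- classify_architecture(dplyr::bind_rows(p2x7, nanor, other, decoy))
  expect_equal(cls$class_label,
               c("P2X7_LIKE", "NANOR_LIKE", "ZCD_OTHER", "UNCLASSIFIED"))
  # channel domain without ZCD
  non7 <- classify_architecture(nanor, sidecar = tibble::tibble(seq_id = "nanor", has_p2x = TRUE))
  expect_equal(non7$class_label, "P2X7_LIKE")
  no_zcd <- classify_architecture(decoy, sidecar = tibble::tibble(seq_id = decoy$id, has_p2x = TRUE))
  expect_equal(no_zcd$class_label, "P2X_NON7")
})

test_that("a ZCD far from the C-terminus downgrades ZCD-only calls", {
  fx <- perfect_zcd(nterm = 40, tail = 150)
  expect_warning(
    cls <- classify_architecture(sequence_records("longtail", fx$seq)),
    "C-terminal"
  )
  expect_equal(cls$class_label, "UNCLASSIFIED")
  expect_true(cls$has_zcd)
})

test_that("classification is a pure function of its inputs", {
  recs <- sequence_records("z", perfect_zcd()$seq)
  expect_identical(classify_architecture(recs), classify_architecture(recs))
})

test_that("detection degrades monotonically with constrained-site noise", {
  rates <- c(0, 0.3, 0.7, 1)
  recall <- vapply(seq_along(rates), function(i) {
    sim <- simulate_zcd_proteins(30, mu_c = rates[i], mu_u = 0.1,
                                 seed = 1000 + i)
    length(unique(detect_zcd(sim$sequences)$seq_id)) / 30
  }, numeric(1))
  expect_equal(recall[1], 1)
  expect_lt(recall[4], 0.05)
  expect_true(all(diff(recall) <= 0.05))  # non-increasing up to MC noise
})
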