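# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; coordinates asserted in closed-loop tests
# come from the generators' truth records, never typed by hand.

# Deterministic perfect-consensus ZCD sequence: exact cluster realizations
# ("A" at every wildcard), fixed spacers, optional anchor/GDP planting.
# Returns the sequence string plus the layout used to build it.
perfect_zcd <- function(nterm = 30, sp1 = 20, sp2 = 40, tail = 5,
                        cs = "C", anchor = NULL, plant_gdp = FALSE,
                        break_cluster2_g = FALSE) {
  c1 <- "PAWCACAAC"                                # PxWCxCx2C
  c2 <- "LCCRAAAGACITTS"                           # LCCRx3GxCITTS/T
  if (break_cluster2_g) substr(c2, 8, 8) <- "A"
  # (L/I/V)PSC(C/S)x3IRx2(F/Y)Px5Y(S/T)G; when the GDP site is planted the
  # wildcards at the R574/K583 offsets (6 and 15) hold R and K
  c3 <- if (plant_gdp) {
    paste0("LPSC", cs, "RAAIRAAFPKAAAAYSG")
  } else {
    paste0("LPSC", cs, "AAAIRAAFPAAAAAYSG")
  }
  nt <- strrep("A", nterm)
  if (!is.null(anchor)) {
    stopifnot(nchar(anchor) + 4 <= nterm)
    at <- nterm - nchar(anchor) - 2
    substr(nt, at, at + nchar(anchor) - 1) <- anchor
  }
  s2 <- strrep("A", sp2)
  if (plant_gdp) {
    stopifnot(sp2 >= 16)
    substr(s2, 3, 18) <- "RHAAYAAAAAAAAWRF"        # R(H/Y)x2Yx8WRF
  }
  seqstr <- paste0(nt, c1, strrep("A", sp1), c2, s2, c3, strrep("A", tail))
  list(
    seq = seqstr,
    c1_start = nterm + 1L,
    c2_start = nterm + nchar(c1) + sp1 + 1L,
    c3_start = nterm + nchar(c1) + sp1 + nchar(c2) + sp2 + 1L,
    end = nterm + nchar(c1) + sp1 + nchar(c2) + sp2 + nchar(c3)
  )
}

perfect_zcd_records <- function(ids = "zcd1", ...) {
  fx <- perfect_zcd(...)
  sequence_records(ids, rep(fx$seq, length(ids)))
}

# Independent brute-force motif scanner: literal per-window loop over the
# pattern's element expansion, no shared code with scan_motif().
brute_scan_starts <- function(residues, pattern, max_mismatch) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  span <- pattern$span
  if (span > length(chars)) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(length(chars) - span + 1)) {
    win <- chars[s:(s + span - 1)]
    if (any(win == "-")) next
    mm <- 0L
    for (k in seq_len(span)) {
      kind <- pattern$positions$kind[k]
      if (kind == "wildcard") next
      if (!win[k] %in% pattern$positions$allowed[[k]]) mm <- mm + 1L
    }
    if (mm <= max_mismatch) hits <- c(hits, s)
  }
  hits
}

# Random amino-acid string (20-letter alphabet).
random_aa <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Alignment matrix from a record tibble of equal-length (gapless) sequences.
records_to_matrix <- function(recs) {
  m <- do.call(rbind, strsplit(recs$residues, "", fixed = TRUE))
  rownames(m) <- recs$id
  m
}

balanced_tree6 <- function(bl = 0.2) {
  ape::read.tree(text = sprintf(
    "(((t1:%g,t2:%g):%g,t3:%g):%g,(t4:%g,(t5:%g,t6:%g):%g):%g);",
    bl, bl, bl, bl, bl, bl, bl, bl, bl, bl))
}
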