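#' Configuration for ZCD detection and classification
#'
#' Collects the tunable thresholds of the annotator. Defaults:
#' \itemize{
#'   \item `spacer_range1`, `spacer_range2`: allowed residue counts between
#'     cluster1–cluster2 and cluster2–cluster3, `c(5, 60)` each. The region
#'     between clusters varies in length across species, so the windows are
#'     deliberately wide.
#'   \item `max_mismatch`: mismatch budget per cluster (default 1 each).
#'   \item `obligate_cys`: when `TRUE` (default) no mismatch may fall on a
#'     cysteine-capable pattern position — the Zn-coordinating cysteines are
#'     the defining, near-invariant feature of the domain.
#'   \item `anchor_max_mismatch`: budget for the full 18-residue C-cys
#'     anchor (default 2); `teleost_max_mismatch` for the teleost context
#'     (default 0).
#'   \item `p2x_threshold`: fraction of bundled P2X signatures required to
#'     call a P2X domain (default 0.5); `p2x_max_mismatch` per signature
#'     (default 1).
#'   \item `nanor_nterm_max`: maximum non-ZCD N-terminal length (residues)
#'     for a NANOR_LIKE call (default 150); `cterm_tail_max`: maximum
#'     allowed tail after the ZCD for ZCD-only proteins (default 100) —
#'     the domain sits at the C-terminus in every known architecture.
#' }
#'
#' @param ... named overrides of the defaults above.
#' @return A named list of class `zcd_config`.
#' @export
zcd_config <- function(...) {
  cfg <- list(
    spacer_range1 = c(5L, 60L),
    spacer_range2 = c(5L, 60L),
    max_mismatch = c(cluster1 = 1L, cluster2 = 1L, cluster3 = 1L),
    obligate_cys = TRUE,
    anchor_max_mismatch = 2L,
    teleost_max_mismatch = 0L,
    p2x_threshold = 0.5,
    p2x_max_mismatch = 1L,
    nanor_nterm_max = 150L,
    cterm_tail_max = 100L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown zcd_config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "zcd_config")
}

# Drop cluster matches whose mismatches hit a cysteine-capable position.
filter_obligate_cys <- function(matches, pattern) {
  if (nrow(matches) == 0) return(matches)
  c_offsets <- pattern$positions$offset[
    purrr::map_lgl(pattern$positions$allowed, function(a) "C" %in% a)]
  keep <- purrr::map2_lgl(matches$mismatch_positions, matches$start, function(mm, s) {
    length(mm) == 0 || !any((mm - s + 1L) %in% c_offsets)
  })
  matches[keep, , drop = FALSE]
}

#' Detect the Zn-coordinating cysteine domain
#'
#' Scans each sequence for the three ordered cysteine-cluster consensus
#' motifs, assembles every in-order combination whose inter-cluster spacers
#' fall inside the configured ranges, and resolves overlapping candidates
#' to the maximum-score (then leftmost) hit, reporting at most one hit per
#' non-overlapping region.
#'
#' @param records sequence-record tibble.
#' @param config a [zcd_config()].
#' @return Tibble of hits: `seq_id`, `start`, `end`, cluster bounds
#'   (`c1_start` .. `c3_end`), `spacer1`, `spacer2`, `score` (total
#'   satisfied constrained positions across the three clusters),
#'   `n_constrained`, `optional_c_present` (whether cluster3's C/S slot
#'   holds a cysteine), and a `cluster_matches` list-column holding the
#'   three underlying motif matches.
#' @export
detect_zcd <- function(records, config = zcd_config()) {
  pats <- zcd_cluster_patterns()
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    detect_zcd_one(records[i, , drop = FALSE], pats, config)
  })
  bind_rows(out)
}

empty_zcd_hits <- function() {
  tibble(
    seq_id = character(0), start = integer(0), end = integer(0),
    c1_start = integer(0), c1_end = integer(0),
    c2_start = integer(0), c2_end = integer(0),
    c3_start = integer(0), c3_end = integer(0),
    spacer1 = integer(0), spacer2 = integer(0),
    score = integer(0), n_constrained = integer(0),
    optional_c_present = logical(0), cluster_matches = list()
  )
}

detect_zcd_one <- function(rec, pats, config) {
  mm <- config$max_mismatch
  ms <- purrr::imap(pats, function(p, nm) {
    m <- scan_one(rec$id, rec$residues, p, max_mismatch = mm[[nm]])
    if (config$obligate_cys) m <- filter_obligate_cys(m, p)
    m
  })
  if (any(vapply(ms, nrow, 1L) == 0)) return(empty_zcd_hits())
  cand <- list()
  for (i in seq_len(nrow(ms$cluster1))) {
    for (j in seq_len(nrow(ms$cluster2))) {
      sp1 <- ms$cluster2$start[j] - ms$cluster1$end[i] - 1L
      if (sp1 < config$spacer_range1[1] || sp1 > config$spacer_range1[2]) next
      for (k in seq_len(nrow(ms$cluster3))) {
        sp2 <- ms$cluster3$start[k] - ms$cluster2$end[j] - 1L
        if (sp2 < config$spacer_range2[1] || sp2 > config$spacer_range2[2]) next
        cand[[length(cand) + 1L]] <- list(i = i, j = j, k = k, sp1 = sp1, sp2 = sp2)
      }
    }
  }
  if (length(cand) == 0) return(empty_zcd_hits())
  c3 <- pats$cluster3
  cs_offset <- c3$positions$offset[
    c3$positions$kind == "class" &
      purrr::map_lgl(c3$positions$allowed, function(a) "C" %in% a)][1]
  rows <- purrr::map(cand, function(cc) {
    m1 <- ms$cluster1[cc$i, ]; m2 <- ms$cluster2[cc$j, ]; m3 <- ms$cluster3[cc$k, ]
    cs_res <- substring(rec$residues, m3$start + cs_offset - 1L, m3$start + cs_offset - 1L)
    tibble(
      seq_id = rec$id, start = m1$start, end = m3$end,
      c1_start = m1$start, c1_end = m1$end,
      c2_start = m2$start, c2_end = m2$end,
      c3_start = m3$start, c3_end = m3$end,
      spacer1 = cc$sp1, spacer2 = cc$sp2,
      score = m1$n_satisfied + m2$n_satisfied + m3$n_satisfied,
      n_constrained = m1$n_constrained + m2$n_constrained + m3$n_constrained,
      optional_c_present = identical(cs_res, "C"),
      cluster_matches = list(bind_rows(m1, m2, m3))
    )
  })
  hits <- bind_rows(rows)
  hits <- hits[order(-hits$score, hits$start, hits$end), , drop = FALSE]
  taken_start <- integer(0); taken_end <- integer(0); keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    overl <- any(hits$start[r] <= taken_end & hits$end[r] >= taken_start)
    if (!overl) {
      keep[r] <- TRUE
      taken_start <- c(taken_start, hits$start[r])
      taken_end <- c(taken_end, hits$end[r])
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

best_match_in_region <- function(rec, pattern, max_mismatch, from, to) {
  if (to - from + 1L < pattern$span) return(NULL)
  sub <- substring(rec$residues, from, to)
  m <- scan_one(rec$id, sub, pattern, max_mismatch = max_mismatch)
  if (nrow(m) == 0) return(NULL)
  m <- m[order(-m$n_satisfied, m$start), ][1, ]
  m$start <- m$start + from - 1L
  m$end <- m$end + from - 1L
  m$mismatch_positions <- list(m$mismatch_positions[[1]] + from - 1L)
  m
}

#' Detect the C-cys anchor (palmitoylation motif)
#'
#' Tiered call per sequence, searched upstream of the ZCD hit when one
#' exists: the full 18-residue mammalian motif (within the configured
#' mismatch budget) gives `full_mammal`; otherwise the conserved `SxxCC`
#' core gives `sxxcc_core`; otherwise the teleost single-cysteine context
#' `LIGTGCYSK` gives `single_cys`; otherwise `absent`.
#'
#' @param records sequence-record tibble.
#' @param zcd_hits optional output of [detect_zcd()] used to restrict the
#'   search region.
#' @param config a [zcd_config()].
#' @return Tibble: `seq_id`, `anchor_class`, `start`, `end`,
#'   `matched_text`, `n_mismatch` (`NA` coordinates when absent).
#' @export
detect_ccys_anchor <- function(records, zcd_hits = NULL, config = zcd_config()) {
  full <- bundled_pattern("ccys_anchor_full")
  core <- bundled_pattern("ccys_core")
  tele <- bundled_pattern("ccys_teleost")
  purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    limit <- nchar(rec$residues)
    if (!is.null(zcd_hits)) {
      z <- zcd_hits[zcd_hits$seq_id == rec$id, ]
      if (nrow(z) > 0) limit <- min(z$start) - 1L
    }
    if (limit < 1) {
      return(tibble(seq_id = rec$id, anchor_class = "absent",
                    start = NA_integer_, end = NA_integer_,
                    matched_text = NA_character_, n_mismatch = NA_integer_))
    }
    tiers <- list(
      list(p = full, mm = config$anchor_max_mismatch, cls = "full_mammal"),
      list(p = core, mm = 0L, cls = "sxxcc_core"),
      list(p = tele, mm = config$teleost_max_mismatch, cls = "single_cys")
    )
    for (t in tiers) {
      m <- best_match_in_region(rec, t$p, t$mm, 1L, limit)
      if (!is.null(m)) {
        return(tibble(seq_id = rec$id, anchor_class = t$cls,
                      start = m$start, end = m$end,
                      matched_text = m$matched_text,
                      n_mismatch = m$n_constrained - m$n_satisfied))
      }
    }
    tibble(seq_id = rec$id, anchor_class = "absent",
           start = NA_integer_, end = NA_integer_,
           matched_text = NA_character_, n_mismatch = NA_integer_)
  }) %>% bind_rows()
}

#' Report the GDP-binding-site residues of a ZCD hit
#'
#' Locates the canonical guanosine-nucleotide-pocket residues relative to
#' the detected cluster landmarks and reports, for each of R546, H547,
#' R574, R578 and K583 (human P2X7 numbering), whether the equivalent
#' position is `present`, `substituted` (with the observed residue) or
#' `not_locatable`, plus presence flags for the WRF motif and the LPS-like
#' WRIRx5G consensus. The proximal R546-H547 pair (H tolerated as Y, a
#' quasi-conserved substitution), Y550 and WRF are found by scanning a
#' composite template in the cluster2–cluster3 spacer; the distal residues
#' sit at fixed cluster3 offsets.
#'
#' @param records sequence-record tibble.
#' @param zcd_hits output of [detect_zcd()]; every sequence in `records`
#'   must have a hit (the site lies between the cluster landmarks).
#' @return Tibble: `seq_id`, `site` (R546, H547, R574, R578, K583, WRF,
#'   WRIRG), `status`, `observed`, `position`.
#' @export
detect_gdp_site <- function(records, zcd_hits) {
  purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    z <- zcd_hits[zcd_hits$seq_id == rec$id, ]
    if (nrow(z) == 0) {
      abort(sprintf("no ZCD hit for sequence '%s': the GDP site is located from cluster landmarks", rec$id))
    }
    z <- z[1, ]
    rows <- list()
    res_at <- function(p) substring(rec$residues, p, p)
    # proximal half: composite R-(H/Y)-x2-Y-x8-W-R-F template in the spacer
    block <- best_match_in_region(rec, bundled_pattern("gdp_rh_block"), 1L,
                                  z$c2_end + 1L, z$c3_start - 1L)
    if (!is.null(block)) {
      p <- block$start
      rows$R546 <- tibble(site = "R546", position = p,
                          observed = res_at(p),
                          status = if (res_at(p) == "R") "present" else "substituted")
      h <- res_at(p + 1L)
      rows$H547 <- tibble(site = "H547", position = p + 1L, observed = h,
                          status = if (h == "H") "present" else "substituted")
      wrf_ok <- substring(rec$residues, p + 13L, p + 15L) == "WRF"
      rows$WRF <- tibble(site = "WRF", position = p + 13L,
                         observed = substring(rec$residues, p + 13L, p + 15L),
                         status = if (wrf_ok) "present" else "substituted")
    } else {
      rh <- best_match_in_region(rec, bundled_pattern("gdp_rh"), 0L,
                                 z$c2_end + 1L, z$c3_start - 1L)
      if (!is.null(rh)) {
        p <- rh$start
        rows$R546 <- tibble(site = "R546", position = p, observed = res_at(p),
                            status = "present")
        h <- res_at(p + 1L)
        rows$H547 <- tibble(site = "H547", position = p + 1L, observed = h,
                            status = if (h == "H") "present" else "substituted")
      } else {
        rows$R546 <- tibble(site = "R546", position = NA_integer_,
                            observed = NA_character_, status = "not_locatable")
        rows$H547 <- tibble(site = "H547", position = NA_integer_,
                            observed = NA_character_, status = "not_locatable")
      }
      wrf <- best_match_in_region(rec, bundled_pattern("wrf"), 0L,
                                  z$c2_end + 1L, z$c3_start - 1L)
      rows$WRF <- if (!is.null(wrf)) {
        tibble(site = "WRF", position = wrf$start, observed = wrf$matched_text,
               status = "present")
      } else {
        tibble(site = "WRF", position = NA_integer_, observed = NA_character_,
               status = "not_locatable")
      }
    }
    # distal half at fixed cluster3 offsets (R574 = start+5, R578 = start+9,
    # K583 = start+14, from the printed residue numbering)
    distal <- list(R574 = c(5L, "R"), R578 = c(9L, "R"), K583 = c(14L, "K"))
    for (nm in names(distal)) {
      p <- z$c3_start + as.integer(distal[[nm]][1])
      obs <- res_at(p)
      rows[[nm]] <- tibble(site = nm, position = p, observed = obs,
                           status = if (obs == distal[[nm]][2]) "present" else "substituted")
    }
    wrir <- best_match_in_region(rec, bundled_pattern("lps_wrirg"), 0L,
                                 z$c2_end + 1L, nchar(rec$residues))
    rows$WRIRG <- if (!is.null(wrir)) {
      tibble(site = "WRIRG", position = wrir$start, observed = wrir$matched_text,
             status = "present")
    } else {
      tibble(site = "WRIRG", position = NA_integer_, observed = NA_character_,
             status = "not_locatable")
    }
    out <- bind_rows(rows[c("R546", "H547", "R574", "R578", "K583", "WRF", "WRIRG")])
    out$seq_id <- rec$id
    out[, c("seq_id", "site", "status", "observed", "position")]
  }) %>% bind_rows()
}

#' Score a sequence for a P2X channel domain
#'
#' Heuristic: the fraction of the bundled P2X signature patterns (see
#' `inst/extdata/p2x_signatures.tsv`, a synthetic stand-in for a real
#' domain-database lookup) matched anywhere in the sequence; the boolean
#' call applies the configured threshold. A sidecar tibble of precomputed
#' domain calls (`seq_id`, `has_p2x`) overrides the heuristic per sequence.
#'
#' @param records sequence-record tibble.
#' @param config a [zcd_config()].
#' @param sidecar optional tibble (`seq_id`, `has_p2x`) of trusted calls.
#' @return Tibble: `seq_id`, `p2x_score`, `has_p2x`, `source`.
#' @export
detect_p2x_domain <- function(records, config = zcd_config(), sidecar = NULL) {
  sig_path <- system.file("extdata", "p2x_signatures.tsv", package = "zcdtools")
  sigs <- readr::read_tsv(sig_path, col_types = "cc", comment = "#", progress = FALSE)
  pats <- purrr::map2(sigs$notation, sigs$name, parse_pattern)
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    n_hit <- sum(purrr::map_int(pats, function(p) {
      as.integer(nrow(scan_one(rec$id, rec$residues, p, config$p2x_max_mismatch)) > 0)
    }))
    score <- n_hit / length(pats)
    tibble(seq_id = rec$id, p2x_score = score,
           has_p2x = score >= config$p2x_threshold, source = "heuristic")
  }) %>% bind_rows()
  if (!is.null(sidecar) && nrow(sidecar) > 0) {
    idx <- match(out$seq_id, sidecar$seq_id)
    hit <- !is.na(idx)
    out$has_p2x[hit] <- sidecar$has_p2x[idx[hit]]
    out$source[hit] <- "sidecar"
  }
  out
}

human_offset_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "human_offsets.tsv", package = "zcdtools")
      cache <<- readr::read_tsv(path, col_types = "cii", comment = "#", progress = FALSE)
    }
    cache
  }
})

human_equiv_for <- function(motif, offset) {
  tab <- human_offset_table()
  hit <- tab$human_pos[tab$motif == motif & tab$offset == offset]
  if (length(hit) == 1) hit else NA_integer_
}

annot_row <- function(seq_id, position, residue, label, motif_source, human_equiv = NA_integer_) {
  tibble(seq_id = seq_id, position = as.integer(position), residue = residue,
         label = label, motif_source = motif_source,
         human_equiv = as.integer(human_equiv))
}

#' Annotate conserved functional residues
#'
#' Combines the detection results for one or more sequences into per-residue
#' annotations with a controlled label vocabulary: `ZN_CYS` for every
#' cysteine actually present at a cysteine-capable cluster position (7 or 8
#' for a perfect hit, depending on the optional C/S slot), `CCYS_ANCHOR`
#' for the anchor's six cysteines plus its initial serine, the `GDP_*`
#' residues, `Y550`, `F581P582`, `WRF`, `LPS_WRIRG`, the beta-arrestin
#' sites (`ARRB_ITTS`, `ARRB_ATNS`, `ARRB_TYSS`) and the locatable
#' loss-of-function polymorphism sites (`POLY_E496`, `POLY_I568`).
#' Polymorphism sites that cannot be pinned from motif offsets (Q460, A348)
#' are never emitted. Human-equivalent numbering is attached from the
#' bundled offset table where an unambiguous printed anchor exists.
#'
#' @param records sequence-record tibble.
#' @param zcd_hits,anchors,gdp detection results ([detect_zcd()],
#'   [detect_ccys_anchor()], [detect_gdp_site()] output); any may be
#'   omitted (`NULL`) and is then skipped.
#' @return Annotation tibble: `seq_id`, `position`, `residue`, `label`,
#'   `motif_source`, `human_equiv`, ordered by `seq_id` then `position`.
#' @export
annotate_residues <- function(records, zcd_hits = NULL, anchors = NULL, gdp = NULL) {
  rows <- list()
  res_at <- function(residues, p) substring(residues, p, p)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    seqres <- rec$residues
    z <- if (!is.null(zcd_hits)) zcd_hits[zcd_hits$seq_id == rec$id, ] else empty_zcd_hits()
    for (h in seq_len(nrow(z))) {
      cm <- z$cluster_matches[[h]]
      pats <- zcd_cluster_patterns()
      for (ci in seq_len(nrow(cm))) {
        pat <- pats[[cm$pattern_name[ci]]]
        c_offsets <- pat$positions$offset[
          purrr::map_lgl(pat$positions$allowed, function(a) "C" %in% a)]
        for (off in c_offsets) {
          p <- cm$start[ci] + off - 1L
          if (res_at(seqres, p) == "C") {
            rows[[length(rows) + 1L]] <- annot_row(
              rec$id, p, "C", "ZN_CYS", cm$pattern_name[ci],
              human_equiv_for(cm$pattern_name[ci], off))
          }
        }
      }
      # beta-arrestin ITTS at cluster2 offsets 11-14
      itts <- substring(seqres, z$c2_start[h] + 10L, z$c2_start[h] + 13L)
      if (grepl("^ITT[ST]$", itts)) {
        for (off in 11:14) {
          p <- z$c2_start[h] + off - 1L
          rows[[length(rows) + 1L]] <- annot_row(
            rec$id, p, res_at(seqres, p), "ARRB_ITTS", "cluster2",
            human_equiv_for("cluster2", off))
        }
      }
      # beta-arrestin ATNS in the cluster2-cluster3 spacer
      atns <- best_match_in_region(rec, parse_pattern("ATNS", "arrb_atns"), 0L,
                                   z$c2_end[h] + 1L, z$c3_start[h] - 1L)
      if (!is.null(atns)) {
        for (d in 0:3) {
          rows[[length(rows) + 1L]] <- annot_row(
            rec$id, atns$start + d, res_at(seqres, atns$start + d),
            "ARRB_ATNS", "arrb_atns", 540L + d)
        }
      }
      # F/Y581-P582 at cluster3 offsets 13-14
      fy <- res_at(seqres, z$c3_start[h] + 12L)
      pp <- res_at(seqres, z$c3_start[h] + 13L)
      if (fy %in% c("F", "Y") && pp == "P") {
        rows[[length(rows) + 1L]] <- annot_row(rec$id, z$c3_start[h] + 12L, fy,
                                               "F581P582", "cluster3", 581L)
        rows[[length(rows) + 1L]] <- annot_row(rec$id, z$c3_start[h] + 13L, pp,
                                               "F581P582", "cluster3", 582L)
      }
      # locatable polymorphism sites
      if (z$c2_start[h] > 1L) {
        p <- z$c2_start[h] - 1L
        rows[[length(rows) + 1L]] <- annot_row(rec$id, p, res_at(seqres, p),
                                               "POLY_E496", "cluster2", 496L)
      }
      if (z$c3_start[h] > 1L) {
        p <- z$c3_start[h] - 1L
        rows[[length(rows) + 1L]] <- annot_row(rec$id, p, res_at(seqres, p),
                                               "POLY_I568", "cluster3", 568L)
      }
    }
    if (!is.null(anchors)) {
      a <- anchors[anchors$seq_id == rec$id & anchors$anchor_class == "full_mammal", ]
      if (nrow(a) == 1 && !is.na(a$start)) {
        full <- bundled_pattern("ccys_anchor_full")
        c_offsets <- full$positions$offset[
          purrr::map_lgl(full$positions$allowed, function(x) "C" %in% x)]
        for (off in c(1L, c_offsets)) {
          p <- a$start + off - 1L
          obs <- res_at(seqres, p)
          want <- if (off == 1L) "S" else "C"
          if (obs == want) {
            rows[[length(rows) + 1L]] <- annot_row(rec$id, p, obs, "CCYS_ANCHOR",
                                                   "ccys_anchor_full")
          }
        }
        # T357-YSS immediately precedes the anchor serine
        if (a$start >= 4L && substring(seqres, a$start - 3L, a$start) == "TYSS") {
          for (d in 0:3) {
            rows[[length(rows) + 1L]] <- annot_row(
              rec$id, a$start - 3L + d, res_at(seqres, a$start - 3L + d),
              "ARRB_TYSS", "ccys_anchor_full", 357L + d)
          }
        }
      }
    }
    if (!is.null(gdp)) {
      g <- gdp[gdp$seq_id == rec$id, ]
      lab_map <- c(R546 = "GDP_R546", H547 = "GDP_H547", R574 = "GDP_R574",
                   R578 = "GDP_R578", K583 = "GDP_K583")
      for (r in seq_len(nrow(g))) {
        if (is.na(g$position[r])) next
        if (g$site[r] %in% names(lab_map) && g$status[r] %in% c("present", "substituted")) {
          rows[[length(rows) + 1L]] <- annot_row(
            rec$id, g$position[r], res_at(seqres, g$position[r]),
            lab_map[[g$site[r]]], "gdp_site",
            as.integer(sub("^[A-Z]", "", g$site[r])))
        }
        if (g$site[r] == "WRF" && g$status[r] == "present") {
          for (d in 0:2) {
            rows[[length(rows) + 1L]] <- annot_row(
              rec$id, g$position[r] + d, res_at(seqres, g$position[r] + d),
              "WRF", "wrf", 559L + d)
          }
          # Y550 sits four residues after R546 in the same conserved block
          y <- g$position[g$site == "R546"]
          if (length(y) == 1 && !is.na(y) && res_at(seqres, y + 4L) == "Y") {
            rows[[length(rows) + 1L]] <- annot_row(rec$id, y + 4L, "Y", "Y550",
                                                   "gdp_rh_block", 550L)
          }
        }
        if (g$site[r] == "WRIRG" && g$status[r] == "present") {
          lp <- bundled_pattern("lps_wrirg")
          for (off in lp$positions$offset[lp$positions$kind != "wildcard"]) {
            p <- g$position[r] + off - 1L
            rows[[length(rows) + 1L]] <- annot_row(
              rec$id, p, res_at(seqres, p), "LPS_WRIRG", "lps_wrirg")
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(annot_row(character(0), integer(0), character(0), character(0), character(0))[0, ])
  }
  out <- bind_rows(rows)
  out <- distinct(out)
  out[order(out$seq_id, out$position), , drop = FALSE]
}

#' Classify domain architectures
#'
#' Assigns each sequence to one of five architecture classes: `P2X7_LIKE`
#' (P2X channel domain + ZCD), `NANOR_LIKE` (ZCD only, short N-terminal
#' region), `ZCD_OTHER` (ZCD only, long N-terminus), `P2X_NON7` (channel
#' domain without ZCD) and `UNCLASSIFIED`. For ZCD-only proteins the domain
#' must be C-terminal-most (tail after the hit at most
#' `cterm_tail_max` residues); violations downgrade to `UNCLASSIFIED` with
#' a warning.
#'
#' @param records sequence-record tibble.
#' @param config a [zcd_config()].
#' @param sidecar optional precomputed P2X-domain calls (see
#'   [detect_p2x_domain()]).
#' @return Tibble: `seq_id`, `length`, `has_p2x_domain`, `p2x_score`,
#'   `has_zcd`, `zcd_start`, `zcd_end`, `anchor_class`, `class_label`.
#' @export
classify_architecture <- function(records, config = zcd_config(), sidecar = NULL) {
  hits <- detect_zcd(records, config)
  p2x <- detect_p2x_domain(records, config, sidecar)
  anchors <- detect_ccys_anchor(records, hits, config)
  purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    L <- nchar(rec$residues)
    z <- hits[hits$seq_id == rec$id, ]
    has_zcd <- nrow(z) > 0
    px <- p2x[p2x$seq_id == rec$id, ]
    anc <- anchors$anchor_class[anchors$seq_id == rec$id]
    label <- if (px$has_p2x && has_zcd) {
      "P2X7_LIKE"
    } else if (has_zcd && !px$has_p2x) {
      tail_len <- L - max(z$end)
      if (tail_len > config$cterm_tail_max) {
        warn(sprintf("sequence '%s': ZCD is not C-terminal-most (%d-residue tail); downgrading to UNCLASSIFIED",
                     rec$id, tail_len))
        "UNCLASSIFIED"
      } else if (min(z$start) - 1L < config$nanor_nterm_max) {
        "NANOR_LIKE"
      } else {
        "ZCD_OTHER"
      }
    } else if (px$has_p2x) {
      "P2X_NON7"
    } else {
      "UNCLASSIFIED"
    }
    tibble(seq_id = rec$id, length = L,
           has_p2x_domain = px$has_p2x, p2x_score = px$p2x_score,
           has_zcd = has_zcd,
           zcd_start = if (has_zcd) min(z$start) else NA_integer_,
           zcd_end = if (has_zcd) max(z$end) else NA_integer_,
           anchor_class = anc[1], class_label = label)
  }) %>% bind_rows()
}

#' Run the full ZCD annotation pipeline on a sequence table
#'
#' Convenience wrapper running ZCD detection, anchor and P2X-domain calls,
#' GDP-site reporting (for sequences with a hit), residue annotation and
#' architecture classification in one pass.
#'
#' @param records sequence-record tibble.
#' @param config a [zcd_config()].
#' @param sidecar optional precomputed P2X-domain calls.
#' @return A `zcd_annotation` object: list with elements `sequences`,
#'   `hits`, `anchors`, `gdp`, `p2x`, `residues`, `classes`, `config`.
#'   [tidy()][tidy.zcd_annotation()] returns the residue annotations,
#'   [glance()][glance.zcd_annotation()] the per-sequence class summary.
#' @export
zcd_annotate <- function(records, config = zcd_config(), sidecar = NULL) {
  records <- validate_sequence_records(records)
  hits <- detect_zcd(records, config)
  anchors <- detect_ccys_anchor(records, hits, config)
  p2x <- detect_p2x_domain(records, config, sidecar)
  with_hit <- records[records$id %in% hits$seq_id, , drop = FALSE]
  gdp <- if (nrow(with_hit) > 0) detect_gdp_site(with_hit, hits) else
    tibble(seq_id = character(0), site = character(0), status = character(0),
           observed = character(0), position = integer(0))
  residues <- annotate_residues(records, hits, anchors, gdp)
  classes <- classify_architecture(records, config, sidecar)
  structure(
    list(sequences = records, hits = hits, anchors = anchors, gdp = gdp,
         p2x = p2x, residues = residues, classes = classes, config = config),
    class = "zcd_annotation"
  )
}

#' @export
print.zcd_annotation <- function(x, ...) {
  cat(sprintf("<zcd_annotation> %d sequence(s), %d ZCD hit(s)\n",
              nrow(x$sequences), nrow(x$hits)))
  tab <- table(x$classes$class_label)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
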