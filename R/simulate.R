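# Seeded synthetic-data generators. Every generator returns a
# machine-readable truth record alongside the data so closed-loop tests
# never compare against hand-entered coordinates.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_background <- function(n, composition = "uniform") {
  probs <- if (identical(composition, "uniform")) {
    rep(1 / 20, 20)
  } else if (identical(composition, "jtt")) {
    unname(jtt_frequencies())
  } else {
    stopifnot(is.numeric(composition), length(composition) == 20)
    composition / sum(composition)
  }
  sample(AA20, n, replace = TRUE, prob = probs)
}

# Realize one concrete instance of a pattern: exact positions as printed,
# classes sampled uniformly from their members, wildcards from background.
realize_pattern <- function(pattern, composition = "uniform",
                            class_choice = NULL) {
  pos <- pattern$positions
  vapply(seq_len(nrow(pos)), function(i) {
    if (pos$kind[i] == "wildcard") {
      draw_background(1, composition)
    } else if (!is.null(class_choice) && !is.null(class_choice[[as.character(pos$offset[i])]])) {
      class_choice[[as.character(pos$offset[i])]]
    } else if (pos$kind[i] == "exact") {
      pos$allowed[[i]]
    } else {
      sample(pos$allowed[[i]], 1)
    }
  }, character(1))
}

mutate_chars <- function(chars, rate) {
  if (rate <= 0 || length(chars) == 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(cur) {
      sample(setdiff(AA20, cur), 1)
    }, character(1))
  }
  chars
}

#' Simulate ZCD-bearing proteins with a known truth record
#'
#' Builds each sequence as: background N-terminal region (optionally
#' carrying planted P2X signature instances and a C-cys anchor), cluster1,
#' spacer, cluster2, spacer (optionally carrying the conserved
#' R-H/Y..Y..WRF GDP-site block), cluster3, and a background C-terminal
#' tail. Constrained pattern positions are first realized from the
#' consensus, then substituted with probability `mu_c`; all unconstrained
#' positions (wildcards, spacers, background) are substituted with
#' probability `mu_u`. Defaults emulate a compact ZCD protein whose spacer
#' lengths match the vertebrate consensus geometry (the cluster2–cluster3
#' spacer is ~58 residues in human P2X7).
#'
#' @param n_sequences number of sequences.
#' @param mu_c,mu_u substitution probabilities at constrained /
#'   unconstrained positions, each in `[0, 1]`.
#' @param spacer_range1,spacer_range2 inter-cluster spacer length ranges.
#' @param n_term_range,tail_range background region length ranges.
#' @param use_optional_c probability that cluster3's C/S slot holds C.
#' @param include_p2x_signatures plant the bundled P2X signature instances
#'   in the N-terminal region.
#' @param include_anchor one of `"none"`, `"full"`, `"core"`, `"teleost"`.
#' @param plant_gdp plant the GDP-site block in the second spacer and the
#'   distal R574/K583 residues at their cluster3 offsets.
#' @param composition `"uniform"` (default), `"jtt"`, or a length-20
#'   probability vector over A R N D C Q E G H I L K M F P S T W Y V.
#' @param id_prefix sequence id prefix.
#' @param seed integer seed; fixed seed gives identical output.
#' @return List with `sequences` (record tibble) and `truth` (tibble of
#'   planted features: `seq_id`, `feature`, `start`, `end`).
#' @export
simulate_zcd_proteins <- function(n_sequences = 1,
                                  mu_c = 0, mu_u = 0,
                                  spacer_range1 = c(10L, 40L),
                                  spacer_range2 = c(30L, 58L),
                                  n_term_range = c(30L, 120L),
                                  tail_range = c(2L, 10L),
                                  use_optional_c = 0.5,
                                  include_p2x_signatures = FALSE,
                                  include_anchor = c("none", "full", "core", "teleost"),
                                  plant_gdp = TRUE,
                                  composition = "uniform",
                                  id_prefix = "sim",
                                  seed = NULL) {
  include_anchor <- match.arg(include_anchor)
  stopifnot(n_sequences >= 1, mu_c >= 0, mu_c <= 1, mu_u >= 0, mu_u <= 1,
            use_optional_c >= 0, use_optional_c <= 1)
  for (rng in list(spacer_range1, spacer_range2, n_term_range, tail_range)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 0) {
      abort("length ranges must be non-decreasing pairs of non-negative integers")
    }
  }
  if (plant_gdp && spacer_range2[1] < 16) {
    abort("plant_gdp needs spacer_range2 minimum >= 16 (the GDP block spans 16 residues)")
  }
  pats <- zcd_cluster_patterns()
  with_seed(seed, {
    seqs <- vector("list", n_sequences)
    truths <- vector("list", n_sequences)
    for (s in seq_len(n_sequences)) {
      id <- sprintf("%s_%03d", id_prefix, s)
      feats <- list()
      add_feat <- function(feature, start, len) {
        feats[[length(feats) + 1L]] <<- tibble(
          seq_id = id, feature = feature,
          start = as.integer(start), end = as.integer(start + len - 1L))
      }
      n_term <- sample(n_term_range[1]:n_term_range[2], 1)
      nt <- draw_background(n_term, composition)
      if (include_p2x_signatures) {
        sig_path <- system.file("extdata", "p2x_signatures.tsv", package = "zcdtools")
        sigs <- readr::read_tsv(sig_path, col_types = "cc", comment = "#", progress = FALSE)
        at <- 1L
        for (r in seq_len(nrow(sigs))) {
          p <- parse_pattern(sigs$notation[r], sigs$name[r])
          if (at + p$span - 1L > n_term) {
            nt <- c(nt, draw_background(at + p$span - n_term + 4L, composition))
            n_term <- length(nt)
          }
          inst <- realize_pattern(p, composition)
          nt[at:(at + p$span - 1L)] <- inst
          add_feat(sigs$name[r], at, p$span)
          at <- at + p$span + sample(3:8, 1)
        }
      }
      if (include_anchor != "none") {
        motif <- switch(include_anchor,
          full = strsplit("SNCCRSHIYPWCKCCQPC", "")[[1]],
          core = realize_pattern(bundled_pattern("ccys_core"), composition),
          teleost = strsplit("LIGTGCYSK", "")[[1]])
        lead <- if (include_anchor == "full") c("T", "Y", "S") else character(0)
        block <- c(lead, motif)
        at <- length(nt) - length(block) - 2L
        if (at < 1L) {
          nt <- c(draw_background(length(block) + 4L, composition), nt)
          at <- length(nt) - length(block) - 2L
        }
        nt[at:(at + length(block) - 1L)] <- block
        add_feat(paste0("anchor_", include_anchor), at + length(lead), length(motif))
      }
      sp1 <- sample(spacer_range1[1]:spacer_range1[2], 1)
      sp2 <- sample(spacer_range2[1]:spacer_range2[2], 1)
      tail_len <- sample(tail_range[1]:tail_range[2], 1)
      cs_res <- if (runif(1) < use_optional_c) "C" else "S"
      c3_cs_offset <- pats$cluster3$positions$offset[
        pats$cluster3$positions$kind == "class" &
          purrr::map_lgl(pats$cluster3$positions$allowed, function(a) "C" %in% a)][1]
      c1 <- realize_pattern(pats$cluster1, composition)
      c2 <- realize_pattern(pats$cluster2, composition)
      c3 <- realize_pattern(pats$cluster3, composition,
                            class_choice = setNames(list(cs_res), as.character(c3_cs_offset)))
      spacer1 <- draw_background(sp1, composition)
      spacer2 <- draw_background(sp2, composition)
      gdp_at <- NA_integer_
      if (plant_gdp) {
        block <- realize_pattern(bundled_pattern("gdp_rh_block"), composition)
        gdp_at <- sample.int(sp2 - 16L + 1L, 1)
        spacer2[gdp_at:(gdp_at + 15L)] <- block
        c3[6L] <- "R"    # R574 equivalent
        c3[15L] <- "K"   # K583 equivalent
      }
      zcd_start <- length(nt) + 1L
      add_feat("cluster1", zcd_start, pats$cluster1$span)
      c2_start <- zcd_start + pats$cluster1$span + sp1
      add_feat("cluster2", c2_start, pats$cluster2$span)
      c3_start <- c2_start + pats$cluster2$span + sp2
      add_feat("cluster3", c3_start, pats$cluster3$span)
      add_feat("zcd", zcd_start, c3_start + pats$cluster3$span - zcd_start)
      if (plant_gdp) {
        add_feat("gdp_block", c2_start + pats$cluster2$span + gdp_at - 1L, 16L)
      }
      # apply substitution noise: constrained cluster positions at mu_c,
      # everything else at mu_u
      constr1 <- pats$cluster1$positions$kind != "wildcard"
      constr2 <- pats$cluster2$positions$kind != "wildcard"
      constr3 <- pats$cluster3$positions$kind != "wildcard"
      c1[constr1] <- mutate_chars(c1[constr1], mu_c)
      c2[constr2] <- mutate_chars(c2[constr2], mu_c)
      c3[constr3] <- mutate_chars(c3[constr3], mu_c)
      c1[!constr1] <- mutate_chars(c1[!constr1], mu_u)
      c2[!constr2] <- mutate_chars(c2[!constr2], mu_u)
      c3[!constr3] <- mutate_chars(c3[!constr3], mu_u)
      nt <- mutate_chars(nt, mu_u)
      spacer1 <- mutate_chars(spacer1, mu_u)
      spacer2 <- mutate_chars(spacer2, mu_u)
      full <- c(nt, c1, spacer1, c2, spacer2, c3,
                draw_background(tail_len, composition))
      seqs[[s]] <- tibble(id = id, species_tag = NA_character_,
                          residues = paste(full, collapse = ""))
      truths[[s]] <- bind_rows(feats)
    }
    list(sequences = bind_rows(seqs), truth = bind_rows(truths))
  })
}

#' Simulate background decoy sequences
#'
#' I.i.d. amino-acid sequences with no planted structure, for
#' false-positive estimation.
#'
#' @param n number of sequences (>= 1).
#' @param length sequence length.
#' @param composition as in [simulate_zcd_proteins()].
#' @param seed integer seed.
#' @return A sequence-record tibble.
#' @export
simulate_decoys <- function(n, length = 500L, composition = "uniform", seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  with_seed(seed, {
    tibble(
      id = sprintf("decoy_%04d", seq_len(n)),
      species_tag = NA_character_,
      residues = vapply(seq_len(n), function(i) {
        paste(draw_background(length, composition), collapse = "")
      }, character(1))
    )
  })
}

#' Evolve aligned sequences along a tree under the JTT model
#'
#' Site-independent Markov substitution: for each branch of length `t`
#' (substitutions per site) every site of the parent sequence is replaced
#' by a draw from `P(t) = exp(Qt)` under the JTT model. No indels are
#' simulated, so the leaves come back pre-aligned.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param root root sequence (string) or an integer length for a draw from
#'   the JTT equilibrium frequencies.
#' @param seed integer seed.
#' @param model substitution model; only `"JTT"` is supported.
#' @return A sequence-record tibble with one row per leaf (ids = tip
#'   labels), all rows the same length.
#' @export
evolve_along_tree <- function(tree, root = 300L, seed = NULL, model = "JTT") {
  if (!identical(toupper(model), "JTT")) abort("only the JTT model is supported")
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) abort("branch lengths must be non-negative")
  with_seed(seed, {
    root_chars <- if (is.numeric(root)) {
      sample(AA20, root, replace = TRUE, prob = unname(jtt_frequencies()))
    } else {
      strsplit(toupper(root), "", fixed = TRUE)[[1]]
    }
    if (!all(root_chars %in% AA20)) abort("root sequence must use the 20 standard residues")
    L <- length(root_chars)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nrow = nnode, ncol = L)
    root_node <- ntip + 1L
    states[root_node, ] <- match(root_chars, AA20)
    tree2 <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree2$edge))) {
      parent <- tree2$edge[e, 1]; child <- tree2$edge[e, 2]
      t_len <- tree2$edge.length[e]
      ps <- states[parent, ]
      if (t_len == 0) {
        states[child, ] <- ps
      } else {
        P <- jtt_prob_matrix(t_len)
        cum <- t(apply(P, 1, cumsum))
        u <- runif(L)
        states[child, ] <- rowSums(cum[ps, , drop = FALSE] < u) + 1L
      }
    }
    tibble(
      id = tree$tip.label,
      species_tag = parse_species_tag(tree$tip.label),
      residues = vapply(seq_len(ntip), function(i) {
        paste(AA20[states[i, ]], collapse = "")
      }, character(1))
    )
  })
}

#' Simulate gene neighborhoods with planted shared markers
#'
#' Each species receives one scaffold carrying a focal ZCD-like gene
#' flanked by the planted shared ortholog groups (at randomized in-window
#' offsets) plus species-private markers filling the remaining window
#' slots.
#'
#' @param n_species number of species (>= 2).
#' @param shared_groups character vector of ortholog-group labels planted
#'   in every species' window (may be empty).
#' @param k_private private flanking markers per side.
#' @param k window half-width the plant must fit into.
#' @param seed integer seed.
#' @return List with `neighborhoods` (flat tibble in the TSV schema of
#'   [read_neighborhoods()]) and `truth` (the planted shared group labels).
#' @export
simulate_neighborhoods <- function(n_species = 4, shared_groups = c("OG_alpha", "OG_beta"),
                                   k_private = 5, k = 5, seed = NULL) {
  if (n_species < 2) abort("need at least 2 species")
  if (length(shared_groups) > 2 * k) {
    abort("more shared groups than the window can hold")
  }
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_species), function(sp) {
      species <- sprintf("species_%02d", sp)
      n_side <- max(k_private, ceiling(length(shared_groups) / 2))
      n_flank <- 2 * n_side
      # flank indices 1..n_side are upstream (nearest = n_side), the rest
      # downstream (nearest = n_side + 1); keep plants within k of the focal
      kk <- min(k, n_side)
      slots_in_window <- c((n_side - kk + 1L):n_side, n_side + seq_len(kk))
      shared_at <- sample(slots_in_window, length(shared_groups))
      groups <- sprintf("%s_private_%02d", species, seq_len(n_flank))
      flank_groups <- groups
      flank_groups[shared_at] <- shared_groups
      focal_at <- n_side + 1L
      all_groups <- append(flank_groups, "OG_ZCD", after = n_side)
      tibble(
        species = species,
        scaffold = sprintf("scaf_%02d", sp),
        gene_id = sprintf("%s_g%02d", species, seq_len(n_flank + 1L)),
        ortholog_group = all_groups,
        position = seq_len(n_flank + 1L),
        focal_flag = seq_len(n_flank + 1L) == focal_at
      )
    })
    list(neighborhoods = bind_rows(rows), truth = shared_groups)
  })
}
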