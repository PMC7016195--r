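# End-to-end pipeline runners. Each writes its machine-readable outputs
# plus an echo of the effective configuration into `out_dir`, so a rerun
# with the same inputs and config reproduces the outputs byte for byte.
# Log messages go to stderr; files carry the results.

echo_config <- function(cfg, out_dir) {
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  if (is.null(path)) return(NULL)
  sc <- readr::read_tsv(path, col_types = "cl", comment = "#", progress = FALSE)
  names(sc)[1:2] <- c("seq_id", "has_p2x")
  sc
}

#' Scan a FASTA file for ZCD features and write reports
#'
#' Runs the full annotation pipeline and writes `annotations.tsv` (the
#' residue-annotation table), `reports.json` (per-sequence features, hits
#' and class) and `config.json` into `out_dir`. Zero hits is a valid
#' outcome, not an error.
#'
#' @param fasta_path input protein FASTA.
#' @param out_dir output directory (created if needed).
#' @param config a [zcd_config()].
#' @param sidecar_path optional TSV (`seq_id`, `has_p2x`) of precomputed
#'   P2X-domain calls overriding the heuristic.
#' @return The [zcd_annotate()] object, invisibly.
#' @export
run_scan <- function(fasta_path, out_dir, config = zcd_config(), sidecar_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta_path)
  ann <- zcd_annotate(records, config, sidecar = read_sidecar(sidecar_path))
  write_annotation_table(ann$residues, file.path(out_dir, "annotations.tsv"))
  reports <- purrr::map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    list(
      seq_id = id,
      length = nchar(records$residues[i]),
      zcd_hits = ann$hits[ann$hits$seq_id == id,
                          setdiff(names(ann$hits), "cluster_matches")],
      anchor = ann$anchors[ann$anchors$seq_id == id, ],
      gdp_site = ann$gdp[ann$gdp$seq_id == id, ],
      p2x = ann$p2x[ann$p2x$seq_id == id, ],
      class = ann$classes$class_label[ann$classes$seq_id == id]
    )
  })
  jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  echo_config(unclass(config), out_dir)
  invisible(ann)
}

#' Classify architectures of a FASTA file
#'
#' Writes one class row per sequence to `classes.tsv` plus `config.json`.
#'
#' @inheritParams run_scan
#' @return The classification tibble, invisibly.
#' @export
run_classify <- function(fasta_path, out_dir, config = zcd_config(), sidecar_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta_path)
  classes <- classify_architecture(records, config, sidecar = read_sidecar(sidecar_path))
  readr::write_tsv(classes, file.path(out_dir, "classes.tsv"), progress = FALSE)
  echo_config(unclass(config), out_dir)
  invisible(classes)
}

#' Build a bootstrapped NJ tree of ZCD regions
#'
#' From unaligned FASTA the ZCD regions are detected and aligned with the
#' motif-anchored aligner; an externally computed alignment can be supplied
#' instead (`aligned = TRUE`). Writes `tree.nwk`, `supports.tsv` and
#' `config.json`; distance-saturation events are reported on stderr.
#'
#' @param input_path FASTA (unaligned) or aligned FASTA.
#' @param out_dir output directory.
#' @param config a [zcd_config()] (detection step only).
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed integer seed for the bootstrap.
#' @param deletion,cap passed to [jtt_distance_matrix()].
#' @param aligned treat `input_path` as an aligned FASTA import.
#' @return The support-labelled `ape::phylo`, invisibly.
#' @export
run_tree <- function(input_path, out_dir, config = zcd_config(),
                     n_replicates = 100, seed = NULL,
                     deletion = "pairwise", cap = 10, aligned = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (aligned) {
    aln <- read_alignment(input_path)
  } else {
    records <- read_fasta(input_path)
    hits <- detect_zcd(records, config)
    if (length(unique(hits$seq_id)) < 4) {
      abort(paste0("found ZCD hits in only ", length(unique(hits$seq_id)),
                   " sequence(s); the bootstrapped tree needs at least 4 ",
                   "(supply more ZCD-bearing sequences or an alignment import)"))
    }
    aln <- anchored_alignment(hits, records)
  }
  D <- jtt_distance_matrix(alignment_matrix(aln), deletion = deletion, cap = cap)
  n_sat <- sum(attr(D, "saturated")) / 2
  if (n_sat > 0) inform(sprintf("%d pairwise distance(s) hit the saturation cap of %g", n_sat, cap))
  tree <- bootstrap_support(aln, n_replicates = n_replicates, seed = seed,
                            deletion = deletion, cap = cap)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  readr::write_tsv(support_table(tree), file.path(out_dir, "supports.tsv"),
                   progress = FALSE)
  echo_config(c(unclass(config),
                list(n_replicates = n_replicates, seed = seed,
                     deletion = deletion, cap = cap, aligned = aligned)),
              out_dir)
  invisible(tree)
}

#' Run the synteny-window comparison on a neighborhood TSV
#'
#' Writes pairwise reports (`pairs.tsv`), the conserved-synteny edge list
#' (`edges.tsv`), a GraphML rendering (`graph.graphml`), connected
#' components (`components.tsv`) and `config.json`. A file with fewer than
#' two neighborhoods yields empty outputs rather than an error.
#'
#' @param tsv_path neighborhood TSV (schema of [read_neighborhoods()]).
#' @param out_dir output directory.
#' @param k markers per side (default 5).
#' @param threshold minimum shared groups for an edge (default 1).
#' @return The [synteny_graph()] (or `NULL` for < 2 neighborhoods),
#'   invisibly.
#' @export
run_synteny <- function(tsv_path, out_dir, k = 5, threshold = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nbhd <- read_neighborhoods(tsv_path)
  echo_config(list(k = k, threshold = threshold), out_dir)
  empty_edges <- tibble(from = character(0), to = character(0),
                        weight = integer(0), shared_groups = character(0))
  if (nrow(nbhd) < 2) {
    inform("fewer than 2 neighborhoods: writing empty reports")
    readr::write_tsv(empty_edges, file.path(out_dir, "pairs.tsv"), progress = FALSE)
    readr::write_tsv(empty_edges, file.path(out_dir, "edges.tsv"), progress = FALSE)
    readr::write_tsv(tibble(focal_gene_id = nbhd$focal_gene_id,
                            component = seq_len(nrow(nbhd))),
                     file.path(out_dir, "components.tsv"), progress = FALSE)
    return(invisible(NULL))
  }
  wins <- purrr::map(seq_len(nrow(nbhd)), function(i) synteny_window(nbhd[i, ], k = k))
  pairs <- list()
  for (i in seq_len(length(wins) - 1)) {
    for (j in (i + 1):length(wins)) {
      pairs[[length(pairs) + 1L]] <- shared_markers(wins[[i]], wins[[j]], threshold)
    }
  }
  pairs <- bind_rows(pairs)
  pairs$shared_groups <- purrr::map_chr(pairs$shared_groups, paste, collapse = ",")
  readr::write_tsv(pairs, file.path(out_dir, "pairs.tsv"), progress = FALSE)
  g <- synteny_graph(nbhd, k = k, threshold = threshold)
  write_synteny_graph(g, file.path(out_dir, "edges.tsv"),
                      file.path(out_dir, "graph.graphml"))
  readr::write_tsv(g$components, file.path(out_dir, "components.tsv"), progress = FALSE)
  invisible(g)
}

#' Generate synthetic fixtures from the command line
#'
#' Writes simulated ZCD proteins (FASTA + truth JSON), decoys, or a
#' neighborhood TSV with planted shared markers into `out_dir`.
#'
#' @param out_dir output directory.
#' @param what one of `"zcd"`, `"decoys"`, `"neighborhoods"`.
#' @param n number of sequences / species.
#' @param seed integer seed.
#' @param ... forwarded to the corresponding generator.
#' @return The generator's return value, invisibly.
#' @export
run_simulate <- function(out_dir, what = c("zcd", "decoys", "neighborhoods"),
                         n = 10, seed = 1, ...) {
  what <- match.arg(what)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(what,
    zcd = {
      sim <- simulate_zcd_proteins(n_sequences = n, seed = seed, ...)
      write_fasta(sim$sequences, file.path(out_dir, "zcd_proteins.fasta"))
      jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      sim
    },
    decoys = {
      d <- simulate_decoys(n, seed = seed, ...)
      write_fasta(d, file.path(out_dir, "decoys.fasta"))
      d
    },
    neighborhoods = {
      sim <- simulate_neighborhoods(n_species = n, seed = seed, ...)
      readr::write_tsv(sim$neighborhoods, file.path(out_dir, "neighborhoods.tsv"),
                       progress = FALSE)
      jsonlite::write_json(list(shared_groups = sim$truth),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      sim
    })
  echo_config(list(what = what, n = n, seed = seed), out_dir)
  invisible(res)
}
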