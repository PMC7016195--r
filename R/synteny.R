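#' Read gene neighborhoods from a TSV
#'
#' Expects columns `species`, `scaffold`, `gene_id`, `ortholog_group`,
#' `position` (ordinal along the scaffold), `focal_flag` (TRUE/1 for the
#' focal ZCD-bearing gene). Each (species, scaffold) group becomes one
#' neighborhood and must contain the focal gene exactly once. Rows out of
#' positional order are sorted with a warning.
#'
#' @param path TSV path.
#' @return A nested tibble with one row per focal gene: `focal_gene_id`,
#'   `focal_group`, `species`, `scaffold`, and a `markers` list-column of
#'   position-sorted marker tibbles (focal gene included).
#' @export
read_neighborhoods <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    species = "c", scaffold = "c", gene_id = "c", ortholog_group = "c",
    position = "i", focal_flag = "c"
  ), comment = "#", progress = FALSE)
  missing <- setdiff(c("species", "scaffold", "gene_id", "ortholog_group",
                       "position", "focal_flag"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("neighborhood TSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  raw$focal_flag <- tolower(raw$focal_flag) %in% c("true", "1", "t", "yes")
  groups <- split(raw, paste(raw$species, raw$scaffold, sep = "\r"))
  out <- purrr::map(groups, function(g) {
    focal <- g[g$focal_flag, ]
    if (nrow(focal) == 0) {
      abort(sprintf("no focal gene on scaffold '%s' (%s)", g$scaffold[1], g$species[1]))
    }
    if (nrow(focal) > 1) {
      abort(sprintf("duplicate focal flag: %s", paste(focal$gene_id, collapse = ", ")))
    }
    if (is.unsorted(g$position)) {
      warn(sprintf("unsorted positions on scaffold '%s' (%s); sorting",
                   g$scaffold[1], g$species[1]))
      g <- g[order(g$position), ]
    }
    tibble(focal_gene_id = focal$gene_id, focal_group = focal$ortholog_group,
           species = g$species[1], scaffold = g$scaffold[1],
           markers = list(as_tibble(g[, c("gene_id", "ortholog_group",
                                          "position", "focal_flag")])))
  })
  out <- bind_rows(out)
  out[order(out$species, out$scaffold), , drop = FALSE]
}

#' Extract the flanking marker window of a neighborhood
#'
#' Returns up to `k` markers on each side of the focal gene (fewer at
#' scaffold ends), focal gene excluded, ordered by position.
#'
#' @param nbhd one row of the tibble returned by [read_neighborhoods()].
#' @param k markers per side (default 5).
#' @param gap_bound optional ordinal-gap bound: when set, markers whose
#'   positional gap to the previous window member exceeds it are flagged in
#'   a `long_gap` column (rendering of "distant on the same scaffold").
#' @return Marker tibble with a `side` column (`upstream`/`downstream`),
#'   carrying the focal gene id and ortholog group as attributes
#'   `focal_gene_id` / `focal_group`.
#' @export
synteny_window <- function(nbhd, k = 5, gap_bound = NULL) {
  stopifnot(k >= 1, nrow(nbhd) == 1)
  m <- nbhd$markers[[1]]
  fi <- which(m$focal_flag)
  up <- m[seq_len(fi - 1), , drop = FALSE]
  up <- tail(up, k)
  down <- m[seq(fi + 1, length.out = nrow(m) - fi), , drop = FALSE]
  down <- head(down, k)
  win <- bind_rows(
    if (nrow(up) > 0) mutate(up, side = "upstream"),
    if (nrow(down) > 0) mutate(down, side = "downstream")
  )
  if (is.null(win)) {
    win <- mutate(m[0, ], side = character(0))
  }
  if (!is.null(gap_bound) && nrow(win) > 0) {
    win$long_gap <- c(FALSE, diff(win$position) > gap_bound)
  }
  attr(win, "focal_gene_id") <- nbhd$focal_gene_id
  attr(win, "focal_group") <- nbhd$focal_group
  win
}

#' Shared ortholog groups between two marker windows
#'
#' Intersects the ortholog-group labels of two windows, excluding the focal
#' genes' own groups, and applies the conservation threshold. Symmetric
#' under argument swap.
#'
#' @param a,b marker windows from [synteny_window()].
#' @param threshold minimum shared groups to call the pair conserved
#'   (default 1; use 2 for the stricter ancestral-synteny criterion).
#' @return One-row tibble: `focal_a`, `focal_b`, `shared_groups`
#'   (list-column), `n_shared`, `conserved`.
#' @export
shared_markers <- function(a, b, threshold = 1) {
  exclude <- c(attr(a, "focal_group"), attr(b, "focal_group"))
  shared <- sort(intersect(setdiff(a$ortholog_group, exclude),
                           setdiff(b$ortholog_group, exclude)))
  tibble(
    focal_a = attr(a, "focal_gene_id") %||% NA_character_,
    focal_b = attr(b, "focal_gene_id") %||% NA_character_,
    shared_groups = list(shared),
    n_shared = length(shared),
    conserved = length(shared) >= threshold
  )
}

#' Conserved-synteny graph over all focal genes
#'
#' Compares every pair of neighborhoods via their `k`-marker windows and
#' builds an undirected graph on the focal genes with edges weighted by the
#' number of shared ortholog groups (edges below `threshold` dropped).
#' Connected components are the candidate ancestral synteny sets.
#'
#' @param neighborhoods tibble from [read_neighborhoods()] (>= 2 rows).
#' @param k markers per side.
#' @param threshold minimum shared groups for an edge.
#' @return A `synteny_graph`: list with `nodes` (focal gene tibble),
#'   `edges` (`from`, `to`, `weight`, `shared_groups`), `graph` (igraph)
#'   and `components` (tibble `focal_gene_id`, `component`).
#' @export
synteny_graph <- function(neighborhoods, k = 5, threshold = 1) {
  if (nrow(neighborhoods) < 2) abort("need at least 2 neighborhoods")
  wins <- purrr::map(seq_len(nrow(neighborhoods)), function(i) {
    synteny_window(neighborhoods[i, ], k = k)
  })
  n <- length(wins)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rep <- shared_markers(wins[[i]], wins[[j]], threshold = threshold)
      if (rep$conserved) pairs[[length(pairs) + 1L]] <- rep
    }
  }
  edges <- if (length(pairs) > 0) {
    bind_rows(pairs) %>%
      rename(from = "focal_a", to = "focal_b", weight = "n_shared") %>%
      select("from", "to", "weight", "shared_groups")
  } else {
    tibble(from = character(0), to = character(0), weight = integer(0),
           shared_groups = list())
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = neighborhoods$focal_gene_id)
  )
  comp <- igraph::components(g)
  structure(
    list(
      nodes = neighborhoods[, c("focal_gene_id", "focal_group", "species", "scaffold")],
      edges = edges,
      graph = g,
      components = tibble(focal_gene_id = names(comp$membership),
                          component = unname(comp$membership))
    ),
    class = "synteny_graph"
  )
}

#' @export
print.synteny_graph <- function(x, ...) {
  cat(sprintf("<synteny_graph> %d focal genes, %d edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), max(x$components$component)))
  invisible(x)
}

#' Write a synteny graph to disk
#'
#' Writes the edge list as TSV (`from`, `to`, `weight`, `shared_groups`
#' comma-collapsed) and the graph as GraphML.
#'
#' @param x a [synteny_graph()].
#' @param edges_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @return `edges_path`, invisibly.
#' @export
write_synteny_graph <- function(x, edges_path, graphml_path = NULL) {
  stopifnot(inherits(x, "synteny_graph"))
  flat <- x$edges
  flat$shared_groups <- purrr::map_chr(flat$shared_groups, paste, collapse = ",")
  readr::write_tsv(flat, edges_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(x$graph, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}
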