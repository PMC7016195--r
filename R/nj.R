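#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration on the Q-criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest label-sorted
#' pair (a joined node is represented by the smallest leaf label it
#' contains). Negative branch lengths are clamped to zero and the total
#' clamped deficit is recorded in the `"negative_deficit"` attribute of the
#' returned tree.
#'
#' @param d symmetric numeric matrix with row/column names (or a `dist`);
#'   at least 3 labels.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || is.null(rownames(d))) abort("need a labeled distance matrix")
  n <- nrow(d)
  if (n < 3) abort("neighbor-joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  fmt <- function(v) sprintf("%.12g", v)
  nodes <- rownames(d)                 # newick fragment per active node
  reps <- rownames(d)                  # smallest contained leaf label
  D <- unname(d)
  deficit <- 0
  clamp <- function(v) {
    if (v < 0) { deficit <<- deficit - v; 0 } else v
  }
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(reps[cand[, 1]], reps[cand[, 2]])
    key2 <- pmax(reps[cand[, 1]], reps[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newnode <- paste0("(", nodes[i], ":", fmt(vi), ",", nodes[j], ":", fmt(vj), ")")
    newrep <- min(reps[i], reps[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    reps <- c(reps[keep], newrep)
  }
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- paste0("(", nodes[1], ":", fmt(va), ",", nodes[2], ":", fmt(vb), ",",
                nodes[3], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_deficit") <- deficit
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the JTT-distance
#' NJ tree for each replicate, and labels every internal edge of the
#' full-alignment tree with the percentage of replicates containing the
#' same bipartition. Reproducible under a fixed seed. A degenerate
#' alignment (every column constant across rows) still yields supports but
#' is flagged via the `"degenerate"` attribute.
#'
#' @param aln an [anchored_alignment()] or character matrix (>= 4 rows).
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @param deletion,cap passed to [jtt_distance_matrix()].
#' @return The NJ tree (`ape::phylo`) with integer supports in
#'   `node.label` (root label empty) and attributes `n_replicates` and
#'   `degenerate`.
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed = NULL,
                              deletion = "pairwise", cap = 10) {
  mat <- alignment_matrix(aln)
  if (nrow(mat) < 4) abort("bootstrap support needs an alignment with >= 4 rows")
  degenerate <- all(apply(mat, 2, function(col) length(unique(col)) == 1))
  if (degenerate) warn("degenerate alignment: all columns identical across rows")
  tree <- nj_tree(jtt_distance_matrix(mat, deletion = deletion, cap = cap))
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    reps[[b]] <- nj_tree(jtt_distance_matrix(mat[, cols, drop = FALSE],
                                             deletion = deletion, cap = cap))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_replicates)
  labels <- as.character(support)
  labels[1] <- ""                      # basal trichotomy carries no bipartition
  tree$node.label <- labels
  attr(tree, "n_replicates") <- n_replicates
  attr(tree, "degenerate") <- degenerate
  tree
}

#' Bootstrap supports as a table
#'
#' @param tree a tree from [bootstrap_support()].
#' @return Tibble with one row per internal node: `node`, `support`, and
#'   the clade's tip labels collapsed with `,`.
#' @export
support_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$node.label))
  ntip <- length(tree$tip.label)
  nodes <- seq_len(tree$Nnode) + ntip
  tips <- purrr::map_chr(nodes, function(nd) {
    paste(sort(ape::extract.clade(tree, nd)$tip.label), collapse = ",")
  })
  tibble(node = nodes,
         support = suppressWarnings(as.integer(tree$node.label)),
         tips = tips)
}

#' Write a tree in Newick format
#'
#' Single-line standard Newick with branch lengths; integer bootstrap
#' supports, when present, are written as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
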