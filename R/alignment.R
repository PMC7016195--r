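#' Motif-anchored alignment of ZCD regions
#'
#' Aligns detected ZCD regions without a general-purpose aligner: the
#' cluster pattern columns are pinned exactly (every row carries the same
#' pattern offset in an anchor column) and the two inter-cluster spacers are
#' left-justified and gap-padded to the longest spacer. The ungapped content
#' of each row is exactly the extracted ZCD region of that sequence.
#'
#' @param hits output of [detect_zcd()] (one hit per sequence is used; at
#'   least 2 hits required).
#' @param records the sequence-record tibble the hits came from.
#' @return An `anchored_alignment`: list with `seq_ids`, `matrix` (rows =
#'   sequences, columns = alignment positions, gap `-`), and
#'   `anchor_columns` (indices pinned to pattern positions).
#' @export
anchored_alignment <- function(hits, records) {
  if (nrow(hits) < 2) abort("anchored alignment needs at least 2 ZCD hits")
  hits <- hits %>% group_by(.data$seq_id) %>% slice(1) %>% ungroup()
  pats <- zcd_cluster_patterns()
  spans <- vapply(pats, function(p) p$span, 1L)
  max_sp1 <- max(hits$spacer1)
  max_sp2 <- max(hits$spacer2)
  width <- sum(spans) + max_sp1 + max_sp2
  mat <- matrix(GAP_CHAR, nrow = nrow(hits), ncol = width)
  rownames(mat) <- hits$seq_id
  put <- function(row, at, text) {
    if (nchar(text) == 0) return(invisible())
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    mat[row, at:(at + length(chars) - 1L)] <<- chars
  }
  c1_at <- 1L
  s1_at <- c1_at + spans[["cluster1"]]
  c2_at <- s1_at + max_sp1
  s2_at <- c2_at + spans[["cluster2"]]
  c3_at <- s2_at + max_sp2
  for (r in seq_len(nrow(hits))) {
    res <- records$residues[records$id == hits$seq_id[r]]
    h <- hits[r, ]
    put(r, c1_at, substring(res, h$c1_start, h$c1_end))
    put(r, s1_at, substring(res, h$c1_end + 1L, h$c2_start - 1L))
    put(r, c2_at, substring(res, h$c2_start, h$c2_end))
    put(r, s2_at, substring(res, h$c2_end + 1L, h$c3_start - 1L))
    put(r, c3_at, substring(res, h$c3_start, h$c3_end))
  }
  anchor_cols <- c(c1_at:(c1_at + spans[["cluster1"]] - 1L),
                   c2_at:(c2_at + spans[["cluster2"]] - 1L),
                   c3_at:(c3_at + spans[["cluster3"]] - 1L))
  structure(list(seq_ids = hits$seq_id, matrix = mat,
                 anchor_columns = anchor_cols),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d sequences x %d columns (%d anchored)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$anchor_columns)))
  invisible(x)
}

#' @export
as.matrix.anchored_alignment <- function(x, ...) x$matrix

#' Import an externally computed alignment
#'
#' Reads aligned FASTA (e.g. from a general-purpose aligner) into the
#' character-matrix form used by the distance and tree functions, as an
#' alternative to [anchored_alignment()].
#'
#' @param path aligned-FASTA file.
#' @return A character matrix, rows named by sequence id.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path, allow_gaps = TRUE)
  lens <- nchar(recs$residues)
  if (length(unique(lens)) != 1) abort("aligned FASTA rows differ in length")
  mat <- do.call(rbind, strsplit(recs$residues, "", fixed = TRUE))
  rownames(mat) <- recs$id
  mat
}

alignment_matrix <- function(aln) {
  if (inherits(aln, "anchored_alignment")) return(aln$matrix)
  if (is.matrix(aln)) return(aln)
  abort("expected an anchored_alignment or a character matrix")
}
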