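#' Sequence record tables
#'
#' Protein sequences are carried throughout the package as ordinary tibbles
#' with one row per sequence ("sequence records"):
#' \describe{
#'   \item{id}{accession or name, unique within the table}
#'   \item{species_tag}{optional four-letter lowercase species code parsed
#'     from ids of the form `"dare_..."`; `NA` otherwise}
#'   \item{residues}{uppercase amino-acid string over the 20-letter alphabet
#'     plus `X` (unknown) and, in alignments only, `-` (gap)}
#' }
#' All coordinates reported by the package are 1-based and inclusive in
#' protein space.
#'
#' @param id character vector of sequence ids.
#' @param residues character vector of amino-acid strings (recycled against
#'   `id` must be the same length).
#' @return A validated sequence-record tibble.
#' @examples
#' sequence_records(c("hosa_P2X7", "seq2"), c("MKVLL", "PAWCACAAC"))
#' @export
sequence_records <- function(id, residues) {
  stopifnot(length(id) == length(residues))
  recs <- tibble(
    id = as.character(id),
    species_tag = parse_species_tag(id),
    residues = toupper(as.character(residues))
  )
  validate_sequence_records(recs)
}

parse_species_tag <- function(id) {
  tag <- stringr::str_match(id, "^([a-z]{4})_")[, 2]
  tag
}

#' @noRd
validate_sequence_records <- function(recs, allow_gaps = FALSE) {
  if (!all(c("id", "residues") %in% names(recs))) {
    abort("sequence records need `id` and `residues` columns")
  }
  dup <- recs$id[duplicated(recs$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(recs$residues))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(recs$id[!nzchar(recs$residues)], collapse = ", ")))
  }
  alphabet <- if (allow_gaps) c(AA_ALPHABET, GAP_CHAR) else AA_ALPHABET
  for (i in seq_len(nrow(recs))) {
    chars <- strsplit(recs$residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad) > 0) {
      abort(sprintf("invalid residue '%s' at position %d of sequence '%s'",
                    chars[bad[1]], bad[1], recs$id[i]))
    }
  }
  if (!"species_tag" %in% names(recs)) {
    recs$species_tag <- parse_species_tag(recs$id)
  }
  as_tibble(recs[, c("id", "species_tag", "residues"), drop = FALSE])
}

#' Read protein sequences from a FASTA file
#'
#' Reads plain (unaligned or aligned) protein FASTA. Sequences are uppercased;
#' trailing/internal `*` stop characters are stripped with a warning. Ids are
#' the full header lines up to the first whitespace. Duplicate ids, empty
#' files and characters outside the amino-acid alphabet (20 residues plus
#' `X`, and `-` when `allow_gaps = TRUE`) are errors that name the offending
#' record and position.
#'
#' @param path path to a FASTA file.
#' @param allow_gaps accept `-` gap characters (for aligned FASTA import).
#' @return A sequence-record tibble (see [sequence_records()]); record order
#'   follows file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warn("stop character '*' found in sequence(s); stripped")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  recs <- tibble(id = ids, species_tag = parse_species_tag(ids), residues = unname(seqs))
  validate_sequence_records(recs, allow_gaps = allow_gaps)
}

#' Write sequence records to FASTA
#'
#' Standard FASTA output wrapped at 60 columns per line.
#'
#' @param records a sequence-record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a residue-annotation table to TSV
#'
#' Writes the annotation tibble produced by [annotate_residues()] (or
#' [tidy()][tidy.zcd_annotation()] on a ZCD annotation object) as a TSV with
#' columns `seq_id`, `position`, `residue`, `label`, `motif_source` in
#' deterministic order (`seq_id`, then `position`). A header comment records
#' that positions are 1-based inclusive.
#'
#' @param annotations tibble with at least the five columns above.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  cols <- c("seq_id", "position", "residue", "label", "motif_source")
  missing <- setdiff(cols, names(annotations))
  if (length(missing) > 0) {
    abort(paste0("annotation table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- annotations[order(annotations$seq_id, annotations$position), cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 1-based inclusive protein coordinates", con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
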