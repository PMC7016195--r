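#' Scan sequences for a motif pattern
#'
#' Slides the compiled pattern over every window of each sequence and
#' reports all windows whose number of unsatisfied constrained positions is
#' at most `max_mismatch`. Wildcard positions never mismatch (an unknown
#' `X` residue satisfies wildcards but no constrained position); windows
#' containing a gap character are ineligible. Overlapping matches are all
#' reported — downstream callers resolve them.
#'
#' @param records a sequence-record tibble (or a single-row slice).
#' @param pattern a `motif_pattern` from [parse_pattern()].
#' @param max_mismatch mismatch budget over constrained positions.
#' @return Tibble sorted by `seq_id` then `start`: `pattern_name`, `seq_id`,
#'   `start`, `end` (1-based inclusive), `matched_text`, `n_constrained`,
#'   `n_satisfied`, and list-column `mismatch_positions` of absolute
#'   1-based sequence positions that failed.
#' @export
scan_motif <- function(records, pattern, max_mismatch = 0L) {
  stopifnot(inherits(pattern, "motif_pattern"), max_mismatch >= 0)
  out <- purrr::map2(records$id, records$residues, scan_one,
                     pattern = pattern, max_mismatch = max_mismatch)
  bind_rows(out)
}

scan_one <- function(seq_id, residues, pattern, max_mismatch) {
  empty <- tibble(
    pattern_name = character(0), seq_id = character(0),
    start = integer(0), end = integer(0), matched_text = character(0),
    n_constrained = integer(0), n_satisfied = integer(0),
    mismatch_positions = list()
  )
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  span <- pattern$span
  if (span > L) return(empty)
  starts <- seq_len(L - span + 1L)
  # gap-containing windows are ineligible
  gap_cum <- c(0L, cumsum(chars == GAP_CHAR))
  has_gap <- (gap_cum[starts + span] - gap_cum[starts]) > 0L
  constr <- pattern$positions[pattern$positions$kind != "wildcard", ]
  k <- nrow(constr)
  if (k == 0) {
    keep <- starts[!has_gap]
    return(tibble(
      pattern_name = pattern$name, seq_id = seq_id,
      start = keep, end = keep + span - 1L,
      matched_text = substring(residues, keep, keep + span - 1L),
      n_constrained = 0L, n_satisfied = 0L,
      mismatch_positions = rep(list(integer(0)), length(keep))
    ))
  }
  fail <- vapply(seq_len(k), function(j) {
    !(chars[starts + constr$offset[j] - 1L] %in% constr$allowed[[j]])
  }, logical(length(starts)))
  fail <- matrix(fail, nrow = length(starts))
  n_mm <- rowSums(fail)
  keep <- which(!has_gap & n_mm <= max_mismatch)
  if (length(keep) == 0) return(empty)
  tibble(
    pattern_name = pattern$name, seq_id = seq_id,
    start = starts[keep], end = starts[keep] + span - 1L,
    matched_text = substring(residues, starts[keep], starts[keep] + span - 1L),
    n_constrained = k,
    n_satisfied = as.integer(k - n_mm[keep]),
    mismatch_positions = purrr::map(keep, function(w) {
      as.integer(starts[w] + constr$offset[which(fail[w, ])] - 1L)
    })
  )
}
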