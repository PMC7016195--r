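#' Compile a consensus-pattern notation string
#'
#' Compiles the compact consensus notation used in the comparative P2X7
#' literature into a scannable motif object. The grammar, left to right:
#' \itemize{
#'   \item an uppercase amino-acid letter is an exact position (`"W"`);
#'   \item `"(A/B/C)"`, or a bare trailing alternative such as `"S/T"`
#'     binding to the single preceding letter, is a residue class;
#'   \item `"x"` is one wildcard position; `"x3"`, `"x(3)"` and `"x_3_"`
#'     are runs of three wildcards.
#' }
#' Input is case-insensitive (`x`/`X` is always the wildcard token; `X` is
#' not a pattern residue). So `"LCCRx3GxCITTS/T"` compiles to the 14-residue
#' motif L C C R x x x G x C I T T (S/T).
#'
#' @param text consensus notation string.
#' @param name pattern name carried into match tables.
#' @return A `motif_pattern` object: element table, per-position allowed
#'   sets, total span and constrained-position count.
#' @examples
#' parse_pattern("PxWCxCx2C", "cluster1")
#' @export
parse_pattern <- function(text, name = text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    abort("pattern text must be a non-empty string")
  }
  src <- toupper(gsub("\\s", "", text))
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- list()
  i <- 1
  take_count <- function(i) {
    # after an 'X': optional digits, "(digits)" or "_digits_"
    if (i <= n && grepl("[0-9]", chars[i])) {
      j <- i
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1
      return(list(count = as.integer(paste(chars[i:(j - 1)], collapse = "")), nxt = j))
    }
    if (i + 1 <= n && chars[i] == "(" && grepl("[0-9]", chars[i + 1])) {
      j <- i + 1
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1
      if (j > n || chars[j] != ")") abort("unbalanced parentheses in wildcard count")
      return(list(count = as.integer(paste(chars[(i + 1):(j - 1)], collapse = "")), nxt = j + 1))
    }
    if (i + 1 <= n && chars[i] == "_" && grepl("[0-9]", chars[i + 1])) {
      j <- i + 1
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1
      if (j > n || chars[j] != "_") abort("unterminated '_N_' wildcard count")
      return(list(count = as.integer(paste(chars[(i + 1):(j - 1)], collapse = "")), nxt = j + 1))
    }
    list(count = 1L, nxt = i)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      cnt <- take_count(i + 1)
      if (cnt$count < 1) abort("zero-length wildcard run")
      elements[[length(elements) + 1]] <-
        list(kind = "wildcard", residues = character(0), length = cnt$count)
      i <- cnt$nxt
    } else if (ch == "(") {
      j <- i + 1
      members <- character(0)
      expect_letter <- TRUE
      while (j <= n && chars[j] != ")") {
        if (expect_letter) {
          if (!chars[j] %in% AA20) abort(sprintf("invalid residue '%s' in class", chars[j]))
          members <- c(members, chars[j])
        } else if (chars[j] != "/") {
          abort("malformed residue class: expected '/'")
        }
        expect_letter <- !expect_letter
        j <- j + 1
      }
      if (j > n) abort("unbalanced parentheses in pattern")
      if (length(members) < 2) abort("residue class needs at least two alternatives")
      elements[[length(elements) + 1]] <-
        list(kind = "class", residues = unique(members), length = 1L)
      i <- j + 1
    } else if (ch %in% AA20) {
      members <- ch
      j <- i + 1
      while (j + 1 <= n && chars[j] == "/" && chars[j + 1] %in% AA20) {
        members <- c(members, chars[j + 1])
        j <- j + 2
      }
      kind <- if (length(members) > 1) "class" else "exact"
      elements[[length(elements) + 1]] <-
        list(kind = kind, residues = unique(members), length = 1L)
      i <- j
    } else {
      abort(sprintf("unexpected character '%s' in pattern notation", ch))
    }
  }
  if (length(elements) == 0) abort("pattern compiled to zero elements")
  el <- tibble(
    kind = purrr::map_chr(elements, "kind"),
    residues = purrr::map(elements, "residues"),
    length = purrr::map_int(elements, "length")
  )
  pos <- tibble(
    offset = seq_len(sum(el$length)),
    kind = rep(el$kind, el$length),
    allowed = rep(el$residues, el$length)
  )
  structure(
    list(name = name, elements = el, positions = pos,
         span = nrow(pos), n_constrained = sum(pos$kind != "wildcard")),
    class = "motif_pattern"
  )
}

#' @export
format.motif_pattern <- function(x, ...) {
  piece <- function(kind, residues, length) {
    if (kind == "wildcard") {
      if (length == 1L) "x" else paste0("x", length)
    } else if (kind == "exact") {
      residues[[1]]
    } else {
      paste0("(", paste(residues, collapse = "/"), ")")
    }
  }
  paste(purrr::pmap_chr(x$elements, function(kind, residues, length) {
    piece(kind, residues, length)
  }), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (span %d, %d constrained)\n",
              x$name, format(x), x$span, x$n_constrained))
  invisible(x)
}

#' Count cysteine-capable positions of a compiled pattern
#'
#' With `include_optional = TRUE`, counts every pattern position whose
#' allowed residue set contains cysteine (so a `(C/S)` class counts); with
#' `FALSE`, counts only positions where cysteine is the sole allowed
#' residue. Across the three ZCD cluster consensus patterns this yields the
#' domain's seven obligate / eight total conserved cysteines.
#'
#' @param pattern a `motif_pattern`.
#' @param include_optional include positions where C is one of several
#'   alternatives.
#' @return Integer count.
#' @export
count_cysteine_positions <- function(pattern, include_optional = TRUE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  has_c <- purrr::map_lgl(pattern$positions$allowed, function(a) "C" %in% a)
  only_c <- purrr::map_lgl(pattern$positions$allowed, function(a) identical(a, "C"))
  if (include_optional) sum(has_c) else sum(only_c)
}

#' Bundled consensus patterns
#'
#' Returns the pattern table shipped with the package: the three ZCD
#' cysteine-cluster consensuses, the C-cys anchor motifs (full mammalian
#' 18-mer, SxxCC core, teleost and gar contexts), the GDP-binding-site
#' templates, and the WRF / LPS-like WRIRx5G motifs. Users can scan their
#' own notation via [parse_pattern()] without touching this table.
#'
#' @param compiled return a named list of compiled `motif_pattern` objects
#'   instead of the raw table.
#' @return A tibble with columns `name`, `notation`, `description`, or a
#'   named list of compiled patterns.
#' @export
zcd_patterns <- function(compiled = FALSE) {
  path <- system.file("extdata", "zcd_patterns.tsv", package = "zcdtools")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (!compiled) return(tab)
  setNames(purrr::map2(tab$notation, tab$name, parse_pattern), tab$name)
}

# Compiled cluster patterns, memoised per session.
zcd_cluster_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pats <- zcd_patterns(compiled = TRUE)
      cache <<- pats[c("cluster1", "cluster2", "cluster3")]
    }
    cache
  }
})

bundled_pattern <- function(name) {
  zcd_patterns(compiled = TRUE)[[name]]
}
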