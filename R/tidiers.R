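#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ZCD annotation object
#'
#' Returns the per-residue annotation table (`seq_id`, `position`,
#' `residue`, `label`, `motif_source`, `human_equiv`).
#'
#' @param x a [zcd_annotate()] object.
#' @param ... unused.
#' @method tidy zcd_annotation
#' @export
tidy.zcd_annotation <- function(x, ...) {
  x$residues
}

#' One-row-per-sequence summary of a ZCD annotation
#'
#' Architecture class, P2X score, ZCD bounds and feature counts per
#' sequence.
#'
#' @param x a [zcd_annotate()] object.
#' @param ... unused.
#' @method glance zcd_annotation
#' @export
glance.zcd_annotation <- function(x, ...) {
  counts <- x$residues %>%
    group_by(.data$seq_id) %>%
    summarise(n_annotations = n(),
              n_zn_cys = sum(.data$label == "ZN_CYS"), .groups = "drop")
  x$classes %>%
    left_join(counts, by = "seq_id") %>%
    mutate(n_annotations = ifelse(is.na(.data$n_annotations), 0L, .data$n_annotations),
           n_zn_cys = ifelse(is.na(.data$n_zn_cys), 0L, .data$n_zn_cys))
}
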