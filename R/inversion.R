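# Classification of template-switch events from parent/child sequence
# pairs at an IR: arm homogenization, complete spacer inversion, or both.

#' Classify a template-switch event at an IR
#'
#' Compares the parent (ancestral) and child (strain) sequences over an IR
#' footprint. The spacer test flags a complete spacer inversion when the
#' child spacer equals the reverse complement of the parent spacer and
#' differs from it; the arm test flags arm homogenization when the parent
#' arms are imperfect as a pair while the child arms are perfect. Both
#' flags give a combined event; neither gives `NULL` (a spacer that is its
#' own reverse complement leaves an inversion unobservable).
#'
#' @param parent_region,child_region Equal-length gap-free strings covering
#'   the IR footprint (parent typically from the marginal ancestral
#'   reconstruction of the leaf's parent node).
#' @param ir The IR in the child region: a one-row data.frame from
#'   [find_perfect_irs()] or a list with `arm_len`, `spacer_len` and
#'   optionally `left_start` (0-based within the region, default 0).
#' @return `NULL`, or a list of class `template_switch_event`: `kind`
#'   (`arm_homogenization`, `spacer_inversion` or `combined`),
#'   `n_substitutions`, `arm_diffs`, `spacer_diffs`,
#'   `parent_arms_perfect` (were the parent arms already a perfect pair),
#'   `parent_spacer`, `child_spacer`.
#' @examples
#' classify_event("TGCCCGACGATaaATCGTCGGGCA", "TGCCCGACGATttATCGTCGGGCA",
#'                list(arm_len = 11, spacer_len = 2))
#' @export
classify_event <- function(parent_region, child_region, ir) {
  parent_region <- toupper(parent_region)
  child_region <- toupper(child_region)
  if (nchar(parent_region) != nchar(child_region)) {
    stop("classify_event(): parent/child region length mismatch")
  }
  ls <- (ir$left_start %||% 0L)
  a <- ir$arm_len
  sp <- ir$spacer_len
  seg <- function(seq, from, len) substr0(seq, from, from + len)
  c_left <- seg(child_region, ls, a)
  c_spacer <- seg(child_region, ls + a, sp)
  c_right <- seg(child_region, ls + a + sp, a)
  if (c_right != reverse_complement(c_left)) {
    stop("classify_event(): child region does not carry the stated perfect IR")
  }
  p_left <- seg(parent_region, ls, a)
  p_spacer <- seg(parent_region, ls + a, sp)
  p_right <- seg(parent_region, ls + a + sp, a)
  spacer_inverted <- sp > 0L && c_spacer == reverse_complement(p_spacer) &&
    c_spacer != p_spacer
  parent_arms_perfect <- p_right == reverse_complement(p_left)
  arms_homogenized <- !parent_arms_perfect
  if (!spacer_inverted && !arms_homogenized) return(NULL)
  arm_diffs <- n_diffs(p_left, c_left) + n_diffs(p_right, c_right)
  spacer_diffs <- if (sp > 0L) n_diffs(p_spacer, c_spacer) else 0L
  kind <- if (spacer_inverted && arms_homogenized) "combined"
          else if (spacer_inverted) "spacer_inversion"
          else "arm_homogenization"
  structure(list(kind = kind,
                 n_substitutions = arm_diffs + spacer_diffs,
                 arm_diffs = arm_diffs, spacer_diffs = spacer_diffs,
                 parent_arms_perfect = parent_arms_perfect,
                 parent_spacer = p_spacer, child_spacer = c_spacer),
            class = "template_switch_event")
}

#' @export
print.template_switch_event <- function(x, ...) {
  cat(sprintf("template switch: %s (%d substitutions: %d arm, %d spacer)\n",
              x$kind, x$n_substitutions, x$arm_diffs, x$spacer_diffs))
  invisible(x)
}

#' Tally independent recurrences of the same event
#'
#' Counts, for each (gene, IR footprint, kind, derived form) combination,
#' the number of distinct terminal branches on which the event occurred --
#' the signature of parallel evolution through repeated template switching.
#'
#' @param events Data.frame with at least `gene`, `taxon`, `kind`, a
#'   footprint coordinate column (`col_left_start` or `left_start`), and
#'   optionally `child_spacer` (distinguishes the two forms of a flip
#'   inversion).
#' @return Data.frame: grouping columns plus `n_branches` and `taxa`.
#' @export
count_parallel_events <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(gene = character(), footprint = integer(),
                      kind = character(), n_branches = integer(),
                      taxa = character()))
  }
  fp <- events$col_left_start %||% events$left_start
  form <- events$child_spacer %||% ""
  key <- paste(events$gene, fp, events$kind, form, sep = "\r")
  parts <- split(seq_len(nrow(events)), key)
  do.call(rbind, lapply(parts, function(i) {
    taxa <- unique(events$taxon[i])
    data.frame(gene = events$gene[i[1L]], footprint = fp[i[1L]],
               kind = events$kind[i[1L]],
               n_branches = length(taxa),
               taxa = paste(sort(taxa), collapse = ","),
               row.names = NULL)
  }))
}
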