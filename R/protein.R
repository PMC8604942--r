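# Protein-level consequences of template-switch events: amino-acid
# replacements with Grantham distances, codon-span classes, and
# transition/transversion tallies.

#' Amino-acid consequences of an event on a CDS pair
#'
#' Translates both sequences in the anchored frame and lists the per-codon
#' replacements, optionally restricted to the codons overlapped by the
#' event's nucleotide columns. The event's span class records whether it
#' touches one codon, two neighboring codons, or more.
#'
#' @param parent_cds,child_cds Equal-length gap-free in-frame sequences.
#' @param event_columns Optional 0-based nucleotide columns of the event
#'   (vector of positions, or `c(start, end)` half-open when length 2 and
#'   increasing); must lie inside the CDS at or after `frame_offset`.
#' @param frame_offset 0, 1 or 2; bases skipped before the first codon.
#' @param grantham_threshold Distance above which a replacement is flagged
#'   `high_distance` (default 120).
#' @return List: `replacements` (data.frame: `position` 1-based codon index
#'   in the anchored frame, `from_codon`, `to_codon`, `from_aa`, `to_aa`,
#'   `synonymous`, `grantham`, `high_distance`), `span_class`
#'   (`one_codon` / `two_codons` / `multi` / `none`), `synonymous_only`.
#' @export
aa_consequences <- function(parent_cds, child_cds, event_columns = NULL,
                            frame_offset = 0L, grantham_threshold = 120L) {
  parent_cds <- toupper(parent_cds)
  child_cds <- toupper(child_cds)
  stopifnot(nchar(parent_cds) == nchar(child_cds))
  frame_offset <- as.integer(frame_offset)
  L <- nchar(parent_cds)
  n_codon <- (L - frame_offset) %/% 3L
  codon_at <- function(seq, i) {
    substr0(seq, frame_offset + 3L * (i - 1L), frame_offset + 3L * i)
  }
  if (!is.null(event_columns)) {
    cols <- as.integer(event_columns)
    if (length(cols) == 2L && cols[2L] > cols[1L] + 1L) {
      cols <- cols[1L]:(cols[2L] - 1L)
    }
    if (any(cols < frame_offset) ||
        any(cols >= frame_offset + 3L * n_codon)) {
      stop("aa_consequences(): event columns outside the anchored CDS")
    }
    touched <- sort(unique((cols - frame_offset) %/% 3L)) + 1L
  } else {
    touched <- seq_len(n_codon)
  }
  rows <- list()
  for (i in touched) {
    pc <- codon_at(parent_cds, i)
    cc <- codon_at(child_cds, i)
    if (pc == cc) next
    pa <- translate_dna(pc)
    ca <- translate_dna(cc)
    g <- if (pa %in% rownames(grantham_matrix()) &&
             ca %in% rownames(grantham_matrix())) {
      grantham_distance(pa, ca)
    } else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      position = i, from_codon = pc, to_codon = cc,
      from_aa = pa, to_aa = ca, synonymous = pa == ca,
      grantham = g,
      high_distance = !is.na(g) && g > grantham_threshold)
  }
  reps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), from_codon = character(),
               to_codon = character(), from_aa = character(),
               to_aa = character(), synonymous = logical(),
               grantham = integer(), high_distance = logical())
  n_changed <- if (is.null(event_columns)) nrow(reps) else {
    length(touched[vapply(touched, function(i)
      codon_at(parent_cds, i) != codon_at(child_cds, i), TRUE)])
  }
  span_class <- if (n_changed == 0L) "none"
    else if (n_changed == 1L) "one_codon"
    else if (n_changed == 2L) "two_codons"
    else "multi"
  list(replacements = reps, span_class = span_class,
       synonymous_only = nrow(reps) > 0L && all(reps$synonymous))
}

#' Transition/transversion tally of event substitutions
#'
#' Purine-purine and pyrimidine-pyrimidine changes (A<->G, C<->T) count as
#' transitions; all other base changes as transversions.
#'
#' @param x Either a data.frame with columns `from` and `to` (one base
#'   change per row), or a string of parent bases (then `y` gives the
#'   child bases, position by position).
#' @param y Optional child string when `x` is a string.
#' @return List: `transitions`, `transversions`, `ratio` (`ts/tv`; `Inf`
#'   when there are transitions but no transversions, `NaN` when there are
#'   no substitutions at all).
#' @examples
#' ts_tv_tally(data.frame(from = c("A", "C", "A"), to = c("G", "T", "C")))
#' @export
ts_tv_tally <- function(x, y = NULL) {
  if (is.character(x)) {
    stopifnot(!is.null(y), nchar(x) == nchar(y))
    a <- strsplit(toupper(x), "")[[1L]]
    b <- strsplit(toupper(y), "")[[1L]]
    d <- a != b & a %in% .BASES & b %in% .BASES
    x <- data.frame(from = a[d], to = b[d])
  }
  from <- toupper(x$from); to <- toupper(x$to)
  chg <- from != to
  is_ts <- chg & paste0(pmin(from, to), pmax(from, to)) %in% c("AG", "CT")
  ts <- sum(is_ts)
  tv <- sum(chg) - ts
  list(transitions = ts, transversions = tv,
       ratio = if (tv == 0L && ts == 0L) NaN else ts / tv)
}
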