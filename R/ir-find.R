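#' Find maximal perfect inverted repeats in a sequence
#'
#' Detects every maximal perfect inverted repeat (IR): two arms in exact
#' reverse-complement orientation around a spacer, with the arms not
#' extendable on either side (neither outward into the flanks nor inward
#' into the spacer). Positions containing `N` never pair. Gaps (`-`) are
#' stripped before scanning and all coordinates refer to the ungapped
#' sequence; use [ir_alignment_columns()] to map footprints back onto
#' alignment columns.
#'
#' @param seq A single character string (case-insensitive; may contain `-`).
#' @param min_arm Minimum arm length in bp (default 7; must be >= 2).
#' @param max_spacer Maximum spacer length in bp (default 70).
#' @param seq_id Label recorded in the output.
#' @return A data.frame with one row per IR and 0-based half-open
#'   coordinates: `seq_id`, `left_start`, `arm_len`, `spacer_len`,
#'   `right_end` (`= left_start + 2*arm_len + spacer_len`).
#' @examples
#' find_perfect_irs("TGCCCGACGATttATCGTCGGGCA")  # arm 11, spacer 2
#' @export
find_perfect_irs <- function(seq, min_arm = 7L, max_spacer = 70L,
                             seq_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  min_arm <- as.integer(min_arm)
  max_spacer <- as.integer(max_spacer)
  if (min_arm < 2L) stop("find_perfect_irs(): min_arm must be >= 2")
  if (max_spacer < 0L) stop("find_perfect_irs(): max_spacer must be >= 0")
  s <- toupper(gsub("-", "", seq, fixed = TRUE))
  if (grepl("[^ACGTN]", s)) stop("find_perfect_irs(): invalid characters")
  m <- .ir_scan_c(s, min_arm, max_spacer)
  out <- data.frame(
    seq_id = rep(seq_id, nrow(m)),
    left_start = m[, 1L],
    arm_len = m[, 2L],
    spacer_len = m[, 3L],
    right_end = m[, 1L] + 2L * m[, 2L] + m[, 3L],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$left_start, out$right_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin IRs by arm length and apply the overlap/nesting rules
#'
#' Each maximal IR belongs to the bin of its (maximal) arm length, and each
#' bin is analyzed separately. Within a bin and a strain, IRs whose
#' footprints overlap are all removed -- unless one is fully nested inside
#' the other, in which case both are kept.
#'
#' @param irs Data.frame as returned by [find_perfect_irs()] (one or more
#'   strains; rows are grouped by `seq_id` internally).
#' @return Named list mapping arm length to the data.frame of retained IRs.
#' @export
bin_and_deduplicate <- function(irs) {
  if (nrow(irs) == 0L) return(setNames(list(), character()))
  bins <- split(irs, irs$arm_len)
  lapply(bins, function(df) {
    keep <- rep(TRUE, nrow(df))
    for (grp in split(seq_len(nrow(df)), df$seq_id)) {
      keep[grp] <- .dedup_keep(df$left_start[grp], df$right_end[grp])
    }
    df[keep, , drop = FALSE]
  })
}

# overlap/nesting rule for one strain's IRs within one bin: overlapping
# footprints are all dropped unless fully nested (then both kept)
.dedup_keep <- function(st, en) {
  n <- length(st)
  keep <- rep(TRUE, n)
  if (n < 2L) return(keep)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (st[i] < en[j] && st[j] < en[i]) {
      nested <- (st[i] <= st[j] && en[j] <= en[i]) ||
                (st[j] <= st[i] && en[i] <= en[j])
      if (!nested) keep[c(i, j)] <- FALSE
    }
  }
  keep
}

#' Map IR footprint coordinates onto alignment columns
#'
#' @param irs Data.frame from [find_perfect_irs()] run on the ungapped
#'   sequence of one alignment row.
#' @param aligned_seq The gapped alignment row the IRs came from.
#' @return `irs` with added 0-based alignment-column interval columns
#'   (`col_left_start`, `col_spacer_start`, `col_spacer_end`, `col_right_end`).
#'   Intervals are half-open; internal gap columns (in other rows) are
#'   spanned.
#' @export
ir_alignment_columns <- function(irs, aligned_seq) {
  map <- attr(strip_gaps(toupper(aligned_seq)), "map")
  # position p (0-based, ungapped) sits at column map[p+1]; the half-open
  # end of an interval ending at ungapped p maps to map[p] + 1
  end_col <- function(p) map[p] + 1L
  irs$col_left_start <- map[irs$left_start + 1L]
  irs$col_spacer_start <- end_col(irs$left_start + irs$arm_len)
  irs$col_spacer_end <- map[irs$left_start + irs$arm_len + irs$spacer_len + 1L]
  irs$col_right_end <- end_col(irs$right_end)
  irs
}

#' Write an IR table to TSV
#'
#' Columns: `seq_id`, `arm_len`, `spacer_len`, `left_start`, `right_end`
#' (0-based half-open).
#'
#' @param irs Data.frame from [find_perfect_irs()].
#' @param path Output file.
#' @export
write_ir_table <- function(irs, path) {
  write.table(irs[, c("seq_id", "arm_len", "spacer_len", "left_start", "right_end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fast paths used by the null-replicate loop -------------------------------

# raw per-strain scan matrices (gap-free sequences assumed)
.scan_strains <- function(seqs, min_arm, max_spacer) {
  lapply(seqs, .ir_scan_c, min_arm = min_arm, max_spacer = max_spacer)
}

# number of distinct retained IR footprints of one arm-length bin, unioned
# over strains, from scan matrices (scanned at min_arm <= bin).  An IR locus
# shared by several strains counts once: the null-set condition matches
# distinct IRs, since a conserved IR is present in every strain and an
# instance count would make long-arm bins impossible to satisfy.
.count_bin_from_scan <- function(scans, bin) {
  keys <- integer(0)
  for (m in scans) {
    m <- m[m[, 2L] == bin, , drop = FALSE]
    n <- nrow(m)
    if (n == 0L) next
    if (n > 1L) {
      en <- m[, 1L] + 2L * m[, 2L] + m[, 3L]
      m <- m[.dedup_keep(m[, 1L], en), , drop = FALSE]
    }
    keys <- c(keys, (m[, 1L] * 1000L + m[, 2L]) * 128L + m[, 3L])
  }
  length(unique(keys))
}

.count_bin_irs <- function(seqs, bin, max_spacer = 70L) {
  .count_bin_from_scan(.scan_strains(seqs, bin, max_spacer), bin)
}
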