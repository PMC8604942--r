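# Multinucleotide mutation (MNM) calling on terminal branches, association
# of MNMs with IR footprints, and the alignment-quality / saturation filters.

#' Prefilter an ortholog sequence set
#'
#' Drops sequences with more than `max_n` ambiguous bases (`N`), then
#' rejects the whole set when fewer than `min_strains` strain sequences
#' remain (the outgroup, when named, is exempt from the strain count and
#' never dropped by it).
#'
#' @param seqs Named character vector of sequences (aligned or not).
#' @param max_n Maximum tolerated `N` count per sequence (default 20).
#' @param min_strains Minimum surviving strains (default 4).
#' @param outgroup Optional outgroup label.
#' @return The kept sequences (possibly empty, with attribute `reason`).
#' @export
prefilter_orthoset <- function(seqs, max_n = 20L, min_strains = 4L,
                               outgroup = NULL) {
  n_count <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
  }, integer(1L))
  kept <- seqs[n_count <= max_n]
  n_strains <- sum(!names(kept) %in% outgroup)
  if (n_strains < min_strains) {
    return(structure(seqs[0L], reason = sprintf(
      "fewer than %d strains after N filter (%d left)", min_strains, n_strains)))
  }
  kept
}

#' Call multinucleotide mutations on terminal branches
#'
#' An MNM is a maximal run of two or more strictly contiguous alignment
#' columns that are each substituted between a leaf and its immediate
#' parent-node reconstruction. Columns carrying a gap or `N` in either
#' sequence are never part of a run (indels are not substitutions), and
#' only terminal branches are scanned.
#'
#' @param alignment A [codon_alignment()] (or named character vector).
#' @param tree Rooted `phylo` tree over the alignment taxa.
#' @param ancestors Result of [reconstruct_ancestors()], or a named
#'   character vector of internal-node sequences (names matching the node
#'   labels used there, i.e. `Node<k>` by ape node number when the tree is
#'   unlabelled).
#' @param exclude Leaf labels not to scan (e.g. the outgroup).
#' @return Data.frame: `taxon`, `start_col`, `end_col` (0-based half-open
#'   alignment columns), `length`, `parent_alleles`, `child_alleles`.
#' @export
call_mnms <- function(alignment, tree, ancestors, exclude = NULL) {
  states <- if (is.list(ancestors)) ancestors$states else ancestors
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip)
  parent_of[tree$edge[tree$edge[, 2L] <= ntip, 2L]] <-
    tree$edge[tree$edge[, 2L] <= ntip, 1L]
  labs <- tree$node.label
  node_lab <- if (!is.null(labs) && all(labs != "") && !anyDuplicated(labs)) {
    setNames(labs, as.character((ntip + 1L):(ntip + tree$Nnode)))
  } else {
    setNames(paste0("Node", (ntip + 1L):(ntip + tree$Nnode)),
             as.character((ntip + 1L):(ntip + tree$Nnode)))
  }
  taxon_v <- character(); start_v <- integer(); len_v <- integer()
  pa_v <- character(); ca_v <- character()
  for (i in seq_len(ntip)) {
    taxon <- tree$tip.label[i]
    if (taxon %in% exclude) next
    plab <- node_lab[[as.character(parent_of[i])]]
    if (is.null(plab) || !plab %in% names(states)) {
      stop("call_mnms(): no ancestral sequence for parent of '", taxon, "'")
    }
    child <- alignment[[taxon]]
    parent <- states[[plab]]
    if (nchar(child) != nchar(parent)) {
      stop("call_mnms(): ancestor/leaf length mismatch for '", taxon, "'")
    }
    runs <- .mnm_runs_c(child, parent, 2L)
    if (nrow(runs) > 0L) {
      s0 <- runs[, 1L]; len <- runs[, 2L]
      taxon_v <- c(taxon_v, rep(taxon, length(s0)))
      start_v <- c(start_v, s0)
      len_v <- c(len_v, len)
      pa_v <- c(pa_v, substring(parent, s0 + 1L, s0 + len))
      ca_v <- c(ca_v, substring(child, s0 + 1L, s0 + len))
    }
  }
  data.frame(taxon = taxon_v, start_col = start_v, end_col = start_v + len_v,
             length = len_v, parent_alleles = pa_v, child_alleles = ca_v,
             stringsAsFactors = FALSE)
}

# half-open interval overlap
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Associate MNMs with IR footprints on the same terminal branch
#'
#' An MNM is arm-associated with an IR when at least one of its columns
#' intersects either arm interval, and spacer-associated when it intersects
#' the spacer; both labels are possible. Association requires the IR's
#' strain to equal the MNM's taxon (terminal-branch mapping).
#'
#' @param irs IR data.frame carrying alignment-column coordinates
#'   (`col_left_start`, `col_spacer_start`, `col_spacer_end`,
#'   `col_right_end`), e.g. from [ir_alignment_columns()].
#' @param mnms Data.frame from [call_mnms()].
#' @return `irs` with added columns `arm_mnms` and `spacer_mnms` (counts),
#'   plus attribute `pairs`: a data.frame of (ir_row, mnm_row, on_arm,
#'   on_spacer) for every associated pair.
#' @export
associate_mnms <- function(irs, mnms) {
  irs$arm_mnms <- 0L
  irs$spacer_mnms <- 0L
  pairs <- list()
  if (nrow(irs) > 0L && nrow(mnms) > 0L) {
    by_taxon <- split(seq_len(nrow(mnms)), mnms$taxon)
    for (i in seq_len(nrow(irs))) {
      m <- by_taxon[[irs$seq_id[i]]]
      if (is.null(m)) next
      on_left <- .overlaps(mnms$start_col[m], mnms$end_col[m],
                           irs$col_left_start[i], irs$col_spacer_start[i])
      on_right <- .overlaps(mnms$start_col[m], mnms$end_col[m],
                            irs$col_spacer_end[i], irs$col_right_end[i])
      on_spacer <- .overlaps(mnms$start_col[m], mnms$end_col[m],
                             irs$col_spacer_start[i], irs$col_spacer_end[i])
      on_arm <- on_left | on_right
      irs$arm_mnms[i] <- sum(on_arm)
      irs$spacer_mnms[i] <- sum(on_spacer)
      sel <- on_arm | on_spacer
      if (any(sel)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          ir_row = i, mnm_row = m[sel],
          on_arm = on_arm[sel], on_spacer = on_spacer[sel])
      }
    }
  }
  attr(irs, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(ir_row = integer(), mnm_row = integer(),
               on_arm = logical(), on_spacer = logical())
  irs
}

# chunk an ungapped nucleotide string into complete triplets (integer codes)
.codon_units <- function(s) {
  v <- match(strsplit(s, "")[[1L]], c(.BASES, "N"))
  v <- v[seq_len(3L * (length(v) %/% 3L))]
  if (length(v) == 0L) return(matrix(integer(), 3L, 0L))
  matrix(v, nrow = 3L)
}

#' Alignment-quality and saturation filter for an IR/MNM association
#'
#' Applies the elimination rules for unreliable hits: (i) the focal strain's
#' terminal branch must not exceed `branch_len_cutoff` (mutation
#' saturation); (ii) the IR footprint may not contain indels between the
#' strain and its parent-node reconstruction; (iii) the IR region plus a
#' 50-bp tail is globally aligned (match 1, mismatch -1, gap 0) between the
#' focal strain and its sister taxon twice -- once per nucleotide and once
#' with codons as indivisible units scored per nucleotide -- and the hit is
#' rejected when the two scores differ by more than `score_diff_threshold`,
#' indicating a problematic codon MSA. An optional per-column confidence
#' vector (e.g. from an external alignment-confidence tool) is thresholded
#' at `confidence_cutoff` when provided.
#'
#' @param ir One row of an IR data.frame with alignment-column coordinates.
#' @param alignment The codon alignment.
#' @param tree Rooted `phylo` tree.
#' @param ancestors Ancestral reconstruction (as in [call_mnms()]).
#' @param score_diff_threshold Maximum tolerated |nt - codon| score
#'   difference (default 15).
#' @param branch_len_cutoff Terminal branch-length cutoff (default 0.2,
#'   expected substitutions per codon site).
#' @param tail_bp Tail appended 3' of the IR footprint (default 50).
#' @param patristic Optional precomputed leaf-leaf distance matrix
#'   (`ape::cophenetic.phylo(tree)`), for repeated calls.
#' @param column_confidence Optional numeric vector of per-column
#'   confidences in `[0, 1]`.
#' @param confidence_cutoff Threshold for `column_confidence` (default 0.95).
#' @return List: `keep` (logical), `reason` (`NA` or one of
#'   `branch_length`, `indel`, `no_sister`, `msa_quality`,
#'   `alignment_confidence`), `nt_score`, `codon_score`.
#' @export
qc_filter <- function(ir, alignment, tree, ancestors,
                      score_diff_threshold = 15, branch_len_cutoff = 0.2,
                      tail_bp = 50L, patristic = NULL,
                      column_confidence = NULL, confidence_cutoff = 0.95) {
  taxon <- ir$seq_id
  reject <- function(reason, nt = NA_real_, cod = NA_real_) {
    list(keep = FALSE, reason = reason, nt_score = nt, codon_score = cod)
  }
  ntip <- length(tree$tip.label)
  tipno <- match(taxon, tree$tip.label)
  edge_row <- which(tree$edge[, 2L] == tipno)
  if (tree$edge.length[edge_row] > branch_len_cutoff) {
    return(reject("branch_length"))
  }
  fp <- ir$col_left_start:(ir$col_right_end - 1L) + 1L  # 1-based columns
  if (!is.null(column_confidence) &&
      any(column_confidence[fp] < confidence_cutoff)) {
    return(reject("alignment_confidence"))
  }
  states <- if (is.list(ancestors)) ancestors$states else ancestors
  parent_no <- tree$edge[edge_row, 1L]
  labs <- tree$node.label
  plab <- if (!is.null(labs) && all(labs != "") && !anyDuplicated(labs)) {
    labs[parent_no - ntip]
  } else paste0("Node", parent_no)
  child_fp <- substring(alignment[[taxon]], min(fp), max(fp))
  parent_fp <- substring(states[[plab]], min(fp), max(fp))
  if (grepl("-", child_fp, fixed = TRUE) || grepl("-", parent_fp, fixed = TRUE)) {
    return(reject("indel"))
  }
  if (ntip < 2L) return(reject("no_sister"))
  if (is.null(patristic)) patristic <- ape::cophenetic.phylo(tree)
  others <- setdiff(tree$tip.label, taxon)
  sister <- others[which.min(patristic[taxon, others])]
  # region: codon-anchored IR footprint + 3' tail, clipped to the gene
  L <- nchar(alignment[[taxon]])
  from <- (ir$col_left_start %/% 3L) * 3L
  to <- min(L, ((ir$col_right_end + tail_bp + 2L) %/% 3L) * 3L)
  a <- gsub("-", "", substring(alignment[[taxon]], from + 1L, to), fixed = TRUE)
  b <- gsub("-", "", substring(alignment[[sister]], from + 1L, to), fixed = TRUE)
  nt_score <- .nw_score_c(matrix(match(strsplit(a, "")[[1L]], c(.BASES, "N")), 1L),
                          matrix(match(strsplit(b, "")[[1L]], c(.BASES, "N")), 1L),
                          1, -1, 0)
  codon_score <- .nw_score_c(.codon_units(a), .codon_units(b), 1, -1, 0)
  if (abs(nt_score - codon_score) > score_diff_threshold) {
    return(reject("msa_quality", nt_score, codon_score))
  }
  list(keep = TRUE, reason = NA_character_,
       nt_score = nt_score, codon_score = codon_score)
}
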