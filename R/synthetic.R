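# Synthetic test universes: clock-free trees with an outgroup, codon
# alignments evolved under the M5 model, and template-switching events
# (arm-homogenization MNMs, spacer inversions) planted on terminal
# branches with a complete ground-truth ledger.

#' Invert the spacer of a perfect IR in a sequence
#'
#' Replaces the spacer by its reverse complement, leaving the arms
#' untouched -- the signature of intermolecular template switching. A
#' spacer that equals its own reverse complement is an error (the
#' inversion would be unobservable).
#'
#' @param seq Sequence string containing the IR.
#' @param ir List or one-row data.frame with `left_start` (0-based),
#'   `arm_len`, `spacer_len`.
#' @return The mutated sequence; attribute `changed_cols` gives the 0-based
#'   positions that differ.
#' @export
plant_spacer_inversion <- function(seq, ir) {
  seq <- toupper(seq)
  ls <- ir$left_start; a <- ir$arm_len; sp <- ir$spacer_len
  left <- substr0(seq, ls, ls + a)
  right <- substr0(seq, ls + a + sp, ls + a + sp + a)
  if (right != reverse_complement(left)) {
    stop("plant_spacer_inversion(): no perfect IR at the stated coordinates")
  }
  spacer <- substr0(seq, ls + a, ls + a + sp)
  rc <- reverse_complement(spacer)
  if (rc == spacer) {
    stop("plant_spacer_inversion(): spacer is its own reverse complement")
  }
  out <- paste0(substr0(seq, 0L, ls + a), rc,
                substr(seq, ls + a + sp + 1L, nchar(seq)))
  changed <- which(strsplit(spacer, "")[[1L]] != strsplit(rc, "")[[1L]]) - 1L
  structure(out, changed_cols = ls + a + changed)
}

#' Homogenize the arms of an imperfect IR
#'
#' Overwrites one arm with the reverse complement of the other, converting
#' an imperfect IR (arms differing at >= 2 contiguous positions) into a
#' perfect one -- the signature of template switching between the arms.
#'
#' @param seq Sequence string containing the imperfect IR.
#' @param ir_spec List with `left_start` (0-based), `arm_len`, `spacer_len`
#'   and optionally `which_arm` (`"right"`, the default, is overwritten).
#' @return The mutated sequence; attribute `changed_cols` gives the 0-based
#'   changed positions.
#' @export
plant_arm_homogenization <- function(seq, ir_spec) {
  seq <- toupper(seq)
  ls <- ir_spec$left_start; a <- ir_spec$arm_len; sp <- ir_spec$spacer_len
  which_arm <- ir_spec$which_arm %||% "right"
  left <- substr0(seq, ls, ls + a)
  right <- substr0(seq, ls + a + sp, ls + a + sp + a)
  if (which_arm == "right") {
    new_arm <- reverse_complement(left)
    old_arm <- right
    arm_start <- ls + a + sp
  } else {
    new_arm <- reverse_complement(right)
    old_arm <- left
    arm_start <- ls
  }
  d <- which(strsplit(old_arm, "")[[1L]] != strsplit(new_arm, "")[[1L]])
  if (length(d) < 2L) {
    stop("plant_arm_homogenization(): arms differ at fewer than 2 positions ",
         "(nothing callable as an MNM to homogenize)")
  }
  if (length(d) >= 2L && !any(diff(d) == 1L)) {
    stop("plant_arm_homogenization(): arm differences are not contiguous")
  }
  out <- paste0(substr0(seq, 0L, arm_start), new_arm,
                substr(seq, arm_start + a + 1L, nchar(seq)))
  structure(out, changed_cols = arm_start + d - 1L)
}

# splice `piece` into `seq` at 0-based position `pos`
.splice <- function(seq, pos, piece) {
  paste0(substr0(seq, 0L, pos), piece,
         substr(seq, pos + nchar(piece) + 1L, nchar(seq)))
}

# does any in-frame codon overlapping 0-based columns [from, to) become a
# stop after splicing `piece` at `pos` into `seq`?
.introduces_stop <- function(seq, pos, piece) {
  new <- .splice(seq, pos, piece)
  c0 <- (pos %/% 3L) * 3L
  c1 <- min(nchar(new), (((pos + nchar(piece)) + 2L) %/% 3L) * 3L)
  grepl("\\*", translate_dna(substr0(new, c0, c1)))
}

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# Construct a plantable IR event at a random position of a gene: returns
# NULL on failure, else a list with pos, parent_piece, child_piece,
# changed columns etc. Both variants are checked against every row (and
# ancestor) for introduced stop codons, and one fixed non-pairing flank
# base on each side blocks outward arm extension so the planted IR is
# maximal at exactly arm_len in every row.
.design_event <- function(rows, kind, arm_len, spacer_len, mismatch_run,
                          tries = 50L) {
  L <- nchar(rows[[1L]])
  fp <- 2L * arm_len + spacer_len
  if (L < fp + 8L) return(NULL)
  for (i in seq_len(tries)) {
    pos <- sample.int(L - fp - 5L, 1L) + 2L   # 0-based, leaves flank room
    arm <- .random_seq(arm_len)
    spacer <- .random_seq(spacer_len)
    perfect <- paste0("A", arm, spacer, reverse_complement(arm), "A")
    # flank 'A' on both sides: A cannot pair with A, blocking outward growth
    hits <- find_perfect_irs(perfect, min_arm = 2L,
                             max_spacer = max(spacer_len, 2L))
    target <- hits$arm_len == arm_len & hits$left_start == 1L &
      hits$spacer_len == spacer_len
    if (!any(target) || max(hits$arm_len) > arm_len) next
    if (kind == "spacer_inversion") {
      if (spacer_len == 0L) return(NULL)
      rc <- reverse_complement(spacer)
      if (rc == spacer) next
      # the inversion must be callable as an MNM: require a run of >= 2
      # contiguous differences between spacer and inverted spacer
      dd <- which(strsplit(spacer, "")[[1L]] != strsplit(rc, "")[[1L]])
      if (length(dd) < 2L || !any(diff(dd) == 1L)) next
      child <- paste0("A", arm, rc, reverse_complement(arm), "A")
      # the inverted form must carry the same maximal IR
      h2 <- find_perfect_irs(child, min_arm = 2L,
                             max_spacer = max(spacer_len, 2L))
      if (!any(h2$arm_len == arm_len & h2$left_start == 1L)) next
      parent <- perfect
      changed <- which(strsplit(spacer, "")[[1L]] != strsplit(rc, "")[[1L]])
      changed_cols <- (pos - 1L) + 1L + arm_len + changed - 1L
    } else {
      k <- mismatch_run
      if (k < 2L || k > arm_len) return(NULL)
      run_at <- sample.int(arm_len - k + 1L, 1L)
      right <- strsplit(reverse_complement(arm), "")[[1L]]
      orig <- right[run_at:(run_at + k - 1L)]
      mut <- vapply(orig, function(b) sample(setdiff(.BASES, b), 1L), "")
      right[run_at:(run_at + k - 1L)] <- mut
      parent <- paste0("A", arm, spacer, paste(right, collapse = ""), "A")
      child <- perfect
      changed_cols <- (pos - 1L) + 1L + arm_len + spacer_len +
        run_at:(run_at + k - 1L) - 1L
    }
    splice_pos <- pos - 1L                     # include left flank base
    if (any(vapply(rows, .introduces_stop, TRUE, pos = splice_pos,
                   piece = parent)) ||
        any(vapply(rows, .introduces_stop, TRUE, pos = splice_pos,
                   piece = child))) next
    return(list(pos = pos, splice_pos = splice_pos,
                parent_piece = parent, child_piece = child,
                left_start = pos, arm_len = arm_len,
                spacer_len = spacer_len, changed_cols = changed_cols))
  }
  NULL
}

#' Generate a synthetic study universe with planted events
#'
#' Simulates a clock-free rooted tree of `n_taxa` ingroup strains plus one
#' outgroup, evolves gap-free in-frame codon alignments along it under the
#' M5 model, and optionally plants template-switching events on terminal
#' branches. Events are planted post hoc: the ancestral (parent) form of
#' the IR region is written into every row and every true ancestral
#' sequence, and the derived form only into the chosen leaf, so the event
#' maps exactly to that terminal branch. A ground-truth ledger records
#' every planted change.
#'
#' @param n_genes Number of genes.
#' @param n_taxa Number of ingroup strains.
#' @param gene_length_codons Gene length (codons; default 200).
#' @param params A [codon_model_params()]; default kappa 3, omega ~
#'   Gamma(0.6, 3) (mean 0.2), uniform codon frequencies.
#' @param event_spec `NULL` (no events) or a list of event descriptions,
#'   each a list with `kind` (`"arm_homogenization"` or
#'   `"spacer_inversion"`), `rate` (per-gene planting probability),
#'   `arm_len`, `spacer_len`, `mismatch_run` (homogenization), `n_leaves`
#'   (inversion recurrences, default 1) and `max_branch` (only leaves with
#'   terminal branch length below this receive events; default `Inf`).
#' @param seed Optional master seed; per-gene seeds are drawn from it and
#'   recorded in the truth ledger.
#' @param mean_terminal Target mean terminal branch length of the ingroup
#'   (expected substitutions per codon site; default 0.06).
#' @param branch_noise_sd Log-normal rate-variation sd applied per branch
#'   to break the clock (default 0.3).
#' @param outgroup_branch,root_stem Branch lengths attaching the outgroup
#'   and the ingroup root (defaults 0.35 and 0.05).
#' @param outgroup_label Outgroup tip name (default `"outgroup"`).
#' @return List of class `ir_universe`: `tree`, `alignments` (named list
#'   of [codon_alignment()]), `outgroup`, and `truth` with `events`
#'   (data.frame ledger), `ancestors` (true internal-node sequences per
#'   gene), `params`, `gene_seeds`, `skipped`.
#' @export
generate_universe <- function(n_genes, n_taxa, gene_length_codons = 200L,
                              params = NULL, event_spec = NULL, seed = NULL,
                              mean_terminal = 0.06, branch_noise_sd = 0.3,
                              outgroup_branch = 0.35, root_stem = 0.05,
                              outgroup_label = "outgroup") {
  if (!is.null(seed)) set.seed(seed)
  params <- params %||% codon_model_params(kappa = 3, omega_shape = 0.6,
                                           omega_rate = 3, n_categories = 8L,
                                           codon_freqs = rep(1 / 61, 61L))
  if (!is.null(event_spec)) {
    stopifnot(all(vapply(event_spec, function(e)
      e$rate >= 0 && e$rate <= 1, TRUE)))
  }
  ing <- ape::rphylo(n_taxa, birth = 1, death = 0)
  ing$tip.label <- sprintf("strain%02d", seq_len(n_taxa))
  term <- ing$edge[, 2L] <= n_taxa
  ing$edge.length <- ing$edge.length * mean_terminal /
    mean(ing$edge.length[term])
  ing$edge.length <- ing$edge.length *
    exp(rnorm(length(ing$edge.length), -branch_noise_sd^2 / 2, branch_noise_sd))
  inner <- sub(";\\s*$", "", ape::write.tree(ing))
  tree <- ape::read.tree(text = sprintf("(%s:%.8f,%s:%.8f);", inner,
                                        root_stem, outgroup_label,
                                        outgroup_branch))
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)
  genes <- setNames(vector("list", n_genes),
                    sprintf("gene%03d", seq_len(n_genes)))
  ancestors <- setNames(vector("list", n_genes), names(genes))
  events <- list()
  skipped <- list()
  ntip <- length(tree$tip.label)
  term_len <- setNames(numeric(ntip), tree$tip.label)
  term_edges <- tree$edge[, 2L] <= ntip
  term_len[tree$tip.label[tree$edge[term_edges, 2L]]] <-
    tree$edge.length[term_edges]
  for (g in seq_len(n_genes)) {
    set.seed(gene_seeds[g])
    sim <- simulate_alignment(tree, params, n_codons = gene_length_codons,
                              return_ancestors = TRUE)
    aln <- unclass(sim$alignment)
    anc <- sim$ancestors
    gene <- names(genes)[g]
    for (spec in event_spec %||% list()) {
      if (runif(1L) > spec$rate) next
      eligible <- setdiff(names(aln), outgroup_label)
      eligible <- eligible[term_len[eligible] <= (spec$max_branch %||% Inf)]
      n_leaves <- spec$n_leaves %||% 1L
      if (length(eligible) < n_leaves) {
        skipped[[length(skipped) + 1L]] <-
          list(gene = gene, kind = spec$kind, reason = "no eligible leaf")
        next
      }
      des <- .design_event(c(aln, anc), spec$kind, spec$arm_len,
                           spec$spacer_len, spec$mismatch_run %||% 3L)
      if (is.null(des)) {
        skipped[[length(skipped) + 1L]] <-
          list(gene = gene, kind = spec$kind, reason = "no placement found")
        next
      }
      leaves <- eligible[sample.int(length(eligible), n_leaves)]
      for (id in names(aln)) aln[[id]] <- .splice(aln[[id]], des$splice_pos,
                                                  des$parent_piece)
      for (id in names(anc)) anc[[id]] <- .splice(anc[[id]], des$splice_pos,
                                                  des$parent_piece)
      for (id in leaves) aln[[id]] <- .splice(aln[[id]], des$splice_pos,
                                              des$child_piece)
      for (id in leaves) {
        events[[length(events) + 1L]] <- data.frame(
          gene = gene, kind = spec$kind, taxon = id,
          left_start = des$left_start, arm_len = des$arm_len,
          spacer_len = des$spacer_len,
          mut_start = min(des$changed_cols),
          mut_end = max(des$changed_cols) + 1L,
          n_changed = length(des$changed_cols),
          parent_region = substr0(des$parent_piece, 1L,
                                  1L + 2L * des$arm_len + des$spacer_len),
          child_region = substr0(des$child_piece, 1L,
                                 1L + 2L * des$arm_len + des$spacer_len),
          stringsAsFactors = FALSE)
      }
    }
    genes[[g]] <- codon_alignment(aln)
    ancestors[[g]] <- anc
  }
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(gene = character(), kind = character(), taxon = character(),
               left_start = integer(), arm_len = integer(),
               spacer_len = integer(), mut_start = integer(),
               mut_end = integer(), n_changed = integer(),
               parent_region = character(), child_region = character())
  structure(list(tree = tree, alignments = genes,
                 outgroup = outgroup_label,
                 truth = list(events = events_df, ancestors = ancestors,
                              params = params, gene_seeds = gene_seeds,
                              skipped = skipped)),
            class = "ir_universe")
}

#' @export
print.ir_universe <- function(x, ...) {
  cat(sprintf(paste0("synthetic universe: %d genes x %d taxa (+%s), ",
                     "%d planted events\n"),
              length(x$alignments), length(x$tree$tip.label) - 1L,
              x$outgroup, nrow(x$truth$events)))
  invisible(x)
}
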