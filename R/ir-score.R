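# Matched IR-less control regions, the pseudo-counted IR score, and its
# empirical significance against the simulated null set.

#' Match an IR-less control region to each IR
#'
#' For every IR a control interval of length `arm_len` is placed in the
#' nearest stretch of the same strain's row that intersects no detected IR
#' footprint and contains no gaps (ties broken toward the 5' side). IRs
#' with identical footprints shared by several strains receive the same
#' control position in every sharing strain (the window must qualify in all
#' of them), so the number of IRs and controls is always equal -- except
#' when no qualifying window exists, in which case the control is marked
#' missing and the IR is excluded from scoring by the caller.
#'
#' @param irs IR data.frame with alignment-column coordinates (the bin
#'   being scored).
#' @param alignment The codon alignment (named character vector).
#' @param all_irs Data.frame of all detected IRs (every bin) with
#'   alignment-column coordinates, defining the forbidden footprints.
#' @return Data.frame parallel to `irs`: `seq_id`, `control_start`,
#'   `control_end` (0-based half-open columns), `distance`, `missing`.
#' @export
match_controls <- function(irs, alignment, all_irs) {
  L <- nchar(alignment[[1L]])
  forbidden <- list()
  for (id in unique(irs$seq_id)) {
    f <- logical(L)
    own <- which(all_irs$seq_id == id)
    for (r in own) {
      f[(all_irs$col_left_start[r] + 1L):all_irs$col_right_end[r]] <- TRUE
    }
    if (grepl("-", alignment[[id]], fixed = TRUE)) {
      f[strsplit(alignment[[id]], "")[[1L]] == "-"] <- TRUE
    }
    forbidden[[id]] <- f
  }
  n <- nrow(irs)
  out <- data.frame(seq_id = if (n) irs$seq_id else character(),
                    control_start = rep(NA_integer_, n),
                    control_end = rep(NA_integer_, n),
                    distance = rep(NA_integer_, n),
                    missing = rep(TRUE, n))
  if (n == 0L) return(out)
  cs_strain <- lapply(forbidden, function(f) c(0L, cumsum(f)))
  key <- paste(irs$col_left_start, irs$col_right_end, irs$arm_len)
  for (grp in split(seq_len(nrow(irs)), key)) {
    wlen <- irs$arm_len[grp[1L]]
    s_ir <- irs$col_left_start[grp[1L]]
    e_ir <- irs$col_right_end[grp[1L]]
    ids <- unique(irs$seq_id[grp])
    if (L < wlen) next
    cs <- if (length(ids) == 1L) cs_strain[[ids]] else {
      f <- forbidden[[ids[1L]]]
      for (id in ids[-1L]) f <- f | forbidden[[id]]
      c(0L, cumsum(f))
    }
    free <- function(w) w >= 0L && w + wlen <= L &&
      cs[w + wlen + 1L] == cs[w + 1L]
    # scan outward from the IR footprint; at equal distance prefer 5'
    best <- NA_integer_; bestd <- NA_integer_
    for (d in 0:L) {
      wl <- s_ir - wlen - d
      if (free(wl)) { best <- wl; bestd <- d; break }
      wr <- e_ir + d
      if (free(wr)) { best <- wr; bestd <- d; break }
      if (wl < 0L && wr + wlen > L) break
    }
    if (is.na(best)) next
    out$control_start[grp] <- best
    out$control_end[grp] <- best + wlen
    out$distance[grp] <- bestd
    out$missing[grp] <- FALSE
  }
  out
}

#' The IR score
#'
#' Ratio of MNM-bearing to MNM-free IR counts, normalized by the same ratio
#' in the matched IR-less controls; a pseudo-count of 1 is added to every
#' element to prevent division by zero:
#' `score = ((a+1)/(b+1)) / ((c+1)/(d+1))` for `a` IRs with MNMs, `b` IRs
#' without, `c` controls with MNMs, `d` controls without.
#'
#' @param irs_with_mnm,irs_without,controls_with_mnm,controls_without
#'   Non-negative counts.
#' @return The score (positive scalar).
#' @examples
#' compute_ir_score(0, 0, 0, 0)  # 1
#' compute_ir_score(1, 0, 0, 1)  # 4
#' @export
compute_ir_score <- function(irs_with_mnm, irs_without,
                             controls_with_mnm, controls_without) {
  counts <- c(irs_with_mnm, irs_without, controls_with_mnm, controls_without)
  if (any(counts < 0)) stop("compute_ir_score(): negative count")
  ((irs_with_mnm + 1) / (irs_without + 1)) /
    ((controls_with_mnm + 1) / (controls_without + 1))
}

#' Empirical significance of a real IR score against its null
#'
#' Upper-tail add-one empirical p-value with ties counted as exceeding:
#' `p = (#\{null >= real\} + 1) / (n_null + 1)`; the gene is significant
#' when `p <= alpha`.
#'
#' @param real_score The real gene's IR score.
#' @param null_scores Vector of replicate scores (typically 100).
#' @param alpha Significance level (default 0.05).
#' @return List: `empirical_p`, `significant`.
#' @export
empirical_significance <- function(real_score, null_scores, alpha = 0.05) {
  if (length(null_scores) == 0L) stop("empirical_significance(): empty null")
  p <- (sum(null_scores >= real_score) + 1) / (length(null_scores) + 1)
  list(empirical_p = p, significant = p <= alpha)
}

# Per-gene, per-bin analysis used for both the real alignment and every
# null replicate: IR detection and binning, MNM association, QC, control
# matching, and the four IR-score counts.
.gene_bin_counts <- function(alignment, tree, ancestors, bin, outgroup,
                             min_arm = 7L, max_spacer = 70L,
                             apply_qc = TRUE, score_diff_threshold = 15,
                             branch_len_cutoff = 0.2, patristic = NULL,
                             mnms = NULL, ir_scan = NULL) {
  strains <- setdiff(names(alignment), outgroup)
  gapless <- !any(grepl("-", alignment[strains], fixed = TRUE))
  if (gapless) {
    # gap-free fast path on raw scan matrices (columns = positions)
    if (is.null(ir_scan)) {
      ir_scan <- .scan_strains(alignment[strains], min_arm, max_spacer)
    }
    nper <- vapply(ir_scan, nrow, 0L)
    m <- do.call(rbind, ir_scan)
    all_irs <- data.frame(
      seq_id = rep(strains, nper),
      left_start = m[, 1L], arm_len = m[, 2L], spacer_len = m[, 3L],
      right_end = m[, 1L] + 2L * m[, 2L] + m[, 3L],
      stringsAsFactors = FALSE)
    all_irs$col_left_start <- all_irs$left_start
    all_irs$col_spacer_start <- all_irs$left_start + all_irs$arm_len
    all_irs$col_spacer_end <- all_irs$col_spacer_start + all_irs$spacer_len
    all_irs$col_right_end <- all_irs$right_end
  } else {
    per_strain <- lapply(strains, function(id) {
      ir_alignment_columns(
        find_perfect_irs(alignment[[id]], min_arm, max_spacer, seq_id = id),
        alignment[[id]])
    })
    all_irs <- do.call(rbind, per_strain)
  }
  bin_list <- bin_and_deduplicate(all_irs[all_irs$arm_len == bin, , drop = FALSE])
  bin_irs <- bin_list[[as.character(bin)]]
  if (is.null(bin_irs)) bin_irs <- all_irs[0L, , drop = FALSE]
  if (is.null(mnms)) mnms <- call_mnms(alignment, tree, ancestors,
                                       exclude = outgroup)
  bin_irs <- associate_mnms(bin_irs, mnms)
  qc <- NULL
  if (apply_qc && nrow(bin_irs) > 0L) {
    hit <- which(bin_irs$arm_mnms > 0L | bin_irs$spacer_mnms > 0L)
    if (length(hit) > 0L && is.null(patristic)) {
      patristic <- ape::cophenetic.phylo(tree)
    }
    drop <- logical(nrow(bin_irs))
    qc <- vector("list", nrow(bin_irs))
    for (i in hit) {
      v <- qc_filter(bin_irs[i, , drop = FALSE], alignment, tree, ancestors,
                     score_diff_threshold = score_diff_threshold,
                     branch_len_cutoff = branch_len_cutoff,
                     patristic = patristic)
      qc[[i]] <- v
      drop[i] <- !v$keep
    }
    bin_irs <- bin_irs[!drop, , drop = FALSE]
    qc <- qc[!drop]
  }
  controls <- match_controls(bin_irs, alignment, all_irs)
  ok <- !controls$missing
  bin_irs <- bin_irs[ok, , drop = FALSE]
  controls <- controls[ok, , drop = FALSE]
  ctrl_mnm <- logical(nrow(controls))
  if (nrow(controls) > 0L && nrow(mnms) > 0L) {
    for (i in seq_len(nrow(controls))) {
      m <- mnms$taxon == controls$seq_id[i]
      ctrl_mnm[i] <- any(.overlaps(mnms$start_col[m], mnms$end_col[m],
                                   controls$control_start[i],
                                   controls$control_end[i]))
    }
  }
  a <- sum(bin_irs$arm_mnms > 0L)
  b <- nrow(bin_irs) - a
  cc <- sum(ctrl_mnm)
  d <- nrow(controls) - cc
  list(counts = c(a = a, b = b, c = cc, d = d),
       score = compute_ir_score(a, b, cc, d),
       irs = bin_irs, controls = controls, mnms = mnms, qc = qc)
}

#' Simulation-based IR-score significance test for one gene and arm bin
#'
#' Computes the real gene's IR score for one arm-length bin, builds (or
#' reuses) the conditional null set of simulated alignments, repeats the
#' identical analysis on every replicate (null replicates are scored
#' against their own true simulated ancestral sequences), and reports the
#' empirical significance.
#'
#' @param alignment The real [codon_alignment()] (including outgroup).
#' @param tree Rooted `phylo` tree over the alignment taxa.
#' @param params A [codon_model_params()] (used for reconstruction when
#'   `ancestors` is missing, and for the null simulations).
#' @param arm_len_bin Arm-length bin to test.
#' @param outgroup Outgroup tip label.
#' @param config A [run_config()] (thresholds and null settings).
#' @param ancestors Optional precomputed [reconstruct_ancestors()] result.
#' @param null Optional precomputed [build_null_set()] result.
#' @param seed Optional integer seed for the null simulations.
#' @return List of class `ir_score_result`: `bin`, `counts`, `score`,
#'   `null_scores`, `empirical_p`, `significant`, `real` (full per-gene
#'   detail), `null` (the null set, counts only).
#' @export
ir_score_test <- function(alignment, tree, params, arm_len_bin, outgroup,
                          config = run_config(), ancestors = NULL,
                          null = NULL, seed = NULL) {
  if (is.null(ancestors)) {
    ancestors <- reconstruct_ancestors(tree, alignment, params)
  }
  patristic <- ape::cophenetic.phylo(tree)
  real <- .gene_bin_counts(alignment, tree, ancestors, arm_len_bin, outgroup,
                           min_arm = config$min_arm,
                           max_spacer = config$max_spacer,
                           apply_qc = TRUE,
                           score_diff_threshold = config$score_diff_threshold,
                           branch_len_cutoff = config$branch_len_cutoff,
                           patristic = patristic)
  if (is.null(null)) {
    null <- build_null_set(alignment, tree, params, arm_len_bin, outgroup,
                           n_null = config$n_null,
                           length_factor = config$length_factor,
                           max_spacer = config$max_spacer, seed = seed,
                           min_arm_scan = config$min_arm)
  }
  null_scores <- vapply(null$replicates, function(rep) {
    .gene_bin_counts(rep$alignment, tree, rep$ancestors, arm_len_bin,
                     outgroup, min_arm = config$min_arm,
                     max_spacer = config$max_spacer, apply_qc = TRUE,
                     score_diff_threshold = config$score_diff_threshold,
                     branch_len_cutoff = config$branch_len_cutoff,
                     patristic = patristic, ir_scan = rep$ir_scan)$score
  }, 0)
  sig <- empirical_significance(real$score, null_scores, config$alpha)
  structure(list(bin = arm_len_bin, counts = real$counts, score = real$score,
                 null_scores = null_scores,
                 empirical_p = sig$empirical_p,
                 significant = sig$significant,
                 real = real,
                 null_ir_counts = null$ir_counts,
                 real_ir_count = null$real_count),
            class = "ir_score_result")
}

#' @export
print.ir_score_result <- function(x, ...) {
  cat(sprintf(paste0("IR score test (arm bin %d): score %.3f ",
                     "(a=%d b=%d c=%d d=%d), empirical p = %.4f%s\n"),
              x$bin, x$score, x$counts["a"], x$counts["b"], x$counts["c"],
              x$counts["d"], x$empirical_p,
              if (x$significant) " *" else ""))
  invisible(x)
}
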