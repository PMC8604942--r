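# End-to-end orchestration: prefilter -> IR detection -> model fit ->
# ancestral reconstruction -> MNM calling -> QC -> controls -> null set ->
# IR score -> inversion classification -> protein effects.

#' Pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' IR arms of at least 7 bp with spacers up to 70 bp, 100 null replicates
#' at significance level 0.05, codon-vs-nucleotide alignment score
#' difference cutoff 15, terminal branch-length (saturation) cutoff 0.2,
#' at most 20 Ns per sequence, at least 4 strains per ortholog set,
#' simulated root length 4.5 times the outgroup length, and a Grantham
#' high-distance threshold of 120.
#'
#' @param min_arm,max_spacer IR detection thresholds (bp).
#' @param n_null Null replicates per gene and bin.
#' @param alpha Empirical significance level.
#' @param score_diff_threshold QC codon-vs-nucleotide score cutoff.
#' @param branch_len_cutoff Terminal branch-length cutoff.
#' @param max_n Maximum Ns per sequence.
#' @param min_strains Minimum strains per ortholog set.
#' @param length_factor Simulated root length multiplier (in `[4, 5]`).
#' @param grantham_threshold High Grantham-distance flag threshold.
#' @param n_categories Omega discretization categories.
#' @param seed Master seed; per-gene seeds are fanned out from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(min_arm = 7L, max_spacer = 70L, n_null = 100L,
                       alpha = 0.05, score_diff_threshold = 15,
                       branch_len_cutoff = 0.2, max_n = 20L,
                       min_strains = 4L, length_factor = 4.5,
                       grantham_threshold = 120L, n_categories = 8L,
                       seed = NULL) {
  cfg <- list(min_arm = as.integer(min_arm),
              max_spacer = as.integer(max_spacer),
              n_null = as.integer(n_null), alpha = alpha,
              score_diff_threshold = score_diff_threshold,
              branch_len_cutoff = branch_len_cutoff,
              max_n = as.integer(max_n),
              min_strains = as.integer(min_strains),
              length_factor = length_factor,
              grantham_threshold = as.integer(grantham_threshold),
              n_categories = as.integer(n_categories), seed = seed)
  stopifnot(cfg$min_arm >= 2L, cfg$max_spacer >= 0L, cfg$n_null >= 1L,
            cfg$alpha > 0, cfg$score_diff_threshold > 0,
            cfg$branch_len_cutoff > 0, cfg$length_factor >= 1)
  structure(cfg, class = "run_config")
}

# classify the template-switch events of one gene from its associations
.classify_gene_events <- function(gene, alignment, tree, ancestors, irs,
                                  mnms, config) {
  states <- if (is.list(ancestors)) ancestors$states else ancestors
  ntip <- length(tree$tip.label)
  parent_lab <- function(taxon) {
    tipno <- match(taxon, tree$tip.label)
    p <- tree$edge[tree$edge[, 2L] == tipno, 1L]
    labs <- tree$node.label
    if (!is.null(labs) && all(labs != "") && !anyDuplicated(labs)) {
      labs[p - ntip]
    } else paste0("Node", p)
  }
  out <- list()
  for (i in seq_len(nrow(irs))) {
    if (irs$arm_mnms[i] == 0L && irs$spacer_mnms[i] == 0L) next
    taxon <- irs$seq_id[i]
    fp0 <- irs$col_left_start[i]; fp1 <- irs$col_right_end[i]
    child <- substr0(alignment[[taxon]], fp0, fp1)
    parent <- substr0(states[[parent_lab(taxon)]], fp0, fp1)
    if (grepl("[^ACGT]", child) || grepl("[^ACGT]", parent)) next
    ev <- classify_event(parent, child,
                         list(left_start = 0L, arm_len = irs$arm_len[i],
                              spacer_len = irs$spacer_len[i]))
    if (is.null(ev)) next
    cons <- aa_consequences(states[[parent_lab(taxon)]], alignment[[taxon]],
                            event_columns = fp0:(fp1 - 1L),
                            grantham_threshold = config$grantham_threshold)
    reps <- cons$replacements
    tst <- ts_tv_tally(parent, child)
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, taxon = taxon, kind = ev$kind,
      col_left_start = fp0, col_right_end = fp1,
      arm_len = irs$arm_len[i], spacer_len = irs$spacer_len[i],
      n_substitutions = ev$n_substitutions,
      arm_diffs = ev$arm_diffs, spacer_diffs = ev$spacer_diffs,
      parent_arms_perfect = ev$parent_arms_perfect,
      child_spacer = ev$child_spacer,
      span_class = cons$span_class,
      synonymous_only = cons$synonymous_only,
      aa_changes = paste(sprintf("%s%d%s", reps$from_aa, reps$position,
                                 reps$to_aa)[!reps$synonymous],
                         collapse = ";"),
      max_grantham = if (nrow(reps) && any(!is.na(reps$grantham)))
        max(reps$grantham, na.rm = TRUE) else NA_integer_,
      transitions = tst$transitions, transversions = tst$transversions,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Run the full template-switch detection pipeline
#'
#' Per gene: prefilter, IR detection and binning, model fit (unless
#' parameters are supplied), marginal ancestral reconstruction, terminal
#' branch MNM calling, QC, control matching, conditional null simulation
#' and IR-score significance per arm-length bin, template-switch event
#' classification, and protein-level annotation. Failures are isolated per
#' gene and recorded. Deterministic under a fixed `config$seed`.
#'
#' @param genes Named list of [codon_alignment()] objects (or a directory
#'   of FASTA files, read with [read_codon_alignment()]).
#' @param tree Rooted `phylo` species tree covering all taxa (pruned per
#'   gene).
#' @param outgroup Outgroup tip label.
#' @param config A [run_config()].
#' @param params Optional [codon_model_params()] used for every gene; when
#'   `NULL`, parameters are fitted per gene.
#' @param bins Optional integer vector restricting the arm-length bins
#'   tested; default: every bin with at least one retained IR.
#' @return List of class `ir_pipeline_result`: `summary` (one row per gene
#'   x bin: counts, score, empirical p, verdict), `events` (classified
#'   template-switch events with protein effects), `genes` (per-gene
#'   detail), `config`.
#' @export
run_pipeline <- function(genes, tree, outgroup, config = run_config(),
                         params = NULL, bins = NULL) {
  if (is.character(genes) && length(genes) == 1L && dir.exists(genes)) {
    files <- list.files(genes, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    genes <- setNames(lapply(files, read_codon_alignment),
                      sub("\\.[^.]*$", "", basename(files)))
  }
  if (length(genes) == 0L) {
    warning("run_pipeline(): no genes to analyze")
    return(structure(list(summary = data.frame(), events = data.frame(),
                          genes = list(), config = config),
                     class = "ir_pipeline_result"))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, length(genes))
  summary_rows <- list()
  event_rows <- list()
  detail <- setNames(vector("list", length(genes)), names(genes))
  for (g in seq_along(genes)) {
    gene <- names(genes)[g]
    detail[[g]] <- tryCatch({
      aln <- prefilter_orthoset(unclass(genes[[g]]), max_n = config$max_n,
                                min_strains = config$min_strains,
                                outgroup = outgroup)
      if (length(aln) == 0L) {
        list(status = "rejected", reason = attr(aln, "reason"))
      } else {
        tr <- ape::keep.tip(tree, names(aln))
        par_g <- params %||% fit_parameters(tr, codon_alignment(aln),
                                            n_categories = config$n_categories)$params
        anc <- reconstruct_ancestors(tr, aln, par_g)
        mnms <- call_mnms(aln, tr, anc, exclude = outgroup)
        strains <- setdiff(names(aln), outgroup)
        all_irs <- do.call(rbind, lapply(strains, function(id) {
          ir_alignment_columns(
            find_perfect_irs(aln[[id]], config$min_arm, config$max_spacer,
                             seq_id = id), aln[[id]])
        }))
        gene_bins <- bins %||% sort(unique(all_irs$arm_len))
        res_bins <- list()
        for (b in gene_bins) {
          res <- ir_score_test(aln, tr, par_g, b, outgroup, config,
                               ancestors = anc, seed = gene_seeds[g] %% 2147483600L + b)
          res_bins[[as.character(b)]] <- res
          summary_rows[[length(summary_rows) + 1L]] <- data.frame(
            gene = gene, bin = b,
            irs_with_mnm = res$counts[["a"]], irs_without = res$counts[["b"]],
            controls_with_mnm = res$counts[["c"]],
            controls_without = res$counts[["d"]],
            score = res$score, empirical_p = res$empirical_p,
            significant = res$significant, stringsAsFactors = FALSE)
          ev <- .classify_gene_events(gene, aln, tr, anc, res$real$irs,
                                      mnms, config)
          if (!is.null(ev)) event_rows[[length(event_rows) + 1L]] <- ev
        }
        list(status = "ok", params = par_g, ancestors = anc, mnms = mnms,
             irs = all_irs, bins = res_bins)
      }
    }, error = function(e) list(status = "error", reason = conditionMessage(e)))
  }
  events <- if (length(event_rows)) {
    ev <- do.call(rbind, event_rows)
    ev[!duplicated(ev[, c("gene", "taxon", "col_left_start", "kind")]), ]
  } else data.frame()
  structure(list(summary = if (length(summary_rows))
                   do.call(rbind, summary_rows) else data.frame(),
                 events = events, genes = detail, config = config),
            class = "ir_pipeline_result")
}

#' @export
print.ir_pipeline_result <- function(x, ...) {
  n_ok <- sum(vapply(x$genes, function(g) identical(g$status, "ok"), TRUE))
  cat(sprintf(paste0("template-switch pipeline: %d/%d genes analyzed, ",
                     "%d gene x bin tests (%d significant), %d events\n"),
              n_ok, length(x$genes), nrow(x$summary),
              if (nrow(x$summary)) sum(x$summary$significant) else 0L,
              nrow(x$events)))
  invisible(x)
}
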