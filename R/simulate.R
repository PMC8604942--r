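# Simulation of codon alignments along a rooted tree under the M5 model,
# and construction of the conditional 100-replicate null set used by the
# IR-score significance test.

# Precompute everything reusable across replicates of one gene: preorder
# edge list and per-edge, per-category cumulative transition probabilities.
.sim_prep <- function(tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  K <- model$K
  E <- nrow(edges)
  UT <- upper.tri(diag(61), diag = TRUE) * 1        # row-cumsum via BLAS
  cum_p <- numeric(E * K * 3721L)
  for (e in seq_len(E)) {
    for (k in seq_len(K)) {
      cp <- .pmat(model, k, elen[e]) %*% UT
      cp[, 61L] <- 1
      ofs <- ((e - 1L) * K + (k - 1L)) * 3721L
      cum_p[ofs + seq_len(3721L)] <- as.vector(t(cp))  # row-major per parent
    }
  }
  list(tree = tr, edges = edges, K = K, cum_p = cum_p,
       ntip = length(tr$tip.label),
       n_nodes = length(tr$tip.label) + tr$Nnode,
       root = length(tr$tip.label) + 1L)
}

# draw one replicate given prepared matrices (0-based states in, strings out)
.sim_draw <- function(prep, root_states, site_cat) {
  states <- .sim_states_c(prep$edges, prep$n_nodes, prep$cum_p, prep$K,
                          root_states, site_cat, prep$root)
  states + 1L
}

.states_to_seqs <- function(states, rows) {
  codons <- .codon_table()$codons
  vapply(rows, function(r) {
    paste(codons[states[r, ]], collapse = "")
  }, character(1L))
}

#' Simulate a codon alignment along a rooted tree
#'
#' Each site draws an omega category once (shared across the whole tree) and
#' then evolves from the root toward the tips by sampling codon states from
#' the per-branch transition probabilities of the M5 model. No indels are
#' generated. Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param tree Rooted `phylo` tree; branch lengths in expected substitutions
#'   per codon site.
#' @param params A [codon_model_params()]. When `codon_freqs` is `NULL`,
#'   uniform sense-codon frequencies are used.
#' @param root_sequence Optional gap-free in-frame root sequence (>= 1
#'   codon, no stops); when `NULL` the root is drawn i.i.d. from the
#'   stationary distribution and `n_codons` is required.
#' @param n_codons Root length in codons (ignored when `root_sequence` given).
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param return_ancestors Also return the true internal-node sequences.
#' @return A [codon_alignment()]; with `return_ancestors = TRUE`, a list
#'   with elements `alignment` and `ancestors` (named nucleotide strings).
#' @export
simulate_alignment <- function(tree, params, root_sequence = NULL,
                               n_codons = NULL, seed = NULL,
                               return_ancestors = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pi <- params$codon_freqs %||% rep(1 / 61, 61L)
  model <- .build_model(params, pi)
  prep <- .sim_prep(tree, model)
  if (!is.null(root_sequence)) {
    s <- toupper(root_sequence)
    if (nchar(s) < 3L) stop("simulate_alignment(): root shorter than 1 codon")
    if (nchar(s) %% 3L != 0L) stop("simulate_alignment(): root not in frame")
    nS <- nchar(s) %/% 3L
    root_idx <- .codon_index(substring(s, 3L * seq_len(nS) - 2L, 3L * seq_len(nS)))
    if (anyNA(root_idx)) stop("simulate_alignment(): root contains gap/N/stop codons")
  } else {
    if (is.null(n_codons) || n_codons < 1L) {
      stop("simulate_alignment(): give root_sequence or n_codons >= 1")
    }
    root_idx <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  }
  S <- length(root_idx)
  site_cat <- sample.int(model$K, S, replace = TRUE)
  states <- .sim_draw(prep, root_idx - 1L, site_cat - 1L)
  aln <- codon_alignment(setNames(.states_to_seqs(states, seq_len(prep$ntip)),
                                  prep$tree$tip.label))
  if (!return_ancestors) return(aln)
  labs <- prep$tree$node.label
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs)) {
    labs <- paste0("Node", (prep$ntip + 1L):prep$n_nodes)
  }
  anc <- setNames(.states_to_seqs(states, (prep$ntip + 1L):prep$n_nodes), labs)
  list(alignment = aln, ancestors = anc, site_categories = site_cat)
}

#' Build the conditional null set of simulated alignments
#'
#' Repeatedly simulates alignments along the tree (root drawn from the
#' stationary distribution, with length `length_factor` times the outgroup
#' sequence length) and keeps only replicates whose retained IR count in the
#' requested arm-length bin is at least the real alignment's count, until
#' `n_null` replicates are accepted. IR counts are distinct retained IR
#' footprints over the ingroup strains, after binning and overlap
#' deduplication: an IR locus conserved across strains counts once, so the
#' condition tracks how many comparable IRs the replicate offers rather
#' than multiplying a single conserved locus by the number of strains.
#'
#' @param real_alignment The real [codon_alignment()] (including outgroup).
#' @param tree Rooted `phylo` covering the alignment taxa.
#' @param params A [codon_model_params()] with frequencies set (or they are
#'   estimated F3x4 from the real alignment).
#' @param arm_len_bin Arm-length bin whose IR count is conditioned on.
#' @param outgroup Outgroup tip label (excluded from IR counting; its
#'   sequence length sets the simulated root length).
#' @param n_null Number of accepted replicates (default 100).
#' @param length_factor Root length multiplier, in `[4, 5]` (default 4.5).
#' @param max_spacer Spacer threshold for IR counting (default 70).
#' @param max_attempts Simulation budget before giving up (default
#'   `50 * n_null`); exhaustion is an error naming the bin, which happens
#'   when the requested arm length is too long to arise in simulation.
#' @param seed Optional integer seed.
#' @param root_from_outgroup Use the real (ungapped) outgroup sequence as
#'   the simulation root instead of drawing from the stationary
#'   distribution (default `FALSE`; the length factor is then ignored).
#' @return List of class `ir_null_set`: `replicates` (each with `alignment`
#'   and true `ancestors`), `ir_counts`, `real_count`, `bin`, `n_attempts`,
#'   `acceptance_rate`, `seed`.
#' @export
build_null_set <- function(real_alignment, tree, params, arm_len_bin,
                           outgroup, n_null = 100L, length_factor = 4.5,
                           max_spacer = 70L, max_attempts = 50L * n_null,
                           seed = NULL, root_from_outgroup = FALSE,
                           min_arm_scan = 7L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length_factor >= 1, outgroup %in% names(real_alignment))
  min_arm_scan <- min(min_arm_scan, arm_len_bin)
  strains <- setdiff(names(real_alignment), outgroup)
  real_ungapped <- vapply(real_alignment[strains],
                          function(s) gsub("-", "", s, fixed = TRUE),
                          character(1L))
  real_count <- .count_bin_irs(real_ungapped, arm_len_bin, max_spacer)
  pi <- params$codon_freqs %||% f3x4_frequencies(real_alignment)
  model <- .build_model(params, pi)
  prep <- .sim_prep(tree, model)
  og_len <- nchar(gsub("-", "", real_alignment[[outgroup]], fixed = TRUE))
  if (root_from_outgroup) {
    og <- gsub("-", "", real_alignment[[outgroup]], fixed = TRUE)
    nS <- nchar(og) %/% 3L
    root_idx0 <- .codon_index(substring(og, 3L * seq_len(nS) - 2L, 3L * seq_len(nS)))
    if (anyNA(root_idx0)) stop("outgroup sequence contains gap/N/stop codons")
    S <- nS
  } else {
    S <- max(1L, round(length_factor * og_len / 3))
  }
  labs <- prep$tree$node.label
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs)) {
    labs <- paste0("Node", (prep$ntip + 1L):prep$n_nodes)
  }
  tip_is_strain <- prep$tree$tip.label != outgroup
  reps <- vector("list", n_null)
  counts <- integer(n_null)
  kept <- 0L
  attempts <- 0L
  while (kept < n_null) {
    if (attempts >= max_attempts) {
      stop(sprintf(paste0("build_null_set(): could not obtain %d replicates ",
                          "with >= %d IRs in arm-length bin %d after %d ",
                          "simulations; no statistical evaluation possible ",
                          "for this bin"),
                   n_null, real_count, arm_len_bin, attempts))
    }
    attempts <- attempts + 1L
    root_idx <- if (root_from_outgroup) root_idx0 else {
      sample.int(61L, S, replace = TRUE, prob = pi)
    }
    site_cat <- sample.int(model$K, S, replace = TRUE)
    states <- .sim_draw(prep, root_idx - 1L, site_cat - 1L)
    leaf_seqs <- .states_to_seqs(states, seq_len(prep$ntip))
    names(leaf_seqs) <- prep$tree$tip.label
    scan <- .scan_strains(leaf_seqs[tip_is_strain], min_arm_scan, max_spacer)
    cnt <- .count_bin_from_scan(scan, arm_len_bin)
    if (cnt >= real_count) {
      kept <- kept + 1L
      anc <- setNames(.states_to_seqs(states, (prep$ntip + 1L):prep$n_nodes), labs)
      reps[[kept]] <- list(alignment = leaf_seqs, ancestors = anc,
                           ir_scan = scan)
      counts[kept] <- cnt
    }
  }
  structure(list(replicates = reps, ir_counts = counts,
                 real_count = real_count, bin = arm_len_bin,
                 n_attempts = attempts,
                 acceptance_rate = n_null / attempts,
                 tree = prep$tree, seed = seed),
            class = "ir_null_set")
}

#' @export
print.ir_null_set <- function(x, ...) {
  cat(sprintf(paste0("IR null set: %d replicates (bin %d, real count %d, ",
                     "%d attempts, acceptance %.2f)\n"),
              length(x$replicates), x$bin, x$real_count, x$n_attempts,
              x$acceptance_rate))
  invisible(x)
}
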