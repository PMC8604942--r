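test_that("spacer-inversion planting is an involution with correct diffs", {
  # the documented worked flips
  syg <- paste0("ATCCAGCTCC", "TACC", "GGAGCTGGAT")
  ir <- list(left_start = 0L, arm_len = 10L, spacer_len = 4L)
  flipped <- plant_spacer_inversion(syg, ir)
  expect_identical(as.character(substr(flipped, 11, 14)), "GGTA")
  expect_identical(as.character(plant_spacer_inversion(flipped, ir)), syg)
  expect_identical(attr(flipped, "changed_cols"), c(10L, 11L, 12L, 13L))
  spo <- "TGCCCGACGATAAATCGTCGGGCA"
  ir2 <- list(left_start = 0L, arm_len = 11L, spacer_len = 2L)
  expect_identical(as.character(substr(plant_spacer_inversion(spo, ir2), 12, 13)),
                   "TT")
  # self-reverse-complement spacer is unobservable
  pal <- paste0("GGATCCA", "AT", reverse_complement("GGATCCA"))
  expect_error(plant_spacer_inversion(pal, list(left_start = 0L, arm_len = 7L,
                                                spacer_len = 2L)),
               "reverse complement")
  expect_error(plant_spacer_inversion(chartr("G", "C", syg), ir), "no perfect IR")
})

test_that("arm homogenization perfects the IR and needs >= 2 mismatches", {
  set.seed(8)
  for (i in 1:20) {
    a <- sample(8:12, 1)
    arm <- random_dna(a)
    sp <- random_dna(4)
    right <- strsplit(reverse_complement(arm), "")[[1]]
    k <- sample(2:4, 1)
    at <- sample(seq_len(a - k + 1), 1)
    right[at:(at + k - 1)] <- vapply(right[at:(at + k - 1)],
      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    seq <- paste0(arm, sp, paste(right, collapse = ""))
    out <- plant_arm_homogenization(seq, list(left_start = 0L, arm_len = a,
                                              spacer_len = 4L))
    new_right <- as.character(substr(out, a + 5L, 2L * a + 4L))
    expect_identical(new_right, reverse_complement(arm))
    expect_equal(length(attr(out, "changed_cols")), k)
  }
  # an already-perfect IR has nothing to homogenize
  arm <- "GGATCCAGG"
  perfect <- paste0(arm, "ACCA", reverse_complement(arm))
  expect_error(plant_arm_homogenization(perfect,
                                        list(left_start = 0L, arm_len = 9L,
                                             spacer_len = 4L)),
               "fewer than 2")
})

test_that("an eleven-bp arm with a six-base contiguous difference homogenizes", {
  arm <- "TGCCCGACGAT"
  right <- strsplit(reverse_complement(arm), "")[[1]]
  right[3:8] <- c("T", "T", "C", "A", "A", "T")   # 6 contiguous mismatches
  stopifnot(sum(right != strsplit(reverse_complement(arm), "")[[1]]) == 6)
  seq <- paste0(arm, "AA", paste(right, collapse = ""))
  out <- plant_arm_homogenization(seq, list(left_start = 0L, arm_len = 11L,
                                            spacer_len = 2L))
  expect_equal(length(attr(out, "changed_cols")), 6L)
  expect_equal(find_perfect_irs(as.character(out), min_arm = 11)$arm_len, 11L)
})

test_that("universes are deterministic and ledger-complete", {
  spec <- list(list(kind = "spacer_inversion", rate = 0.5, arm_len = 9L,
                    spacer_len = 4L),
               list(kind = "arm_homogenization", rate = 0.5, arm_len = 10L,
                    spacer_len = 3L, mismatch_run = 3L))
  u1 <- generate_universe(n_genes = 6, n_taxa = 8, gene_length_codons = 120,
                          event_spec = spec, seed = 99)
  u2 <- generate_universe(n_genes = 6, n_taxa = 8, gene_length_codons = 120,
                          event_spec = spec, seed = 99)
  expect_identical(lapply(u1$alignments, unclass), lapply(u2$alignments, unclass))
  expect_identical(u1$truth$events, u2$truth$events)
  expect_identical(ape::write.tree(u1$tree), ape::write.tree(u2$tree))
  # no events: empty ledger
  u0 <- generate_universe(n_genes = 3, n_taxa = 6, gene_length_codons = 100,
                          seed = 1)
  expect_equal(nrow(u0$truth$events), 0L)
  # every planted event is re-derivable from the stored regions
  ev <- u1$truth$events
  for (r in seq_len(nrow(ev))) {
    aln <- u1$alignments[[ev$gene[r]]]
    child <- substr(aln[[ev$taxon[r]]], ev$left_start[r] + 1L,
                    ev$left_start[r] + 2L * ev$arm_len[r] + ev$spacer_len[r])
    expect_identical(child, ev$child_region[r])
    d <- which(strsplit(ev$parent_region[r], "")[[1]] !=
               strsplit(ev$child_region[r], "")[[1]])
    expect_equal(length(d), ev$n_changed[r])
    expect_true(all(diff(d) == 1L) || ev$kind[r] == "spacer_inversion")
    # planted IR is detectable at the stated arm length in the child
    irs <- find_perfect_irs(aln[[ev$taxon[r]]])
    hit <- irs[irs$left_start == ev$left_start[r], ]
    expect_equal(hit$arm_len, ev$arm_len[r])
    # the untouched rows carry the ancestral (parent) form
    others <- setdiff(names(aln), c(ev$taxon[ev$gene == ev$gene[r]], "outgroup"))
    expect_identical(substr(aln[[others[1]]], ev$left_start[r] + 1L,
                            ev$left_start[r] + 2L * ev$arm_len[r] + ev$spacer_len[r]),
                     ev$parent_region[r])
  }
})

test_that("planted terminal-branch MNMs are fully recovered with exact ancestors", {
  u <- generate_universe(
    n_genes = 10, n_taxa = 8, gene_length_codons = 120, seed = 2024,
    event_spec = list(list(kind = "arm_homogenization", rate = 1,
                           arm_len = 10L, spacer_len = 4L, mismatch_run = 3L,
                           max_branch = 0.2)))
  ev <- u$truth$events
  expect_gt(nrow(ev), 5L)
  hits <- vapply(seq_len(nrow(ev)), function(r) {
    aln <- u$alignments[[ev$gene[r]]]
    anc <- u$truth$ancestors[[ev$gene[r]]]
    mnms <- call_mnms(aln, u$tree, anc, exclude = "outgroup")
    m <- mnms[mnms$taxon == ev$taxon[r], , drop = FALSE]
    any(m$start_col < ev$mut_end & ev$mut_start < m$end_col)
  }, TRUE)
  expect_true(all(hits))
})
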