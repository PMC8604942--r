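mk_two_leaf <- function(child_A, child_B, parent) {
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  list(tree = tr, aln = c(A = child_A, B = child_B),
       anc = setNames(parent, "Node3"))
}

test_that("ortholog prefilter applies the N and strain-count rules", {
  seqs <- c(s1 = strrep("A", 60),
            s2 = paste0(strrep("N", 21), strrep("A", 39)),  # 21 Ns: dropped
            s3 = strrep("A", 60), s4 = strrep("A", 60), s5 = strrep("A", 60))
  kept <- prefilter_orthoset(seqs)
  expect_identical(names(kept), c("s1", "s3", "s4", "s5"))
  # exactly 20 Ns survives the threshold
  seqs["s2"] <- paste0(strrep("N", 20), strrep("A", 40))
  expect_equal(length(prefilter_orthoset(seqs)), 5L)
  # fewer than four strains: whole set rejected
  few <- prefilter_orthoset(seqs[1:3])
  expect_equal(length(few), 0L)
  expect_match(attr(few, "reason"), "fewer than 4")
  # the outgroup does not count toward the strain minimum
  withog <- prefilter_orthoset(c(seqs[1:3], og = strrep("A", 60)),
                               outgroup = "og")
  expect_equal(length(withog), 0L)
  expect_equal(length(prefilter_orthoset(seqs[1:5])), 5L)
})

test_that("MNMs are maximal runs of >= 2 contiguous substitutions", {
  base <- strrep("ACG", 20)
  # two adjacent substitutions at columns 10-11
  child <- base; substr(child, 11, 12) <- "AA"
  parent <- base; substr(parent, 11, 12) <- "TT"
  f <- mk_two_leaf(child, parent, parent)   # B matches the parent exactly
  m <- call_mnms(f$aln, f$tree, f$anc)
  expect_equal(nrow(m), 1L)
  expect_equal(m$taxon, "A")
  expect_equal(m$start_col, 10L)
  expect_equal(m$end_col, 12L)
  expect_equal(m$length, 2L)
  expect_identical(m$parent_alleles, "TT")
  expect_identical(m$child_alleles, "AA")
  # substitutions 2 bp apart are two singletons, not an MNM
  child2 <- base; substr(child2, 11, 11) <- "T"; substr(child2, 13, 13) <- "T"
  f2 <- mk_two_leaf(child2, base, base)
  expect_equal(nrow(call_mnms(f2$aln, f2$tree, f2$anc)), 0L)
  # neighboring substitutions on two different branches are not an MNM
  cA <- base; substr(cA, 11, 11) <- "T"
  cB <- base; substr(cB, 12, 12) <- "A"
  f3 <- mk_two_leaf(cA, cB, base)
  expect_equal(nrow(call_mnms(f3$aln, f3$tree, f3$anc)), 0L)
  # a gap column breaks a run
  child4 <- base; substr(child4, 11, 13) <- "AA-"
  parent4 <- base; substr(parent4, 11, 13) <- "TTG"
  f4 <- mk_two_leaf(child4, parent4, parent4)
  m4 <- call_mnms(f4$aln, f4$tree, f4$anc)
  expect_equal(m4$end_col - m4$start_col, 2L)
  # missing ancestor is an error
  expect_error(call_mnms(f$aln, f$tree, setNames("x", "other")), "no ancestral")
})

test_that("calling is independent of leaf order and excluded taxa are skipped", {
  base <- strrep("ACG", 20)
  child <- base; substr(child, 5, 6) <- "TT"
  f <- mk_two_leaf(child, base, base)
  m1 <- call_mnms(f$aln, f$tree, f$anc)
  m2 <- call_mnms(f$aln[c("B", "A")], f$tree, f$anc)
  expect_identical(m1, m2)
  expect_equal(nrow(call_mnms(f$aln, f$tree, f$anc, exclude = "A")), 0L)
})

test_that("association distinguishes arm, spacer and outside overlaps", {
  irs <- data.frame(seq_id = "A", left_start = 10L, arm_len = 8L,
                    spacer_len = 4L, right_end = 30L,
                    col_left_start = 10L, col_spacer_start = 18L,
                    col_spacer_end = 22L, col_right_end = 30L)
  mnms <- data.frame(taxon = c("A", "A", "A", "B"),
                     start_col = c(16L, 19L, 40L, 16L),
                     end_col = c(18L, 21L, 42L, 18L),
                     length = 2L, parent_alleles = "TT", child_alleles = "AA")
  out <- associate_mnms(irs, mnms)
  expect_equal(out$arm_mnms, 1L)     # columns 16-17 hit the left arm only
  expect_equal(out$spacer_mnms, 1L)  # columns 19-20 sit wholly in the spacer
  pairs <- attr(out, "pairs")
  expect_equal(nrow(pairs), 2L)      # the distant and wrong-taxon MNMs drop out
  # an MNM straddling the arm/spacer boundary carries both labels
  straddle <- data.frame(taxon = "A", start_col = 17L, end_col = 19L,
                         length = 2L, parent_alleles = "TT", child_alleles = "AA")
  out2 <- associate_mnms(irs, straddle)
  expect_equal(out2$arm_mnms, 1L)
  expect_equal(out2$spacer_mnms, 1L)
})

test_that("the QC filter rejects saturated branches and indels", {
  tr <- ape::read.tree(text = "((A:0.25,B:0.05):0.02,C:0.05);")
  gene <- strrep("ACGATT", 20)
  aln <- c(A = gene, B = gene, C = gene)
  anc <- setNames(c(gene, gene), c("Node4", "Node5"))
  ir <- data.frame(seq_id = "A", col_left_start = 12L, col_right_end = 36L,
                   arm_len = 10L, spacer_len = 4L)
  out <- qc_filter(ir, aln, tr, anc)
  expect_false(out$keep)
  expect_identical(out$reason, "branch_length")
  ir$seq_id <- "B"
  out2 <- qc_filter(ir, aln, tr, anc)
  expect_true(out2$keep)
  expect_equal(out2$nt_score, out2$codon_score)  # identical regions
  # a gap inside the footprint between strain and parent is rejected
  alng <- aln
  substr(alng["B"], 20, 20) <- "-"
  out3 <- qc_filter(ir, alng, tr, anc)
  expect_identical(out3$reason, "indel")
})

test_that("frameshifted sister alignments fail the codon-score check", {
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  set.seed(42)
  gene <- random_dna(120)
  # sister carries a 1-bp deletion inside the region, re-padded at the end:
  # the nucleotide alignment absorbs it with one free gap, the codon-unit
  # alignment is thrown out of frame
  shifted <- paste0(substr(gene, 1, 30), substr(gene, 32, 120), "A")
  aln <- c(A = gene, B = shifted)
  anc <- setNames(gene, "Node3")
  ir <- data.frame(seq_id = "A", col_left_start = 12L, col_right_end = 40L,
                   arm_len = 12L, spacer_len = 4L)
  out <- qc_filter(ir, aln, tr, anc)
  expect_false(out$keep)
  expect_identical(out$reason, "msa_quality")
  expect_gt(abs(out$nt_score - out$codon_score), 15)
})

test_that("the optional column-confidence hook applies the 0.95 cutoff", {
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  gene <- strrep("ACGATT", 20)
  aln <- c(A = gene, B = gene)
  anc <- setNames(gene, "Node3")
  ir <- data.frame(seq_id = "A", col_left_start = 12L, col_right_end = 36L,
                   arm_len = 10L, spacer_len = 4L)
  conf <- rep(1, nchar(gene))
  expect_true(qc_filter(ir, aln, tr, anc, column_confidence = conf)$keep)
  conf[20] <- 0.8
  out <- qc_filter(ir, aln, tr, anc, column_confidence = conf)
  expect_identical(out$reason, "alignment_confidence")
})

test_that("the NW scorer agrees with a reference dynamic program", {
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:4, sample(3:12, 1), replace = TRUE)
    b <- sample(1:4, sample(3:12, 1), replace = TRUE)
    expect_equal(
      irswitch:::.nw_score_c(matrix(a, 1), matrix(b, 1), 1, -1, 0),
      nw_reference(a, b, 1, -1, 0))
  }
})
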