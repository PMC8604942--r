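test_that("the IR score formula matches hand-computed values", {
  expect_equal(compute_ir_score(0, 0, 0, 0), 1)
  expect_equal(compute_ir_score(1, 0, 0, 1), 4)
  expect_equal(compute_ir_score(0, 3, 2, 0), 1 / 12)
  expect_error(compute_ir_score(-1, 0, 0, 0), "negative")
})

test_that("the score is antisymmetric and monotone in its counts", {
  set.seed(14)
  for (i in 1:200) {
    x <- sample(0:30, 4, replace = TRUE)
    expect_equal(compute_ir_score(x[1], x[2], x[3], x[4]) *
                 compute_ir_score(x[3], x[4], x[1], x[2]), 1)
  }
  s <- compute_ir_score(2, 5, 1, 6)
  expect_gt(compute_ir_score(3, 5, 1, 6), s)
  expect_gt(compute_ir_score(2, 5, 1, 7), s)
  expect_lt(compute_ir_score(2, 6, 1, 6), s)
  expect_lt(compute_ir_score(2, 5, 2, 6), s)
})

test_that("empirical significance uses the add-one upper tail with ties", {
  r <- empirical_significance(5, rep(1, 100))
  expect_equal(r$empirical_p, 1 / 101)
  expect_true(r$significant)
  r2 <- empirical_significance(1, rep(1, 100))
  expect_equal(r2$empirical_p, 1)
  expect_false(r2$significant)
  # 5 nulls strictly greater, no ties: rank 6 from the top
  nulls <- c(seq(2, 3, length.out = 5), seq(0, 0.9, length.out = 95))
  r3 <- empirical_significance(1.5, nulls)
  expect_equal(r3$empirical_p, 6 / 101)
  expect_false(r3$significant)
  expect_error(empirical_significance(1, numeric()), "empty")
})

test_that("controls sit in the nearest qualifying IR-free window", {
  gene <- strrep("ACT", 300)   # 900 columns
  arm <- 10L
  irs <- data.frame(seq_id = "s", arm_len = arm, spacer_len = 5L,
                    col_left_start = 100L, col_right_end = 125L)
  ctl <- match_controls(irs, c(s = gene), all_irs = irs)
  expect_false(ctl$missing)
  expect_equal(ctl$distance, 0L)
  expect_equal(ctl$control_start, 100L - arm)   # 5' window preferred on ties
  # window overlapping any IR footprint is skipped
  all2 <- rbind(irs, data.frame(seq_id = "s", arm_len = 8L, spacer_len = 0L,
                                col_left_start = 85L, col_right_end = 101L))
  ctl2 <- match_controls(irs, c(s = gene), all_irs = all2)
  expect_equal(ctl2$control_start, 125L)        # left side blocked at d=0
  # gaps disqualify windows: everything 5' of the IR is gapped out
  gapped <- paste0(strrep("-", 100), substr(gene, 101, 900))
  ctl3 <- match_controls(irs, c(s = gapped), all_irs = irs)
  expect_equal(ctl3$control_start, 125L)
})

test_that("control search matches a brute-force nearest-interval oracle", {
  set.seed(77)
  for (i in 1:20) {
    L <- 120L
    arm <- sample(6:10, 1)
    s_ir <- sample(20:80, 1)
    e_ir <- s_ir + 2L * arm + sample(0:6, 1)
    if (e_ir > L) next
    # random forbidden decoy footprints
    n_dec <- sample(0:4, 1)
    dec <- data.frame(seq_id = rep("s", n_dec),
                      col_left_start = sample(0:(L - 12L), n_dec, replace = TRUE))
    dec$col_right_end <- pmin(L, dec$col_left_start +
                                sample(8:20, n_dec, replace = TRUE))
    irs <- data.frame(seq_id = "s", arm_len = arm, spacer_len = e_ir - s_ir - 2L * arm,
                      col_left_start = s_ir, col_right_end = e_ir)
    all_irs <- rbind(irs[, c("seq_id", "col_left_start", "col_right_end")], dec)
    got <- match_controls(irs, c(s = strrep("A", L)), all_irs = all_irs)
    # oracle: test every window
    f <- rep(FALSE, L)
    for (r in seq_len(nrow(all_irs))) {
      f[(all_irs$col_left_start[r] + 1):all_irs$col_right_end[r]] <- TRUE
    }
    best <- NULL
    for (w in 0:(L - arm)) {
      if (any(f[(w + 1):(w + arm)])) next
      d <- if (w + arm <= s_ir) s_ir - (w + arm) else if (w >= e_ir) w - e_ir else NA
      if (is.na(d)) next
      if (is.null(best) || d < best$d) best <- list(w = w, d = d)
    }
    if (is.null(best)) {
      expect_true(got$missing)
    } else {
      expect_equal(got$distance, best$d)
      expect_equal(got$control_start, best$w)
    }
  }
})

test_that("shared IR footprints receive one shared control position", {
  gene <- strrep("ACT", 100)
  irs <- data.frame(seq_id = c("s1", "s2"), arm_len = 8L, spacer_len = 4L,
                    col_left_start = 60L, col_right_end = 80L)
  ctl <- match_controls(irs, c(s1 = gene, s2 = gene), all_irs = irs)
  expect_equal(length(unique(ctl$control_start)), 1L)
  expect_false(any(ctl$missing))
})

test_that("per-gene counts feed the score as documented", {
  # hand-built gene: strain A carries a perfect arm-8 IR formed by an
  # arm-homogenizing MNM on its terminal branch (parent form imperfect)
  arm <- "GGATCCAT"
  core <- paste0(arm, "TCAT", reverse_complement(arm))  # arm 8, spacer 4
  gene <- paste0(strrep("ACT", 30), "T", core, "TT", strrep("GAT", 30))
  gene <- substr(gene, 1, 3 * (nchar(gene) %/% 3))
  old <- gene
  substr(old, 93, 94) <- "TT"                 # ancestral: imperfect left arm
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.02,out:0.2);")
  aln <- c(A = gene, B = old, out = old)
  anc <- setNames(c(old, old), c("Node4", "Node5"))
  res <- irswitch:::.gene_bin_counts(aln, tr, anc, 8L, "out")
  expect_equal(unname(res$counts), c(1L, 0L, 0L, 1L))   # a, b, c, d
  expect_equal(res$score, 4)
  expect_equal(res$mnms$start_col, 92L)
  expect_equal(res$mnms$length, 2L)
})
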