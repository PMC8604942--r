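test_that("GY94 rate matrix has the required structure", {
  par <- test_params(K = 1L)
  # omega = 0 silences every nonsynonymous rate
  Q0 <- build_rate_matrix(par, 0, scale = FALSE)
  tab <- irswitch:::.codon_table()
  expect_true(all(Q0[tab$type >= 3L] == 0))
  expect_true(all(Q0[tab$type %in% c(1L, 2L)] > 0))
  # kappa = 1, omega = 1, uniform frequencies: all single-nt changes equal
  par1 <- codon_model_params(kappa = 1, omega_shape = 1, omega_rate = 1,
                             n_categories = 1, codon_freqs = rep(1 / 61, 61))
  Q1 <- build_rate_matrix(par1, 1, scale = FALSE)
  expect_equal(unname(unique(Q1[tab$type > 0L])), 1 / 61)
  expect_true(all(Q1[tab$type == 0L & row(Q1) != col(Q1)] == 0))
  # rows sum to zero; mean rate 1 after scaling; detailed balance
  Q <- build_rate_matrix(par, 0.5)
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  pi <- rep(1 / 61, 61)
  expect_equal(-sum(pi * diag(Q)), 1)
  expect_equal(pi * Q, t(pi * t(Q)), tolerance = 1e-12)  # pi_i q_ij = pi_j q_ji
  expect_error(build_rate_matrix(par, -0.1), "omega")
})

test_that("transition probabilities are stochastic with stationary pi", {
  par <- test_params(K = 3L)
  model <- irswitch:::.build_model(par, par$codon_freqs)
  for (t in c(0, 1e-4, 0.05, 0.7, 5, 50)) {
    P <- irswitch:::.pmat(model, 2L, t)
    expect_true(all(abs(rowSums(P) - 1) < 1e-10))
    expect_true(all(P >= 0))
    expect_equal(as.vector(par$codon_freqs %*% P), par$codon_freqs,
                 tolerance = 1e-8)
  }
})

test_that("pruning matches the closed form for identical zero-distance taxa", {
  par <- test_params(K = 2L)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln <- codon_alignment(c(A = "ATGAAACCC", B = "ATGAAACCC"))
  expect_equal(pruning_loglik(tr, aln, par), 3 * log(1 / 61))
})

test_that("pruning equals exhaustive enumeration over ancestral codons", {
  par <- test_params(K = 2L)
  tr <- ape::read.tree(text = "((A:0.1,B:0.15):0.05,(C:0.2,D:0.08):0.12);")
  sim <- simulate_alignment(tr, par, n_codons = 10, seed = 101)
  # add missing data to exercise the partial-likelihood path
  seqs <- unclass(sim)
  substr(seqs[["C"]], 4, 6) <- "NNN"
  aln <- codon_alignment(seqs)
  oracle <- exhaustive_4taxon(0.1, 0.15, 0.2, 0.08, 0.05, 0.12, aln, par)
  expect_equal(pruning_loglik(tr, aln, par), oracle$loglik, tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting along a branch", {
  par <- test_params(K = 2L)
  t1 <- ape::read.tree(text = "((A:0.1,B:0.15):0.05,(C:0.2,D:0.08):0.12);")
  t2 <- ape::read.tree(text = "((A:0.1,B:0.15):0.12,(C:0.2,D:0.08):0.05);")
  t3 <- ape::read.tree(text = "((A:0.1,B:0.15):0.17,(C:0.2,D:0.08):0.0);")
  sim <- simulate_alignment(t1, par, n_codons = 20, seed = 7)
  lls <- c(pruning_loglik(t1, sim, par), pruning_loglik(t2, sim, par),
           pruning_loglik(t3, sim, par))
  expect_equal(lls[2], lls[1], tolerance = 1e-8)
  expect_equal(lls[3], lls[1], tolerance = 1e-8)
})

test_that("fitting improves the likelihood and recovers kappa", {
  tr <- ape::rphylo(12, 1, 0)
  tr$edge.length <- tr$edge.length * 0.3 / max(ape::node.depth.edgelength(tr))
  gen <- codon_model_params(kappa = 2, omega_shape = 0.9, omega_rate = 3,
                            n_categories = 8, codon_freqs = rep(1 / 61, 61))
  sim <- simulate_alignment(tr, gen, n_codons = 300, seed = 77)
  init <- codon_model_params(kappa = 1, omega_shape = 1, omega_rate = 1,
                             n_categories = 4)
  ll0 <- pruning_loglik(tr, sim, codon_model_params(
    kappa = 1, omega_shape = 1, omega_rate = 1, n_categories = 4,
    codon_freqs = f3x4_frequencies(sim)))
  fit <- fit_parameters(tr, sim, init = init, n_categories = 4)
  expect_true(fit$converged)
  expect_gte(fit$loglik, ll0)
  expect_gt(fit$params$kappa, 2 * 0.8)
  expect_lt(fit$params$kappa, 2 * 1.2)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.1);")
  aln <- codon_alignment(setNames(rep(paste(rep("ATGAAACCCGGG", 2), collapse = ""), 3),
                                  c("A", "B", "C")))
  fit <- fit_parameters(tr, aln, init = test_params(K = 1L),
                        optimize_branch_lengths = TRUE, n_categories = 1)
  expect_true(all(fit$tree$edge.length < 1e-3))
})

test_that("unanimous leaves reconstruct with near-certain posteriors", {
  par <- test_params(K = 2L)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.05);")
  aln <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG"))
  anc <- reconstruct_ancestors(tr, aln, par)
  expect_identical(unname(anc$states), "ATG")
  expect_gt(anc$max_posterior[1, 1], 0.99)
})

test_that("marginal reconstruction matches the exhaustive posterior", {
  par <- test_params(K = 2L)
  tr <- ape::read.tree(text = "((A:0.1,B:0.15):0.05,(C:0.2,D:0.08):0.12);")
  sim <- simulate_alignment(tr, par, n_codons = 10, seed = 55)
  oracle <- exhaustive_4taxon(0.1, 0.15, 0.2, 0.08, 0.05, 0.12, sim, par)
  anc <- reconstruct_ancestors(tr, sim, par, keep_posteriors = TRUE)
  # ape numbers the (A,B) ancestor 6 and the (C,D) ancestor 7 here
  tab <- irswitch:::.codon_table()
  got_u <- anc$posteriors[["Node6"]]
  got_v <- anc$posteriors[["Node7"]]
  expect_equal(max(abs(got_u - oracle$post_u)), 0, tolerance = 1e-8)
  expect_equal(max(abs(got_v - oracle$post_v)), 0, tolerance = 1e-8)
  # argmax states agree with the oracle argmax
  amax_u <- apply(oracle$post_u, 2, which.max)
  expect_identical(anc$states[["Node6"]], paste(tab$codons[amax_u], collapse = ""))
})

test_that("ancestral codons are recovered on short-branch synthetic data", {
  u <- generate_universe(n_genes = 2, n_taxa = 10, gene_length_codons = 120,
                         seed = 404)
  acc <- vapply(1:2, function(g) {
    anc <- reconstruct_ancestors(u$tree, u$alignments[[g]], u$truth$params)
    true <- u$truth$ancestors[[g]]
    ids <- intersect(names(true), names(anc$states))
    S <- nchar(true[[1]]) / 3
    mean(vapply(ids, function(n) {
      tc <- substring(true[[n]], 3 * (1:S) - 2, 3 * (1:S))
      rc <- substring(anc$states[[n]], 3 * (1:S) - 2, 3 * (1:S))
      mean(tc == rc)
    }, 0))
  }, 0)
  expect_gt(mean(acc), 0.95)
})

test_that("all-gap columns are reported as gaps in ancestors", {
  par <- test_params(K = 1L)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.05);")
  aln <- c(A = "---ATG", B = "---ATG", C = "---ATG")
  anc <- reconstruct_ancestors(tr, aln, par)
  expect_identical(unname(anc$states), "---ATG")
})
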