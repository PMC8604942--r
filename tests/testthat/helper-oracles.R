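# Independent oracles and small fixture builders used across the suite.

# Brute-force IR oracle: enumerate every (left_start, arm, spacer) triple,
# test arm perfection by substring equality against the reverse-complemented
# sequence, and keep triples whose arms cannot extend outward or inward.
brute_irs <- function(seq, min_arm, max_spacer) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1L]]),
              collapse = "")
  nN <- c(0L, cumsum(strsplit(seq, "")[[1L]] == "N"))
  noN <- function(from0, len) nN[from0 + len + 1L] - nN[from0 + 1L] == 0L
  keyset <- new.env(parent = emptyenv())
  trip <- list()
  for (a in min_arm:(L %/% 2L)) {
    for (g in 0:max_spacer) {
      n <- L - 2L * a - g
      if (n < 0L) next
      ls <- 0:n
      rs <- ls + a + g
      eq <- substring(seq, rs + 1L, rs + a) ==
        substring(rc, L - ls - a + 1L, L - ls) & noN(ls, a) & noN(rs, a)
      for (l in ls[eq]) {
        assign(sprintf("%d:%d:%d", l, a, g), TRUE, keyset)
        trip[[length(trip) + 1L]] <- c(l, a, g)
      }
    }
  }
  has <- function(l, a, g) exists(sprintf("%d:%d:%d", l, a, g), keyset)
  out <- NULL
  for (t in trip) {
    l <- t[1L]; a <- t[2L]; g <- t[3L]
    if (has(l - 1L, a + 1L, g)) next                # outward extendable
    if (g >= 2L && has(l, a + 1L, g - 2L)) next     # inward extendable
    out <- rbind(out, t)
  }
  if (is.null(out)) out <- matrix(integer(), 0L, 3L)
  colnames(out) <- c("left_start", "arm_len", "spacer_len")
  unname(out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE])
}

ir_triples <- function(df) {
  m <- as.matrix(df[, c("left_start", "arm_len", "spacer_len")])
  storage.mode(m) <- "integer"
  unname(m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE])
}

random_dna <- function(n, with_n = FALSE) {
  pool <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(.24, .24, .24, .24, .04) else rep(.25, 4)
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

# Exhaustive likelihood/posterior oracle for the rooted 4-taxon topology
# ((A,B)u,(C,D)v)r: sums over all 61^3 internal codon assignments.
exhaustive_4taxon <- function(tA, tB, tC, tD, t1, t2, aln, params) {
  model <- irswitch:::.build_model(params, params$codon_freqs)
  idx <- irswitch:::.codon_index_matrix(aln)
  S <- nrow(idx)
  K <- model$K
  grid <- expand.grid(r = 1:61, u = 1:61, v = 1:61)
  pi <- model$pi
  lik <- matrix(0, S, K)
  post_u <- matrix(0, 61L, S)
  post_v <- matrix(0, 61L, S)
  leafvec <- function(P, state) if (is.na(state)) rep(1, 61) else P[, state]
  for (k in seq_len(K)) {
    P1 <- irswitch:::.pmat(model, k, t1); P2 <- irswitch:::.pmat(model, k, t2)
    PA <- irswitch:::.pmat(model, k, tA); PB <- irswitch:::.pmat(model, k, tB)
    PC <- irswitch:::.pmat(model, k, tC); PD <- irswitch:::.pmat(model, k, tD)
    base <- pi[grid$r] * P1[cbind(grid$r, grid$u)] * P2[cbind(grid$r, grid$v)]
    for (s in seq_len(S)) {
      joint <- base *
        leafvec(PA, idx[s, "A"])[grid$u] * leafvec(PB, idx[s, "B"])[grid$u] *
        leafvec(PC, idx[s, "C"])[grid$v] * leafvec(PD, idx[s, "D"])[grid$v]
      lik[s, k] <- sum(joint)
      post_u[, s] <- post_u[, s] + rowsum(joint, grid$u)[, 1L] / K
      post_v[, s] <- post_v[, s] + rowsum(joint, grid$v)[, 1L] / K
    }
  }
  list(loglik = sum(log(rowMeans(lik))),
       post_u = sweep(post_u, 2L, colSums(post_u), "/"),
       post_v = sweep(post_v, 2L, colSums(post_v), "/"))
}

# Plain R Needleman-Wunsch reference for small unit-sequence cases
nw_reference <- function(a, b, match, mismatch, gap) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- (0:n) * gap
  S[1L, ] <- (0:m) * gap
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1L, j + 1L] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1L] + gap, S[i + 1L, j] + gap)
  }
  S[n + 1L, m + 1L]
}

# parameters used by most model-level tests (uniform codon frequencies)
test_params <- function(K = 2L, kappa = 2.5, shape = 0.7, rate = 2) {
  codon_model_params(kappa = kappa, omega_shape = shape, omega_rate = rate,
                     n_categories = K, codon_freqs = rep(1 / 61, 61L))
}
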