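# GY94-type codon substitution model with gamma-distributed omega (M5):
# likelihood by Felsenstein pruning over 61 sense-codon states, numerical
# parameter estimation, and marginal ancestral sequence reconstruction.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

# Lazily built codon lookup tables: the 61 sense codons (lexicographic
# A<C<G<T), their amino acids, and a 61x61 "change type" matrix:
#   0 = multi-nucleotide change (rate 0), 1 = synonymous transversion,
#   2 = synonymous transition, 3 = nonsyn transversion, 4 = nonsyn transition
.codon_table <- function() {
  if (!is.null(.irswitch$codon_table)) return(.irswitch$codon_table)
  codons64 <- paste0(rep(.BASES, each = 16L),
                     rep(rep(.BASES, each = 4L), 4L),
                     rep(.BASES, 16L))
  codons <- codons64[!codons64 %in% .STOPS]
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  nt <- t(vapply(codons, function(cd) {
    match(strsplit(cd, "")[[1L]], .BASES)
  }, integer(3L)))
  is_ts <- function(x, y) (x + y) %in% c(4L, 6L)  # A(1)+G(3), C(2)+T(4)
  type <- matrix(0L, 61L, 61L)
  for (i in 1:61) for (j in 1:61) {
    if (i == j) next
    d <- which(nt[i, ] != nt[j, ])
    if (length(d) != 1L) next
    ts <- is_ts(nt[i, d], nt[j, d])
    syn <- aa[i] == aa[j]
    type[i, j] <- 1L + ts + 2L * !syn
  }
  .irswitch$codon_table <- list(codons = codons, aa = aa, nt = nt, type = type)
  .irswitch$codon_table
}

# codon strings -> 1..61 index; stops, gaps, N-containing codons -> NA
.codon_index <- function(codons) {
  match(codons, .codon_table()$codons)
}

#' Parameters of the M5 codon model
#'
#' A GY94-type codon model in which the nonsynonymous/synonymous rate ratio
#' omega varies across sites following a Gamma(`omega_shape`, `omega_rate`)
#' distribution, discretized into `n_categories` equal-probability categories
#' (category value = bin mean). `kappa` is the transition/transversion rate
#' ratio.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_shape,omega_rate Gamma shape and rate for omega (> 0);
#'   mean omega = `omega_shape / omega_rate`.
#' @param n_categories Number of discrete omega categories (>= 1).
#' @param codon_freqs Optional vector of 61 stationary sense-codon
#'   frequencies (summing to 1); when `NULL`, consumers estimate F3x4
#'   frequencies from the alignment (or use uniform frequencies for
#'   de novo simulation).
#' @return A list with class `codon_model_params`.
#' @export
codon_model_params <- function(kappa = 2, omega_shape = 1, omega_rate = 2,
                               n_categories = 8L, codon_freqs = NULL) {
  stopifnot(kappa > 0, omega_shape > 0, omega_rate > 0, n_categories >= 1L)
  if (!is.null(codon_freqs)) {
    stopifnot(length(codon_freqs) == 61L, all(codon_freqs >= 0),
              abs(sum(codon_freqs) - 1) < 1e-8)
  }
  structure(list(kappa = kappa, omega_shape = omega_shape,
                 omega_rate = omega_rate,
                 n_categories = as.integer(n_categories),
                 codon_freqs = codon_freqs),
            class = "codon_model_params")
}

# means of equal-probability gamma quantile bins (standard discretization)
.discretize_omega <- function(shape, rate, k) {
  if (k == 1L) return(shape / rate)
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = rate)
  k * (shape / rate) *
    (pgamma(b[-1L], shape = shape + 1, rate = rate) -
     pgamma(b[-(k + 1L)], shape = shape + 1, rate = rate))
}

#' Build the GY94 instantaneous rate matrix for one omega value
#'
#' Rates are zero for codon pairs differing at more than one nucleotide;
#' otherwise proportional to the target codon frequency, multiplied by
#' `kappa` for transitions and by `omega_value` for nonsynonymous changes.
#' Rows sum to zero; with `scale = TRUE` the matrix is scaled so the mean
#' substitution rate at stationarity is 1 (branch lengths are then expected
#' substitutions per codon site).
#'
#' @param params A [codon_model_params()] object.
#' @param omega_value Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freqs Optional 61 stationary frequencies (overrides params).
#' @param scale Scale mean rate at stationarity to 1 (default `TRUE`).
#' @return 61 x 61 generator matrix (codons in lexicographic order).
#' @export
build_rate_matrix <- function(params, omega_value, codon_freqs = NULL,
                              scale = TRUE) {
  if (omega_value < 0) stop("build_rate_matrix(): omega_value must be >= 0")
  pi <- codon_freqs %||% params$codon_freqs
  if (is.null(pi)) stop("build_rate_matrix(): no codon frequencies available")
  tab <- .codon_table()
  Q <- matrix(0, 61L, 61L)
  ty <- tab$type
  Q[ty > 0L] <- 1
  Q[ty == 2L | ty == 4L] <- params$kappa
  Q[ty >= 3L] <- Q[ty >= 3L] * omega_value
  Q <- Q * rep(pi, each = 61L)        # q_ij ~ pi_j
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# F3x4 codon frequencies from the alignment (position-specific nucleotide
# frequencies with a +1 pseudocount to keep all sense codons reachable)
#' Empirical F3x4 codon frequencies of a codon alignment
#'
#' @param alignment A [codon_alignment()] (or named character vector).
#' @return Vector of 61 sense-codon frequencies.
#' @export
f3x4_frequencies <- function(alignment) {
  counts <- matrix(1, 4L, 3L, dimnames = list(.BASES, NULL))
  for (s in alignment) {
    ch <- strsplit(s, "")[[1L]]
    pos <- (seq_along(ch) - 1L) %% 3L + 1L
    ok <- ch %in% .BASES
    if (any(ok)) {
      t3 <- table(factor(ch[ok], levels = .BASES), pos[ok])
      counts[, as.integer(colnames(t3))] <-
        counts[, as.integer(colnames(t3))] + t3
    }
  }
  p <- sweep(counts, 2L, colSums(counts), "/")
  tab <- .codon_table()
  pi <- p[tab$nt[, 1L], 1L] * p[tab$nt[, 2L], 2L] * p[tab$nt[, 3L], 3L]
  pi / sum(pi)
}

# Assemble the computational model: scaled per-category generators plus
# eigendecompositions of the symmetrized reversible generators. Scaling is
# applied across the omega mixture (equal category weights), so branch
# lengths are expected substitutions per codon site under the full model.
.build_model <- function(params, codon_freqs = NULL) {
  pi <- codon_freqs %||% params$codon_freqs
  if (is.null(pi)) stop("no codon frequencies: supply codon_freqs or set them in params")
  K <- params$n_categories
  omegas <- .discretize_omega(params$omega_shape, params$omega_rate, K)
  Qs <- lapply(omegas, function(w) {
    build_rate_matrix(params, w, codon_freqs = pi, scale = FALSE)
  })
  mu <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  f <- mean(mu)
  sp <- sqrt(pi)
  eig <- lapply(Qs, function(Q) {
    Q <- Q / f
    B <- diag(sp) %*% Q %*% diag(1 / sp)
    B <- (B + t(B)) / 2                      # enforce symmetry numerically
    e <- eigen(B, symmetric = TRUE)
    list(U = e$vectors / sp, Uinv = t(e$vectors) * rep(sp, each = 61L),
         lambda = e$values)
  })
  list(params = params, pi = pi, omegas = omegas, K = K, eig = eig)
}

# transition probability matrix P(t) for category k
.pmat <- function(model, k, t) {
  e <- model$eig[[k]]
  P <- e$U %*% (exp(e$lambda * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# alignment -> S x ntaxa matrix of codon indices (NA = gap/N/stop codon)
.codon_index_matrix <- function(alignment) {
  S <- nchar(alignment[[1L]]) %/% 3L
  idx <- vapply(alignment, function(s) {
    .codon_index(substring(s, 3L * seq_len(S) - 2L, 3L * seq_len(S)))
  }, integer(S))
  if (S == 1L) idx <- matrix(idx, nrow = 1L, dimnames = list(NULL, names(alignment)))
  idx
}

# 61 x S indicator partials for one leaf (missing data = all ones)
.leaf_partial <- function(idx, S) {
  L <- matrix(0, 61L, S)
  obs <- !is.na(idx)
  L[cbind(idx[obs], which(obs))] <- 1
  if (any(!obs)) L[, !obs] <- 1
  L
}

# Pruning engine. Returns per-site, per-category log-likelihoods and, when
# keep_messages, the scaled per-node partials/messages needed for marginal
# ancestral reconstruction.
.prune <- function(tree, idx, model, keep_messages = FALSE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge
  elen <- tr$edge.length
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L
  S <- nrow(idx)
  tip_col <- match(tr$tip.label, colnames(idx))
  if (anyNA(tip_col)) stop("tree tips missing from alignment: ",
                           paste(tr$tip.label[is.na(tip_col)], collapse = ", "))
  leafL <- lapply(seq_len(ntip), function(i) .leaf_partial(idx[, tip_col[i]], S))
  K <- model$K
  llmat <- matrix(NA_real_, S, K)
  msgs <- if (keep_messages) vector("list", K)
  parts <- if (keep_messages) vector("list", K)
  for (k in seq_len(K)) {
    partial <- vector("list", ntip + nnode)
    logsc <- vector("list", ntip + nnode)
    msg <- if (keep_messages) vector("list", ntip + nnode)
    for (i in seq_len(ntip)) { partial[[i]] <- leafL[[i]]; logsc[[i]] <- numeric(S) }
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L]; ch <- edges[e, 2L]
      P <- .pmat(model, k, elen[e])
      M <- P %*% partial[[ch]]
      sc <- colSums(M)
      sc[sc == 0] <- 1
      M <- M * rep(1 / sc, each = 61L)
      if (keep_messages) msg[[ch]] <- M
      lg <- logsc[[ch]] + log(sc)
      if (is.null(partial[[p]])) {
        partial[[p]] <- M
        logsc[[p]] <- lg
      } else {
        partial[[p]] <- partial[[p]] * M
        logsc[[p]] <- logsc[[p]] + lg
      }
    }
    site_l <- colSums(partial[[root]] * model$pi)
    llmat[, k] <- ifelse(site_l > 0, log(site_l), -Inf) + logsc[[root]]
    if (keep_messages) { msgs[[k]] <- msg; parts[[k]] <- partial }
  }
  list(tree = tr, llmat = llmat, msgs = msgs, parts = parts,
       root = root, ntip = ntip, edges = edges, elen = elen)
}

#' Log-likelihood of a codon alignment under the M5 model
#'
#' Felsenstein pruning over the 61 sense-codon states; site likelihoods are
#' averaged over the discretized omega categories (equal prior weights) and
#' summed as logs over sites. Gaps, Ns and stop codons are treated as
#' missing data.
#'
#' @param tree Rooted `phylo` tree; branch lengths in expected substitutions
#'   per codon site; tip labels must match alignment names.
#' @param alignment A [codon_alignment()].
#' @param params A [codon_model_params()]; when `codon_freqs` is `NULL`,
#'   F3x4 frequencies are estimated from the alignment.
#' @return Total log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, alignment, params) {
  pi <- params$codon_freqs %||% f3x4_frequencies(alignment)
  model <- .build_model(params, pi)
  idx <- .codon_index_matrix(alignment)
  pr <- .prune(tree, idx, model)
  mx <- apply(pr$llmat, 1L, max)
  ll <- ifelse(is.finite(mx),
               log(rowMeans(exp(pr$llmat - mx))) + mx, -Inf)
  if (any(!is.finite(ll))) {
    warning("zero-likelihood site(s); returning -Inf")
    return(-Inf)
  }
  sum(ll)
}

#' Fit M5 model parameters by maximum likelihood
#'
#' Optimizes kappa and the gamma parameters of omega (and optionally all
#' branch lengths) on the log scale with Nelder-Mead, using F3x4 codon
#' frequencies estimated from the alignment.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param alignment A [codon_alignment()] (>= 2 taxa).
#' @param init Optional starting [codon_model_params()].
#' @param optimize_branch_lengths Also optimize branch lengths (default
#'   `FALSE`; slower).
#' @param n_categories Omega discretization (default from `init`, else 8).
#' @return List: `params` (fitted [codon_model_params()] with F3x4
#'   frequencies), `tree` (branch lengths updated if optimized), `loglik`,
#'   and `converged` flag.
#' @export
fit_parameters <- function(tree, alignment, init = NULL,
                           optimize_branch_lengths = FALSE,
                           n_categories = NULL) {
  stopifnot(length(alignment) >= 2L)
  init <- init %||% codon_model_params()
  K <- as.integer(n_categories %||% init$n_categories)
  pi <- f3x4_frequencies(alignment)
  idx <- .codon_index_matrix(alignment)
  nedge <- nrow(tree$edge)
  mk_ll <- function(par) {
    pars <- codon_model_params(kappa = exp(par[1L]),
                               omega_shape = exp(par[2L]),
                               omega_rate = exp(par[3L]),
                               n_categories = K, codon_freqs = pi)
    tr <- tree
    if (optimize_branch_lengths) tr$edge.length <- exp(par[-(1:3)])
    model <- .build_model(pars, pi)
    pr <- .prune(tr, idx, model)
    mx <- apply(pr$llmat, 1L, max)
    ll <- ifelse(is.finite(mx), log(rowMeans(exp(pr$llmat - mx))) + mx, -1e10)
    -sum(ll)
  }
  par0 <- log(c(init$kappa, init$omega_shape, init$omega_rate))
  if (optimize_branch_lengths) {
    par0 <- c(par0, log(pmax(tree$edge.length, 1e-6)))
  }
  opt <- optim(par0, mk_ll, method = "Nelder-Mead",
               control = list(maxit = if (optimize_branch_lengths) 2000L else 500L,
                              reltol = 1e-8))
  fitted_tree <- tree
  if (optimize_branch_lengths) fitted_tree$edge.length <- exp(opt$par[-(1:3)])
  list(params = codon_model_params(kappa = exp(opt$par[1L]),
                                   omega_shape = exp(opt$par[2L]),
                                   omega_rate = exp(opt$par[3L]),
                                   n_categories = K, codon_freqs = pi),
       tree = fitted_tree,
       loglik = -opt$value,
       converged = opt$convergence == 0L)
}

#' Marginal ancestral codon sequence reconstruction
#'
#' For every internal node and codon site, the marginal posterior over the
#' 61 sense codons is computed (mixing the omega categories by their
#' per-site posterior weights); the reported state is the argmax. Alignment
#' columns that are gaps in every leaf are reported as gaps.
#'
#' @param tree Rooted `phylo` tree; branch lengths in expected substitutions
#'   per codon site.
#' @param alignment A [codon_alignment()].
#' @param params A [codon_model_params()] (fitted; F3x4 frequencies are
#'   estimated from the alignment when not set).
#' @param keep_posteriors Keep the full 61 x sites posterior matrix per node
#'   (default `FALSE`; the per-site maximum posterior is always returned).
#' @return List: `states` (named character vector of nucleotide sequences,
#'   one per internal node), `max_posterior` (nodes x codon-sites matrix),
#'   `node_numbers` (ape node ids, named as in `states`), `loglik`, and
#'   optionally `posteriors`.
#' @export
reconstruct_ancestors <- function(tree, alignment, params,
                                  keep_posteriors = FALSE) {
  pi <- params$codon_freqs %||% f3x4_frequencies(alignment)
  model <- .build_model(params, pi)
  idx <- .codon_index_matrix(alignment)
  S <- nrow(idx)
  pr <- .prune(tree, idx, model, keep_messages = TRUE)
  tr <- pr$tree; edges <- pr$edges; elen <- pr$elen
  ntip <- pr$ntip; root <- pr$root
  nnode_tot <- ntip + tr$Nnode
  K <- model$K
  # per-site category weights
  mx <- apply(pr$llmat, 1L, max)
  w <- exp(pr$llmat - mx)
  w <- w / rowSums(w)                                   # S x K
  site_ll <- log(rowMeans(exp(pr$llmat - mx))) + mx
  children <- split(edges[, 2L], edges[, 1L])
  edge_of <- integer(nnode_tot); edge_of[edges[, 2L]] <- seq_len(nrow(edges))
  all_gap <- apply(idx, 1L, function(r) all(is.na(r)))
  post_mix <- vector("list", nnode_tot)
  for (k in seq_len(K)) {
    U <- vector("list", nnode_tot)
    U[[root]] <- matrix(model$pi, 61L, S)
    for (e in rev(seq_len(nrow(edges)))) {             # preorder
      p <- edges[e, 1L]; ch <- edges[e, 2L]
      if (ch <= ntip) next                             # leaf posteriors not needed
      Fmat <- U[[p]]
      for (sib in children[[as.character(p)]]) {
        if (sib != ch) Fmat <- Fmat * pr$msgs[[k]][[sib]]
      }
      P <- .pmat(model, k, elen[e])
      Uc <- crossprod(P, Fmat)
      sc <- colSums(Uc); sc[sc == 0] <- 1
      U[[ch]] <- Uc * rep(1 / sc, each = 61L)
    }
    for (v in (ntip + 1L):nnode_tot) {
      po <- U[[v]] * pr$parts[[k]][[v]]
      cs <- colSums(po); cs[cs == 0] <- 1
      po <- po * rep(w[, k] / cs, each = 61L)
      post_mix[[v]] <- if (is.null(post_mix[[v]])) po else post_mix[[v]] + po
    }
  }
  tab <- .codon_table()
  labs <- tr$node.label
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs)) {
    labs <- paste0("Node", (ntip + 1L):nnode_tot)
  }
  states <- character(tr$Nnode)
  maxp <- matrix(NA_real_, tr$Nnode, S)
  posts <- if (keep_posteriors) vector("list", tr$Nnode)
  for (v in (ntip + 1L):nnode_tot) {
    i <- v - ntip
    po <- post_mix[[v]]
    amax <- max.col(t(po), ties.method = "first")
    cods <- tab$codons[amax]
    cods[all_gap] <- "---"
    states[i] <- paste(cods, collapse = "")
    maxp[i, ] <- po[cbind(amax, seq_len(S))]
    if (keep_posteriors) posts[[i]] <- po
  }
  names(states) <- labs
  rownames(maxp) <- labs
  out <- list(states = states, max_posterior = maxp,
              node_numbers = setNames((ntip + 1L):nnode_tot, labs),
              tree = tr, loglik = sum(site_ll))
  if (keep_posteriors) out$posteriors <- setNames(posts, labs)
  out
}

#' Write reconstructed ancestral sequences
#'
#' Writes the ancestral states as FASTA (node-labelled) and the per-site
#' maximum posterior probabilities as TSV.
#'
#' @param anc Result of [reconstruct_ancestors()].
#' @param fasta_path,posterior_path Output files (`NULL` to skip one).
#' @export
write_ancestors <- function(anc, fasta_path, posterior_path = NULL) {
  write_fasta(anc$states, fasta_path)
  if (!is.null(posterior_path)) {
    df <- data.frame(node = rep(rownames(anc$max_posterior),
                                each = ncol(anc$max_posterior)),
                     codon_site = rep(seq_len(ncol(anc$max_posterior)) - 1L,
                                      nrow(anc$max_posterior)),
                     max_posterior = as.vector(t(anc$max_posterior)))
    write.table(df, posterior_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(anc)
}
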