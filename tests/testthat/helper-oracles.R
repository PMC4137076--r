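# Independent oracles used across the test suite.

# Path probabilities by plain scalar accumulation, summing over topics in
# ascending index order (the mathematically pinned-down order the
# implementation also uses, but coded independently in R).
oracle_path_probs <- function(theta, phi) {
  M <- nrow(theta); K <- ncol(theta); V <- ncol(phi)
  out <- matrix(0, M, V, dimnames = list(rownames(theta), colnames(phi)))
  for (d in seq_len(M)) {
    for (v in seq_len(V)) {
      acc <- 0
      for (k in seq_len(K)) acc <- acc + theta[d, k] * phi[k, v]
      out[d, v] <- acc
    }
  }
  out
}

# Exact LDA posterior means by exhaustive enumeration of all K^T topic
# assignment vectors under the collapsed joint. Feasible for <= 8 tokens.
# Returns E[theta] (M x K) and E[phi] (K x V).
oracle_lda_posterior <- function(docs, V, K, alpha, beta) {
  doc_of <- rep(seq_along(docs), lengths(docs))
  words <- unlist(docs)
  Tn <- length(words)
  M <- length(docs)
  stopifnot(Tn <= 10)

  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  theta_num <- matrix(0, M, K)
  phi_num <- matrix(0, K, V)
  total_w <- 0
  nd <- lengths(docs)

  for (r in seq_len(nrow(grid))) {
    z <- grid[r, ]
    ndk <- matrix(0, M, K)
    nkv <- matrix(0, K, V)
    for (i in seq_len(Tn)) {
      ndk[doc_of[i], z[i]] <- ndk[doc_of[i], z[i]] + 1
      nkv[z[i], words[i]] <- nkv[z[i], words[i]] + 1
    }
    logw <- sum(lgamma(ndk + alpha)) - sum(lgamma(nd + K * alpha)) +
      sum(lgamma(nkv + beta)) - sum(lgamma(rowSums(nkv) + V * beta))
    w <- exp(logw)
    total_w <- total_w + w
    theta_num <- theta_num + w * (ndk + alpha) / (nd + K * alpha)
    phi_num <- phi_num + w * (nkv + beta) / (rowSums(nkv) + V * beta)
  }
  list(theta = theta_num / total_w, phi = phi_num / total_w)
}

# Best-permutation topic matching: minimal mean absolute error between the
# rows of two phi matrices over all topic permutations.
matched_phi_mae <- function(phi_hat, phi_true) {
  K <- nrow(phi_true)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(K))) {
    mae <- mean(abs(phi_hat[p, , drop = FALSE] - phi_true))
    if (mae < best) best <- mae
  }
  best
}

# Construct a phenome_corpus directly from token-index documents.
corpus_from_docs <- function(docs, vocabulary) {
  if (is.null(names(docs))) {
    names(docs) <- sprintf("doc%02d", seq_along(docs))
  }
  structure(list(documents = docs, vocabulary = vocabulary),
            class = "phenome_corpus")
}

# Construct a bare lda_model from given theta/phi (for scoring tests).
model_from_matrices <- function(theta, phi) {
  structure(
    list(theta = theta, phi = phi,
         config = phenorepo::lda_config(ncol(theta)), n_samples = 1L),
    class = "lda_model"
  )
}

# Random row-normalized matrix with dimnames.
random_simplex_matrix <- function(nr, nc, rnames, cnames) {
  m <- matrix(stats::runif(nr * nc), nr, nc, dimnames = list(rnames, cnames))
  m / rowSums(m)
}
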