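#' Generate a synthetic phenome with known latent structure
#'
#' Simulates the generative process the model assumes: per-topic phenotype
#' distributions `phi` drawn from a symmetric Dirichlet(`beta`), per-drug
#' topic mixtures `theta` from a symmetric Dirichlet(`alpha`), and
#' `tokens_per_drug` phenotype tokens per drug via topic-then-phenotype
#' sampling. Token counts are binarized (cell = 1 iff drawn at least once) to
#' mirror the 0/1 incidence matrix the pipeline consumes; the raw counts are
#' kept for diagnostics. Optionally, `n_planted` known indication links with
#' high generative probability (above the `planted_quantile` of all
#' drug-indication cells, so above the matrix-wide median by default) are
#' removed from the emitted matrix as ground-truth held-out links for
#' recovery experiments. Fully deterministic given `seed`.
#'
#' @param n_drugs,n_side_effects,n_indications,n_topics positive counts.
#' @param alpha,beta generative Dirichlet concentrations.
#' @param tokens_per_drug phenotype draws per drug (>= 1).
#' @param n_planted number of high-probability known indication links to
#'   strip from the matrix; an error if more are requested than exist.
#' @param planted_quantile minimum generative `p(i|d)` quantile for a link to
#'   be plantable (default 0.75: top quartile).
#' @param seed integer seed.
#' @return a `synthetic_phenome`: `matrix` (a [phenome_matrix]), true
#'   `theta` and `phi`, raw token `counts`, `planted` links tibble
#'   (`drug_id`, `term_id`, `probability`), and the generating `spec`.
#' @export
generate_lda_phenome <- function(n_drugs = 200L, n_side_effects = 60L,
                                 n_indications = 40L, n_topics = 5L,
                                 alpha = 0.1, beta = 0.1,
                                 tokens_per_drug = 50L, n_planted = 0L,
                                 planted_quantile = 0.75, seed = 1L) {
  stopifnot(
    n_drugs >= 1L, n_side_effects >= 1L, n_indications >= 1L,
    n_topics >= 1L, alpha > 0, beta > 0, tokens_per_drug >= 1L,
    n_planted >= 0L, planted_quantile >= 0, planted_quantile <= 1
  )
  set.seed(as.integer(seed))
  pad <- function(prefix, n) sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))
  drugs <- pad("d", n_drugs)
  terms <- c(pad("se", n_side_effects), pad("ind", n_indications))
  classes <- rep(c("side_effect", "indication"),
                 c(n_side_effects, n_indications))
  V <- length(terms)
  K <- as.integer(n_topics)

  rdirichlet <- function(n, dim, conc) {
    g <- matrix(rgamma(n * dim, shape = conc), nrow = n)
    g / rowSums(g)
  }
  phi <- rdirichlet(K, V, beta)
  theta <- rdirichlet(n_drugs, K, alpha)
  dimnames(phi) <- list(paste0("topic", seq_len(K)), terms)
  dimnames(theta) <- list(drugs, paste0("topic", seq_len(K)))

  counts <- matrix(0L, n_drugs, V, dimnames = list(drugs, terms))
  for (d in seq_len(n_drugs)) {
    z <- sample.int(K, tokens_per_drug, replace = TRUE, prob = theta[d, ])
    for (k in unique(z)) {
      w <- sample.int(V, sum(z == k), replace = TRUE, prob = phi[k, ])
      tab <- tabulate(w, nbins = V)
      counts[d, ] <- counts[d, ] + tab
    }
  }
  binary <- (counts > 0) * 1

  # generative p(i|d): path probabilities restricted to indications,
  # renormalized per drug
  pphd <- theta %*% phi
  ind_cols <- which(classes == "indication")
  gen_pid <- pphd[, ind_cols, drop = FALSE]
  gen_pid <- gen_pid / rowSums(gen_pid)

  planted <- tibble(drug_id = character(), term_id = character(),
                    probability = numeric())
  if (n_planted > 0L) {
    thresh <- quantile(gen_pid, planted_quantile)
    ones <- which(binary[, ind_cols, drop = FALSE] == 1, arr.ind = TRUE)
    keepable <- ones[
      gen_pid[ones] >= thresh & rowSums(binary)[ones[, 1]] >= 2, ,
      drop = FALSE
    ]
    if (nrow(keepable) < n_planted) {
      abort(paste0(
        "only ", nrow(keepable), " plantable high-probability links exist; ",
        n_planted, " requested"
      ))
    }
    pick <- keepable[sample.int(nrow(keepable), n_planted), , drop = FALSE]
    planted <- tibble(
      drug_id = drugs[pick[, 1]],
      term_id = terms[ind_cols[pick[, 2]]],
      probability = gen_pid[pick]
    )
    binary[cbind(pick[, 1], ind_cols[pick[, 2]])] <- 0
  }

  structure(
    list(
      matrix = new_phenome_matrix(binary, classes),
      theta = theta, phi = phi, counts = counts, planted = planted,
      spec = list(
        n_drugs = n_drugs, n_side_effects = n_side_effects,
        n_indications = n_indications, n_topics = K, alpha = alpha,
        beta = beta, tokens_per_drug = tokens_per_drug,
        n_planted = n_planted, planted_quantile = planted_quantile,
        seed = as.integer(seed)
      )
    ),
    class = "synthetic_phenome"
  )
}

#' Block-structured phenome fixture
#'
#' Builds a block-diagonal incidence matrix: the drugs of block `b` carry
#' exactly block `b`'s phenotypes, a stated fraction of which are labelled
#' indications, and side-effect cells are then flipped independently with
#' probability `noise_rate`. Indication cells are left noise-free so each
#' block indication keeps a column sum of `drugs_per_block` and the eligible
#' maskable-pair count stays at its closed form
#' `n_blocks * drugs_per_block * round(phenos_per_block * indication_fraction)`
#' (for `drugs_per_block >= 2`). The true `theta` is the one-hot block
#' membership and the true `phi` is uniform over each block's phenotypes.
#'
#' @param n_blocks,drugs_per_block,phenos_per_block positive counts.
#' @param indication_fraction fraction of each block's phenotypes labelled
#'   as indications (rounded to a count).
#' @param noise_rate side-effect bit-flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a `synthetic_phenome` (with an empty `planted` set).
#' @export
make_block_fixture <- function(n_blocks = 3L, drugs_per_block = 20L,
                               phenos_per_block = 30L,
                               indication_fraction = 0.3,
                               noise_rate = 0.05, seed = 1L) {
  stopifnot(
    n_blocks >= 1L, drugs_per_block >= 1L, phenos_per_block >= 1L,
    indication_fraction >= 0, indication_fraction <= 1,
    noise_rate >= 0, noise_rate < 0.5
  )
  set.seed(as.integer(seed))
  n_ind_pb <- round(phenos_per_block * indication_fraction)
  n_se_pb <- phenos_per_block - n_ind_pb
  M <- n_blocks * drugs_per_block
  V <- n_blocks * phenos_per_block

  drugs <- sprintf("d%03d", seq_len(M))
  block_of_drug <- rep(seq_len(n_blocks), each = drugs_per_block)
  se_terms <- ind_terms <- character(0)
  se_block <- ind_block <- integer(0)
  for (b in seq_len(n_blocks)) {
    se_terms <- c(se_terms, sprintf("b%02d_se%03d", b, seq_len(n_se_pb)))
    ind_terms <- c(ind_terms, sprintf("b%02d_ind%03d", b, seq_len(n_ind_pb)))
    se_block <- c(se_block, rep(b, n_se_pb))
    ind_block <- c(ind_block, rep(b, n_ind_pb))
  }
  terms <- c(se_terms, ind_terms)
  classes <- rep(c("side_effect", "indication"),
                 c(length(se_terms), length(ind_terms)))
  block_of_term <- c(se_block, ind_block)

  binary <- matrix(0, M, V, dimnames = list(drugs, terms))
  for (d in seq_len(M)) binary[d, block_of_term == block_of_drug[d]] <- 1

  if (noise_rate > 0 && length(se_terms) > 0) {
    se_cols <- seq_along(se_terms)
    flips <- matrix(stats::runif(M * length(se_cols)) < noise_rate,
                    M, length(se_cols))
    binary[, se_cols] <- ifelse(flips, 1 - binary[, se_cols],
                                binary[, se_cols])
  }

  theta <- matrix(0, M, n_blocks,
                  dimnames = list(drugs, paste0("topic", seq_len(n_blocks))))
  theta[cbind(seq_len(M), block_of_drug)] <- 1
  phi <- matrix(0, n_blocks, V,
                dimnames = list(paste0("topic", seq_len(n_blocks)), terms))
  for (b in seq_len(n_blocks)) {
    phi[b, block_of_term == b] <- 1 / phenos_per_block
  }

  structure(
    list(
      matrix = new_phenome_matrix(binary, classes),
      theta = theta, phi = phi, counts = binary,
      planted = tibble(drug_id = character(), term_id = character(),
                       probability = numeric()),
      spec = list(
        n_blocks = n_blocks, drugs_per_block = drugs_per_block,
        phenos_per_block = phenos_per_block,
        indication_fraction = indication_fraction,
        noise_rate = noise_rate, seed = as.integer(seed)
      )
    ),
    class = "synthetic_phenome"
  )
}

#' @export
print.synthetic_phenome <- function(x, ...) {
  g <- generics::glance(x$matrix)
  cat("<synthetic_phenome> ", g$n_drugs, " drugs x ", g$n_phenotypes,
      " phenotypes, ", nrow(x$planted), " planted held-out link(s)\n",
      sep = "")
  invisible(x)
}
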