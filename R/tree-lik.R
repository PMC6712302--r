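#' Amino-acid substitution model for likelihood computations
#'
#' Builds a time-reversible 20-state model from an exchangeability matrix
#' and equilibrium frequencies, scaled so branch lengths are expected
#' substitutions per site. The default is the Poisson model (equal
#' exchangeabilities, uniform frequencies), which is sufficient for the
#' rank-order likelihood differences the topology tests consume; any custom
#' matrix (e.g. LG) can be supplied. Optional discrete-Gamma rate variation
#' uses `gamma_categories` equal-weight classes with mean rates computed
#' from the Gamma quantile bins.
#'
#' @param exchangeabilities Symmetric 20x20 matrix of exchangeabilities
#'   (diagonal ignored); default all-equal (Poisson).
#' @param freqs Equilibrium frequencies (length 20, summing to 1); default
#'   uniform.
#' @param gamma_categories Number of discrete Gamma rate classes (1 = no
#'   rate variation).
#' @param gamma_shape Gamma shape parameter alpha (used when
#'   `gamma_categories > 1`).
#' @return Object of class `subst_model`.
#' @export
subst_model <- function(exchangeabilities = NULL, freqs = NULL,
                        gamma_categories = 1L, gamma_shape = 1) {
  k <- 20L
  if (is.null(exchangeabilities)) {
    exchangeabilities <- matrix(1, k, k)
  }
  stopifnot(nrow(exchangeabilities) == k, ncol(exchangeabilities) == k)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  stopifnot(length(freqs) == k, abs(sum(freqs) - 1) < 1e-8, all(freqs > 0))
  R <- (exchangeabilities + t(exchangeabilities)) / 2
  diag(R) <- 0
  Q <- R * rep(freqs, each = k)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))  # expected substitutions per unit time
  Q <- Q / mu
  # symmetrized eigendecomposition for numerical stability
  d_half <- sqrt(freqs)
  B <- diag(d_half) %*% Q %*% diag(1 / d_half)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  rates <- if (gamma_categories > 1L) {
    discrete_gamma_rates(gamma_shape, gamma_categories)
  } else {
    1
  }
  structure(
    list(freqs = freqs, values = eig$values,
         vectors_left = diag(1 / d_half) %*% eig$vectors,
         vectors_right = t(eig$vectors) %*% diag(d_half),
         rates = rates),
    class = "subst_model"
  )
}

# Mean rate of each equal-probability Gamma(alpha, alpha) bin.
discrete_gamma_rates <- function(alpha, k) {
  edges <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  means <- diff(pgamma(edges, shape = alpha + 1, rate = alpha)) * k
  means / mean(means)  # normalize mean rate to 1
}

transition_matrix <- function(model, t) {
  e <- exp(model$values * t)
  P <- model$vectors_left %*% (e * model$vectors_right)
  P[P < 0] <- 0
  P
}

#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Felsenstein pruning over the 20 amino-acid states. The tree's branch
#' lengths are used as given (no optimization); unrooted trees are handled
#' by treating their basal multifurcation as the root, which is valid for
#' any reversible model. Gaps and non-standard residues are treated as
#' missing data. With discrete-Gamma rate classes the per-site likelihood
#' is the equal-weight mixture across classes.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths), or a character matrix with rownames.
#' @param tree An [ape::phylo]; leaf set must equal the alignment's names.
#' @param model A [subst_model()].
#' @return Numeric vector of per-site log-likelihoods; their sum is the
#'   tree's total log-likelihood.
#' @examples
#' aln <- c(a = "ACDE", b = "ACDF")
#' tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
#' sum(site_loglik(aln, tr, subst_model()))
#' @export
site_loglik <- function(alignment, tree, model = subst_model()) {
  mat <- alignment_matrix(alignment)
  tips <- tree$tip.label
  if (!setequal(rownames(mat), tips)) {
    stop(sprintf(
      "alignment/tree leaf mismatch; only in alignment: %s; only in tree: %s",
      paste(setdiff(rownames(mat), tips), collapse = ","),
      paste(setdiff(tips, rownames(mat)), collapse = ",")), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  nsite <- ncol(mat)
  ntip <- length(tips)
  states <- matrix(match(mat, AA_ALPHABET), nrow(mat), nsite)
  rownames(states) <- rownames(mat)

  per_rate <- lapply(model$rates, function(r) {
    pruning_loglik(tree, states[tips, , drop = FALSE], model, rate = r)
  })
  if (length(per_rate) == 1L) {
    return(per_rate[[1]])
  }
  # equal-weight mixture, computed in log space
  m <- do.call(rbind, per_rate)
  mx <- apply(m, 2, max)
  mx + log(colMeans(exp(sweep(m, 2, mx))))
}

pruning_loglik <- function(tree, states, model, rate = 1) {
  ntip <- nrow(states)
  nsite <- ncol(states)
  nnode <- ntip + tree$Nnode
  ord <- reorder(tree, "postorder")
  partial <- vector("list", nnode)
  scaler <- numeric(nsite)
  for (i in seq_len(ntip)) {
    L <- matrix(0, nsite, 20)
    s <- states[i, ]
    known <- !is.na(s)
    L[cbind(which(known), s[known])] <- 1
    L[!known, ] <- 1
    partial[[i]] <- L
  }
  visited <- logical(nnode)
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    P <- transition_matrix(model, rate * ord$edge.length[k])
    contrib <- partial[[child]] %*% t(P)
    if (!visited[parent]) {
      partial[[parent]] <- contrib
      visited[parent] <- TRUE
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
    # rescale to avoid underflow on large trees
    mx <- pmax(matrixStats_rowMaxs(partial[[parent]]), 1e-300)
    partial[[parent]] <- partial[[parent]] / mx
    scaler <- scaler + log(mx)
  }
  root <- ord$edge[nrow(ord$edge), 1]
  log(as.vector(partial[[root]] %*% model$freqs)) + scaler
}

matrixStats_rowMaxs <- function(m) {
  do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
}

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) {
      stop("alignment matrix needs rownames", call. = FALSE)
    }
    return(alignment)
  }
  if (is.null(names(alignment))) {
    stop("alignment needs sequence names", call. = FALSE)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(unname(toupper(alignment)), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Per-site log-likelihood matrix across candidate topologies
#'
#' Convenience wrapper running [site_loglik()] for each tree; rows are
#' topologies, columns are sites — the input expected by [au_test()].
#'
#' @param alignment As in [site_loglik()].
#' @param trees A list of [ape::phylo] trees (names become rownames).
#' @param model A [subst_model()].
#' @return Matrix `[topology x site]` of per-site log-likelihoods.
#' @export
site_loglik_matrix <- function(alignment, trees, model = subst_model()) {
  rows <- lapply(trees, function(tr) site_loglik(alignment, tr, model))
  m <- do.call(rbind, rows)
  rownames(m) <- names(trees) %||% paste0("topology", seq_along(trees))
  m
}
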