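# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results with straightforward (often brute-force)
# code that shares no internals with the package implementation paths they
# check.

# ---- dense MCL reimplementation (same update rule, fixed iteration count) ----

oracle_mcl <- function(edges, nodes, inflation = 1.5, expansion = 2L,
                       iters = 200L) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$from[k], nodes)
      j <- match(edges$to[k], nodes)
      A[i, j] <- A[j, i] <- edges$weight[k]
    }
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (t in seq_len(iters)) {
    M2 <- M
    for (e in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M <- sweep(M2, 2, colSums(M2), "/")
    stopifnot(all(abs(colSums(M) - 1) < 1e-9))  # column stochasticity
  }
  supp <- (M > 1e-6) | t(M > 1e-6)
  diag(supp) <- TRUE
  comp <- rep(0L, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cl <- cl + 1L
      queue <- s
      comp[s] <- cl
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        nb <- which(supp[v, ] & comp == 0L)
        comp[nb] <- cl
        queue <- c(queue, nb)
      }
    }
  }
  canonical_partition(split(nodes, comp))
}

canonical_partition <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  unname(clusters[order(vapply(clusters, `[`, "", 1))])
}

families_partition <- function(fams) {
  canonical_partition(split(fams$membership$protein_id,
                            fams$membership$family_id))
}

build_graph_from_edges <- function(edges, nodes) {
  structure(list(edges = edges, nodes = nodes), class = "ortho_graph")
}

random_test_graph <- function(n, p = 0.25) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  nodes <- sprintf("n%02d", seq_len(n))
  tibble::tibble(
    from = nodes[pairs[, 1]],
    to = nodes[pairs[, 2]],
    weight = round(runif(nrow(pairs), 0.5, 10), 3)
  )
}

# ---- exhaustive-state-enumeration likelihood oracle ----

# Per-site log-likelihood by summing over every assignment of internal-node
# states; works on any (rooted or basal-multifurcating) ape tree with <= 5
# leaves. Poisson model with uniform frequencies.
oracle_site_loglik <- function(alignment, tree) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  mat <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  states <- matrix(match(mat, aa), nrow(mat), ncol(mat),
                   dimnames = list(rownames(mat), NULL))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internal <- ntip + seq_len(nnode)
  p_same <- function(t) 1 / 20 + (19 / 20) * exp(-20 / 19 * t)
  p_diff <- function(t) (1 / 20) * (1 - exp(-20 / 19 * t))
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  nsite <- ncol(states)
  out <- numeric(nsite)
  for (s in seq_len(nsite)) {
    state_of <- function(node, assign) {
      if (node <= ntip) states[tree$tip.label[node], s] else
        assign[node - ntip]
    }
    total <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      pr <- 1 / 20  # root state frequency
      for (e in seq_len(nrow(tree$edge))) {
        a <- state_of(tree$edge[e, 1], assign)
        b <- state_of(tree$edge[e, 2], assign)
        t <- tree$edge.length[e]
        pr <- pr * if (a == b) p_same(t) else p_diff(t)
      }
      total <- total + pr
    }
    out[s] <- log(total)
  }
  out
}

# ---- naive single-scale RELL bootstrap ----

oracle_rell_bp <- function(site_ll, nboot = 1000L, seed = 1L) {
  set.seed(seed)
  n <- ncol(site_ll)
  wins <- integer(nrow(site_ll))
  for (b in seq_len(nboot)) {
    idx <- sample.int(n, n, replace = TRUE)
    tot <- rowSums(site_ll[, idx, drop = FALSE])
    mx <- which(tot >= max(tot) - 1e-12)
    w <- if (length(mx) > 1L) sample(mx, 1L) else mx
    wins[w] <- wins[w] + 1L
  }
  wins / nboot
}

# ---- tree traversal oracles ----

# Stem/median-internal-branch ratio computed directly from the edge table.
oracle_stem_ratio <- function(phy, recipient_tips) {
  ntip <- length(phy$tip.label)
  m <- ape::getMRCA(phy, recipient_tips)
  stem <- which(phy$edge[, 2] == m)
  internal <- setdiff(which(phy$edge[, 2] > ntip), stem)
  phy$edge.length[stem] / stats::median(phy$edge.length[internal])
}

# Edge count on the root-to-leaf path of every tip.
oracle_leaf_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  parent <- function(x) phy$edge[phy$edge[, 2] == x, 1]
  vapply(seq_len(ntip), function(tp) {
    d <- 0L
    node <- tp
    repeat {
      p <- parent(node)
      if (length(p) == 0L) break
      d <- d + 1L
      node <- p
    }
    d
  }, integer(1))
}

# All bipartitions of an unrooted tree, as sets of tip labels (one side).
oracle_bipartitions <- function(phy) {
  un <- ape::unroot(phy)
  ntip <- length(un$tip.label)
  lapply(which(un$edge[, 2] > ntip), function(e) {
    node <- un$edge[e, 2]
    sort(un$tip.label[unlist(phangorn::Descendants(un, node, "tips"))])
  })
}

oracle_is_monophyletic <- function(phy, taxa) {
  taxa <- sort(unique(taxa))
  tips <- sort(phy$tip.label)
  if (identical(taxa, tips) || length(taxa) <= 1L) return(TRUE)
  comp <- sort(setdiff(tips, taxa))
  # sides defined by internal edges, plus trivial single-tip sides
  sides <- c(oracle_bipartitions(phy),
             lapply(phy$tip.label, identity))
  any(vapply(sides, function(s) {
    identical(sort(s), taxa) || identical(sort(s), comp)
  }, logical(1)))
}

# ---- misc ----

random_aln <- function(tips, nsite, seed = 1) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  withr::with_seed(seed, {
    setNames(vapply(tips, function(t) {
      paste(sample(aa, nsite, TRUE), collapse = "")
    }, character(1)), tips)
  })
}

expected_label_for_class <- function(families) {
  dplyr::case_when(
    families$class == "shared" ~ "shared",
    families$class == "unique" ~ "unique_recipient",
    families$class == "lost" ~ "lost_recipient",
    families$class == "hgt" & families$fungal_homologs ~ "shared",
    TRUE ~ "unique_recipient"
  )
}

pair_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- min(length(av), length(bv))
  sum(av[seq_len(m)] == bv[seq_len(m)]) / m
}
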