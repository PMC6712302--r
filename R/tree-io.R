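#' Parse a Newick gene tree (supports-as-internal-labels dialect)
#'
#' Wraps [ape::read.tree()] with an explicit balance check (reporting the
#' character position of the first unbalanced parenthesis) and numeric
#' parsing of internal node labels as bootstrap-style supports. Polytomies
#' are preserved.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] tree; internal-node supports (if present) remain
#'   in `node.label`.
#' @export
parse_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readr::read_lines(x), collapse = "") else x
  depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                    (strsplit(txt, "")[[1]] == ")"))
  if (any(depth < 0)) {
    stop(sprintf("unbalanced parenthesis at position %d",
                 which(depth < 0)[1]), call. = FALSE)
  }
  if (length(depth) && depth[length(depth)] != 0) {
    stop("unbalanced parenthesis: unclosed '(' remains at end of input",
         call. = FALSE)
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  phy
}

node_support <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (is.null(phy$node.label)) return(NA_real_)
  lab <- phy$node.label[node - ntip]
  suppressWarnings(as.numeric(lab))
}

#' Test whether a taxon set is monophyletic (unrooted sense)
#'
#' TRUE iff the set is one side of some bipartition of the tree (the tree is
#' treated as unrooted, so the complement of a clade is also monophyletic).
#' Also reports the support value attached to the set's stem edge, if any.
#'
#' @param tree An [ape::phylo].
#' @param taxa Character vector of leaf labels.
#' @return List: `monophyletic` (logical), `support` (numeric or NA).
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) {
    stop(sprintf("unknown taxa: %s", paste(head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  taxa <- unique(taxa)
  if (setequal(taxa, tips) || length(taxa) == 0L) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  if (length(taxa) == 1L) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  out_tip <- setdiff(tips, taxa)[1]
  rt <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
  m <- ape::getMRCA(rt, taxa)
  desc <- rt$tip.label[unlist(phangorn::Descendants(rt, m, "tips"))]
  mono <- setequal(desc, taxa)
  list(
    monophyletic = mono,
    support = if (mono) node_support(rt, m) else NA_real_
  )
}

#' Sister lineage and donor hypothesis for a monophyletic clade
#'
#' Midpoint-roots an unrooted tree, locates the clade's stem, and reports
#' the leaves of the sibling subtree, their majority lineage group (the
#' donor hypothesis) and the stem support. The donor call requires stem
#' support of at least `support_threshold` (default 80); below it the donor
#' is `"unresolved"`. A tied majority gives `"ambiguous"`.
#'
#' @param tree An [ape::phylo] (gene tree; tip labels are protein ids).
#' @param clade_taxa Leaf labels of the (monophyletic) recipient clade.
#' @param groups Named character vector mapping every leaf label to a
#'   lineage group.
#' @param support_threshold Minimum stem support for a donor call; `NA`
#'   disables the check.
#' @return Tibble: `donor`, `support`, `n_sister`, `sister_groups`
#'   (semicolon-joined tally), `sister_taxa` (semicolon-joined labels).
#' @export
sister_lineage <- function(tree, clade_taxa, groups, support_threshold = 80) {
  mono <- is_monophyletic(tree, clade_taxa)
  if (!mono$monophyletic) {
    stop("clade is not monophyletic; see is_monophyletic()", call. = FALSE)
  }
  phy <- tree
  if (!ape::is.rooted(phy)) {
    phy <- phangorn::midpoint(phy)
  }
  tips <- phy$tip.label
  m <- ape::getMRCA(phy, clade_taxa)
  desc <- tips[unlist(phangorn::Descendants(phy, m, "tips"))]
  if (!setequal(desc, clade_taxa) || is.null(m)) {
    # clade spans the midpoint root; reroot on a leaf outside the clade
    phy <- ape::root(tree, outgroup = setdiff(tips, clade_taxa)[1],
                     resolve.root = TRUE)
    m <- ape::getMRCA(phy, clade_taxa)
  }
  parent <- phy$edge[phy$edge[, 2] == m, 1]
  if (length(parent) == 0L) {
    stop("clade covers the whole tree; no sister lineage", call. = FALSE)
  }
  siblings <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], m)
  ntip <- length(phy$tip.label)
  sister_tips <- phy$tip.label[unlist(lapply(siblings, function(s) {
    if (s <= ntip) s else unlist(phangorn::Descendants(phy, s, "tips"))
  }))]
  sg <- groups[sister_tips]
  tal <- sort(table(sg), decreasing = TRUE)
  support <- node_support(phy, m)
  donor <- if (length(tal) == 0L) {
    NA_character_
  } else if (length(tal) > 1L && tal[1] == tal[2]) {
    "ambiguous"
  } else {
    names(tal)[1]
  }
  if (!is.na(support_threshold) &&
      (is.na(support) || support < support_threshold)) {
    donor <- "unresolved"
  }
  tibble(
    donor = donor,
    support = support,
    n_sister = length(sister_tips),
    sister_groups = paste(sprintf("%s=%d", names(tal), tal), collapse = ";"),
    sister_taxa = paste(sister_tips, collapse = ";")
  )
}

#' Force a taxon group to be monophyletic by minimal regrafting
#'
#' Finds the maximal subtrees of non-group taxa that break the group's
#' monophyly, prunes them, and regrafts each onto the group's stem edge (so
#' the group becomes a clade with the intruders as its closest outside
#' relatives — the minimal rearrangement of the original placement). When an
#' alignment is supplied, the length of each regrafted branch is
#' re-optimized by a golden-section line search on the total log-likelihood
#' (tolerance 1e-4); other branch lengths are untouched.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param group_taxa Leaf labels to force into one clade.
#' @param alignment Optional named character vector of aligned sequences
#'   (names = leaf labels) used to re-optimize moved branch lengths.
#' @param model A [subst_model()] (default Poisson) for the re-optimization.
#' @return The constrained tree. If the group is already monophyletic the
#'   input is returned unchanged with a message.
#' @export
constrain_monophyly <- function(tree, group_taxa, alignment = NULL,
                                model = subst_model()) {
  mono <- is_monophyletic(tree, group_taxa)
  if (mono$monophyletic) {
    message("group is already monophyletic; returning tree unchanged")
    return(tree)
  }
  phy <- tree
  if (!ape::is.rooted(phy)) {
    phy <- ape::root(phy, outgroup = setdiff(phy$tip.label, group_taxa)[1],
                     resolve.root = TRUE)
  }
  phy$node.label <- NULL
  repeat {
    m <- ape::getMRCA(phy, group_taxa)
    desc <- phy$tip.label[unlist(phangorn::Descendants(phy, m, "tips"))]
    intruders <- setdiff(desc, group_taxa)
    if (length(intruders) == 0L) break
    block <- max_intruder_clade(phy, m, intruders)
    phy <- move_to_stem(phy, block, group_taxa)
  }
  if (!is.null(alignment)) {
    phy <- optimize_grafted_edges(phy, group_taxa, alignment, model)
  }
  phy
}

# Tips of one maximal pure-intruder subtree under `m` (deterministic: the
# one containing the alphabetically first intruder).
max_intruder_clade <- function(phy, m, intruders) {
  tip <- sort(intruders)[1]
  node <- match(tip, phy$tip.label)
  best <- node
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(parent) == 0L || parent == m) break
    tips_above <- phy$tip.label[unlist(phangorn::Descendants(phy, parent, "tips"))]
    if (!all(tips_above %in% intruders)) break
    best <- parent
    node <- parent
  }
  ntip <- length(phy$tip.label)
  if (best <= ntip) {
    phy$tip.label[best]
  } else {
    phy$tip.label[unlist(phangorn::Descendants(phy, best, "tips"))]
  }
}

GRAFT_EDGE_LENGTH <- 0.05

# Prune `block` tips and regraft them as one subtree onto the stem edge of
# `group_taxa`.
move_to_stem <- function(phy, block, group_taxa) {
  sub <- if (length(block) == 1L) {
    ape::read.tree(text = sprintf("(%s:%s);", block, format_bl(GRAFT_EDGE_LENGTH)))
  } else {
    s <- ape::keep.tip(phy, block)
    s$root.edge <- GRAFT_EDGE_LENGTH
    s
  }
  if (length(block) == 1L) sub$root.edge <- GRAFT_EDGE_LENGTH
  rest <- ape::drop.tip(phy, block)
  m <- ape::getMRCA(rest, group_taxa)
  if (is.null(m)) stop("cannot locate group stem after pruning", call. = FALSE)
  stem_idx <- which(rest$edge[, 2] == m)
  if (length(stem_idx) == 0L) {
    # group clade is at the root: attach the subtree at the root instead
    return(ape::bind.tree(rest, sub, where = m))
  }
  pos <- rest$edge.length[stem_idx] / 2
  ape::bind.tree(rest, sub, where = m, position = pos)
}

# Golden-section search re-optimizing the lengths of edges created by
# regrafting (identified as edges of length GRAFT_EDGE_LENGTH above a node
# that is not in the original tree is impractical; instead re-optimize the
# stem edge of the group and every edge incident to its parent node).
optimize_grafted_edges <- function(phy, group_taxa, alignment, model) {
  m <- ape::getMRCA(phy, group_taxa)
  parent <- phy$edge[phy$edge[, 2] == m, 1]
  if (length(parent) == 0L) return(phy)
  edges <- which(phy$edge[, 1] == parent | phy$edge[, 2] == parent)
  for (e in edges) {
    f <- function(len) {
      p2 <- phy
      p2$edge.length[e] <- len
      sum(site_loglik(alignment, p2, model))
    }
    phy$edge.length[e] <- golden_section(f, 1e-8, 5, tol = 1e-4)
  }
  phy
}

# Maximize f on [lo, hi] by golden-section search.
golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (abs(b - a) > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' Neighbor-joining gene tree with bootstrap supports
#'
#' Builds an unrooted NJ tree from Poisson-corrected pairwise distances of a
#' protein alignment and attaches nonparametric bootstrap supports (site
#' resampling, NJ on each replicate) as internal node labels (percent).
#'
#' @param alignment Named character vector of aligned protein sequences.
#' @param nboot Bootstrap replicates (default 100).
#' @param seed Integer seed for resampling.
#' @return An [ape::phylo] with `node.label` percent supports.
#' @export
infer_gene_tree <- function(alignment, nboot = 100L, seed = 1L) {
  if (length(alignment) < 4L) {
    stop("need at least 4 sequences for a meaningful gene tree", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  tr <- ape::nj(dist_poisson(mat))
  with_seed(seed, {
    boots <- lapply(seq_len(nboot), function(b) {
      idx <- sample.int(ncol(mat), replace = TRUE)
      ape::nj(dist_poisson(mat[, idx, drop = FALSE]))
    })
    counts <- ape::prop.clades(tr, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tr$node.label <- as.character(round(100 * counts / nboot))
    tr
  })
}

# Poisson-corrected protein distance: d = -(19/20) log(1 - (20/19) p).
dist_poisson <- function(mat) {
  n <- nrow(mat)
  p <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pij <- mean(mat[i, ] != mat[j, ])
      pij <- min(pij, 0.94)  # cap below saturation (p = 19/20)
      d <- -(19 / 20) * log(1 - (20 / 19) * pij)
      p[i, j] <- p[j, i] <- d
    }
  }
  stats::as.dist(p)
}
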