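#' Simulate the backbone species tree for a synthetic dataset
#'
#' Builds a rooted binary species tree in which the recipient taxa form a
#' single clade attached by a long stem branch (at least five times the median
#' internal branch length), sister to the outgroup clade; other fungi attach
#' next, and candidate donor groups (bacteria, animal, plant, ...) attach on
#' the far side of the root. Within-group topologies are random (seeded);
#' backbone depths are fixed so that within-kingdom protein identities stay
#' well above, and cross-kingdom identities well below, the similarity-search
#' reporting floor — mirroring real inter-kingdom divergence.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `species_tree`: a list with `phylo` (an
#'   [ape::phylo]), `lineage` (tibble: `taxon_id`, `group`), and `newick`.
#' @examples
#' tr <- simulate_species_tree(sim_config(n_recipient_taxa = 4,
#'                                        n_outgroup_taxa = 2, seed = 1))
#' tr$phylo$Nnode
#' @export
simulate_species_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lineage <- config_lineage(cfg)
  with_seed(derive_seed(cfg$seed, 101L), {
    grp <- split(lineage$taxon_id, lineage$group)

    sub <- function(labels) random_subtree_newick(labels, 0.01, 0.04)

    rec <- paste0(sub(grp$recipient), ":", format_bl(0.25))
    out <- paste0(sub(grp$outgroup), ":", format_bl(0.05))
    fungal <- if (!is.null(grp$other_fungi)) {
      sprintf("((%s,%s):%s,%s:%s)", rec, out, format_bl(0.03),
              sub(grp$other_fungi), format_bl(0.10))
    } else {
      sprintf("(%s,%s)", rec, out)
    }
    donor_stems <- c(bacteria = 0.35, animal = 0.20, plant = 0.20,
                     archaea = 0.40, protist = 0.25)
    donors <- intersect(names(donor_stems), names(grp))
    if (length(donors) > 0L) {
      parts <- vapply(donors, function(g) {
        paste0(sub(grp[[g]]), ":", format_bl(donor_stems[[g]]))
      }, character(1))
      nonf <- parts[[1L]]
      for (p in parts[-1L]) {
        nonf <- sprintf("(%s,%s):%s", nonf, p, format_bl(0.05))
      }
      newick <- sprintf("(%s:%s,%s:%s);", fungal, format_bl(0.80),
                        nonf, format_bl(0.80))
    } else {
      newick <- paste0(fungal, ";")
    }

    phy <- ape::read.tree(text = newick)
    phy <- adjust_recipient_stem(phy, grp$recipient)
    newick <- ape::write.tree(phy)
    structure(
      list(phylo = phy, lineage = lineage, newick = newick),
      class = "species_tree"
    )
  })
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d taxa (%s)\n",
              length(x$phylo$tip.label),
              paste(sprintf("%d %s", table(x$lineage$group)[unique(x$lineage$group)],
                            unique(x$lineage$group)), collapse = ", ")))
  invisible(x)
}

format_bl <- function(x) sprintf("%.6f", x)

# Random rooted binary topology over `labels` by recursive random bipartition;
# every edge gets an independent U(lo, hi) length.
random_subtree_newick <- function(labels, lo, hi) {
  n <- length(labels)
  if (n == 1L) return(labels)
  if (n == 2L) {
    pick <- sample.int(2L)
    return(sprintf("(%s:%s,%s:%s)",
                   labels[pick[1]], format_bl(runif(1, lo, hi)),
                   labels[pick[2]], format_bl(runif(1, lo, hi))))
  }
  k <- sample.int(n - 1L, 1L)
  idx <- sample.int(n)
  left <- labels[idx[seq_len(k)]]
  right <- labels[idx[(k + 1L):n]]
  sprintf("(%s:%s,%s:%s)",
          random_subtree_newick(left, lo, hi), format_bl(runif(1, lo, hi)),
          random_subtree_newick(right, lo, hi), format_bl(runif(1, lo, hi)))
}

# Ensure the recipient stem is >= 5x the median of the other internal branch
# lengths (lengthening it if a small tree makes the backbone edges dominate).
adjust_recipient_stem <- function(phy, recipient_tips) {
  stem <- recipient_stem_edge(phy, recipient_tips)
  ntip <- length(phy$tip.label)
  internal <- which(phy$edge[, 2] > ntip)
  internal <- setdiff(internal, stem)
  med <- if (length(internal)) median(phy$edge.length[internal]) else 0.02
  phy$edge.length[stem] <- max(0.25, 5.5 * med)
  phy
}

# Index (into phy$edge) of the edge subtending exactly the recipient tips.
recipient_stem_edge <- function(phy, recipient_tips) {
  ntip <- length(phy$tip.label)
  mrca <- if (length(recipient_tips) == 1L) {
    match(recipient_tips, phy$tip.label)
  } else {
    ape::getMRCA(phy, recipient_tips)
  }
  desc <- unlist(phangorn::Descendants(phy, mrca, type = "tips"))
  if (!setequal(phy$tip.label[desc], recipient_tips)) {
    stop("recipient taxa are not monophyletic in the species tree", call. = FALSE)
  }
  which(phy$edge[, 2] == mrca)
}
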