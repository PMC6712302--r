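#' Simulate protein sequences for one gene family
#'
#' Sequences evolve along the family's gene tree under a Poisson (equal
#' exchangeabilities, uniform frequencies) substitution model: on a branch of
#' length `t` (expected substitutions/site) each site is hit by an event with
#' probability `1 - exp(-20/19 t)` and then redrawn uniformly from the 20
#' amino acids. Vertical families use the species tree restricted to the taxa
#' carrying the family; transferred families use a gene tree in which the
#' recipient clade attaches inside the donor lineage (with any fungal
#' homologs on a distant branch), so donor sequences are the most similar to
#' the recipient copies. Redundant transcript variants are point-mutated
#' copies of their parent (at most 10% of sites, guaranteeing >90% identity);
#' fusion proteins carry an extra 3' segment holding the native partner
#' domain.
#'
#' @param tree A [simulate_species_tree()] result.
#' @param fam An [evolve_families()] result.
#' @param family_id Family identifier (e.g. `"FAM0001"`).
#' @param cfg The [sim_config()].
#' @param seed Optional integer overriding the seed derived from
#'   `cfg$seed` and the family index.
#' @return List with `sequences` (tibble: `protein_id`, `sequence` for every
#'   gene of the family, variants and fusion segments included) and
#'   `alignment` (named character vector of core-region sequences, one per
#'   non-variant gene; co-linear, so directly usable as an alignment).
#' @examples
#' cfg <- sim_config(n_recipient_taxa = 4, n_outgroup_taxa = 2,
#'                   n_families = 4, seed = 1)
#' tr <- simulate_species_tree(cfg)
#' fam <- evolve_families(tr, cfg)
#' sq <- evolve_sequences(tr, fam, "FAM0001", cfg)
#' nchar(sq$alignment[[1]])
#' @export
evolve_sequences <- function(tree, fam, family_id, cfg, seed = NULL) {
  stopifnot(inherits(tree, "species_tree"), inherits(fam, "synth_families"))
  famrow <- fam$ledger$families[fam$ledger$families$family_id == family_id, ]
  if (nrow(famrow) != 1L) {
    stop(sprintf("unknown family `%s`", family_id), call. = FALSE)
  }
  genes <- fam$genes[fam$genes$family_id == family_id, ]
  if (nrow(genes) == 0L) {
    stop(sprintf("family `%s` is present in no taxon", family_id), call. = FALSE)
  }
  fidx <- match(family_id, fam$ledger$families$family_id)
  seed <- seed %||% derive_seed(cfg$seed, 1000L + fidx)
  with_seed(seed, {
    gtree <- family_gene_tree(tree, famrow, genes, cfg)
    core <- simulate_core_sequences(gtree, cfg$seq_length)

    base <- genes[!genes$is_variant, ]
    aln <- setNames(core[base$taxon_id], base$protein_id)

    seqs <- setNames(core[genes$taxon_id], genes$protein_id)
    vari <- which(genes$is_variant)
    for (i in vari) {
      seqs[[i]] <- mutate_variant(seqs[[i]], cfg$seq_length)
    }
    # 3' fusion segment for proteins whose true architecture has two domains
    arch <- fam$ledger$architectures
    fused <- unique(arch$protein_id[arch$start > 1L])
    for (i in which(genes$protein_id %in% fused)) {
      seqs[[i]] <- paste0(seqs[[i]], random_aa_string(FUSION_DOMAIN_LEN))
    }
    list(
      sequences = tibble(protein_id = genes$protein_id,
                         sequence = unname(seqs)),
      alignment = aln
    )
  })
}

# Gene tree (ape phylo) for one family; tips are taxon ids.
family_gene_tree <- function(tree, famrow, genes, cfg) {
  taxa <- unique(genes$taxon_id[!genes$is_variant])
  phy <- tree$phylo
  if (famrow$class != "hgt") {
    return(induced_subtree(phy, taxa))
  }
  lineage <- tree$lineage
  grp <- setNames(lineage$group, lineage$taxon_id)
  donor_taxa <- taxa[grp[taxa] == famrow$donor_group]
  rec_taxa <- taxa[grp[taxa] == "recipient"]
  fungal_taxa <- taxa[grp[taxa] %in% c("outgroup", "other_fungi")]
  rec_part <- part_newick(phy, rec_taxa, scale = 0.3)
  core <- if (length(donor_taxa) == 0L && is.null(rec_part)) {
    NULL
  } else if (length(donor_taxa) == 0L) {
    rec_part  # donors all lost by chance: recipient clade alone
  } else if (is.null(rec_part)) {
    part_newick(phy, donor_taxa)
  } else if (length(donor_taxa) >= 2L && length(rec_taxa) >= 2L) {
    # transferred copies nest INSIDE the donor clade, sister to one donor
    # leaf (the "closest relative"), leaving the donor group paraphyletic
    nested_donor_newick(phy, donor_taxa, rec_part)
  } else {
    sprintf("(%s:%s,%s:%s)", part_newick(phy, donor_taxa), format_bl(0.03),
            rec_part, format_bl(0.06))
  }
  if (is.null(core)) {
    return(induced_subtree(phy, fungal_taxa))
  }
  txt <- if (length(fungal_taxa) == 0L) {
    if (length(donor_taxa) == 0L && length(rec_taxa) == 1L) {
      sprintf("(%s:0.0);", core)
    } else {
      paste0(core, ";")
    }
  } else {
    sprintf("(%s:%s,%s:%s);", core, format_bl(0.18),
            part_newick(phy, fungal_taxa), format_bl(0.18))
  }
  ape::read.tree(text = txt)
}

# Donor subtree with the recipient subclade grafted onto a randomly chosen
# donor leaf's pendant edge (seeded), so donors are paraphyletic with
# respect to the transferred copies.
nested_donor_newick <- function(phy, donor_taxa, rec_part) {
  host <- sample(donor_taxa, 1L)
  # donor divergences kept deep (x2) so the nesting is recoverable from
  # sequence distances
  donor_part <- part_newick(phy, donor_taxa, scale = 2)
  host_pat <- paste0(host, ":")
  # split the host pendant edge and insert the recipient clade
  repl <- sprintf("(%s:%s,%s:%s):", host, format_bl(0.015),
                  rec_part, format_bl(0.06))
  sub(host_pat, repl, donor_part, fixed = TRUE)
}

# keep.tip() that also works for 1-2 tips; returns NULL for 0 tips.
part_newick <- function(phy, tips, scale = 1) {
  if (length(tips) == 0L) return(NULL)
  if (length(tips) == 1L) return(tips)
  if (length(tips) == 2L) {
    return(sprintf("(%s:%s,%s:%s)", tips[1], format_bl(0.02 * scale),
                   tips[2], format_bl(0.02 * scale)))
  }
  sub <- ape::keep.tip(phy, tips)
  sub$edge.length <- sub$edge.length * scale
  sub$node.label <- NULL
  sub("; *$", "", ape::write.tree(sub))
}

induced_subtree <- function(phy, tips) {
  if (length(tips) == 1L) {
    return(ape::read.tree(text = sprintf("(%s:0.0);", tips)))
  }
  if (length(tips) == 2L) {
    return(ape::read.tree(text = sprintf("(%s:0.02,%s:0.02);", tips[1], tips[2])))
  }
  ape::keep.tip(phy, tips)
}

# Poisson-model simulation along a rooted tree; returns named character
# vector of tip sequences (taxon -> AA string).
simulate_core_sequences <- function(phy, len) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ord <- reorder(phy, "cladewise")
  root <- ntip + 1L
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(20L, len, replace = TRUE)
  rate <- 20 / 19
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]
    ch <- ord$edge[k, 2]
    t <- ord$edge.length[k]
    s <- seqs[[p]]
    hit <- runif(len) < (1 - exp(-rate * t))
    if (any(hit)) s[hit] <- sample.int(20L, sum(hit), replace = TRUE)
    seqs[[ch]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) {
    paste(AA_ALPHABET[seqs[[i]]], collapse = "")
  }, character(1))
  setNames(out, phy$tip.label)
}

# Point-mutate strictly fewer than 10% of the first `core_len` sites.
mutate_variant <- function(seq, core_len) {
  max_mut <- ceiling(0.1 * core_len) - 1L
  k <- sample.int(max_mut + 1L, 1L) - 1L
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(core_len, k)
  chars[pos] <- AA_ALPHABET[sample.int(20L, k, replace = TRUE)]
  paste(chars, collapse = "")
}

random_aa_string <- function(len) {
  paste(AA_ALPHABET[sample.int(20L, len, replace = TRUE)], collapse = "")
}
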