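#' Evolve gene families on the species tree and record the truth ledger
#'
#' Each family gets an origin branch and a presence pattern over taxa.
#' Background families originate at the root (or, with probability
#' `family_birth_rate`, on a random internal branch). Planted
#' recipient-unique families originate on the recipient stem; planted lost
#' families originate at the root and are killed on the recipient stem;
#' planted transfers originate in a donor group and copy into the recipient
#' stem (optionally with distant homologs retained in the non-recipient
#' fungi, so presence/absence alone cannot reveal them). Losses then thin the
#' pattern according to `cfg$loss_model`: per-taxon dropout (default,
#' emulating assembly incompleteness) or per-branch subtree loss (classical
#' phylogenetic loss, leaf survival `(1 - loss_rate)^depth`).
#'
#' @param tree A [simulate_species_tree()] result.
#' @param cfg The [sim_config()] used to build `tree`.
#' @return An object of class `synth_families`: list with `genes` (tibble:
#'   `protein_id`, `taxon_id`, `group`, `family_id`, `is_variant`) and
#'   `ledger` (class `truth_ledger`: `families` and `architectures` tibbles).
#' @examples
#' cfg <- sim_config(n_recipient_taxa = 4, n_outgroup_taxa = 2,
#'                   n_families = 10, n_planted_unique_domains = 2, seed = 1)
#' fam <- evolve_families(simulate_species_tree(cfg), cfg)
#' dplyr::count(fam$ledger$families, class)
#' @export
evolve_families <- function(tree, cfg) {
  stopifnot(inherits(tree, "species_tree"), inherits(cfg, "sim_config"))
  lineage <- tree$lineage
  if (!setequal(tree$phylo$tip.label, lineage$taxon_id)) {
    stop("tree leaves do not cover the configured taxa", call. = FALSE)
  }
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  grp <- split(lineage$taxon_id, lineage$group)
  donor_groups <- intersect(c("bacteria", "animal", "plant", "archaea", "protist"),
                            names(grp))
  fungal_nonrec <- c(grp$outgroup, grp$other_fungi)

  with_seed(derive_seed(cfg$seed, 202L), {
    n <- cfg$n_families
    classes <- rep("shared", n)
    idx <- 0L
    take <- function(k) {
      out <- idx + seq_len(k)
      idx <<- idx + k
      out
    }
    uniq_ids <- take(cfg$n_planted_unique_domains)
    lost_ids <- take(cfg$n_planted_lost_domains)
    hgt_ids <- take(cfg$n_planted_hgt)
    classes[uniq_ids] <- "unique"
    classes[lost_ids] <- "lost"
    classes[hgt_ids] <- "hgt"

    fam_id <- sprintf("FAM%04d", seq_len(n))
    domain <- sprintf("PF_SYN%04d", seq_len(n))
    donor <- rep(NA_character_, n)
    if (length(hgt_ids)) {
      donor[hgt_ids] <- rep_len(donor_groups, length(hgt_ids))
    }
    fungal_hom <- rep(FALSE, n)
    if (length(hgt_ids)) {
      fungal_hom[hgt_ids] <- runif(length(hgt_ids)) < cfg$hgt_fungal_homolog_frac
    }

    # presence pattern before loss, per family: list of taxon vectors
    all_taxa <- lineage$taxon_id
    nonrec <- setdiff(all_taxa, grp$recipient)
    internal_edges <- which(phy$edge[, 2] > ntip)
    origin <- rep("root", n)
    base_present <- vector("list", n)
    for (i in seq_len(n)) {
      base_present[[i]] <- switch(
        classes[i],
        shared = {
          if (cfg$family_birth_rate > 0 && runif(1) < cfg$family_birth_rate) {
            e <- sample(internal_edges, 1L)
            origin[i] <- sprintf("edge%d", e)
            tips <- unlist(phangorn::Descendants(phy, phy$edge[e, 2], "tips"))
            phy$tip.label[tips]
          } else {
            all_taxa
          }
        },
        unique = {
          origin[i] <- "recipient_stem"
          grp$recipient
        },
        lost = {
          origin[i] <- "root_minus_recipient"
          nonrec
        },
        hgt = {
          origin[i] <- paste0("donor_", donor[i])
          c(grp[[donor[i]]], grp$recipient,
            if (fungal_hom[i]) fungal_nonrec)
        }
      )
    }

    present <- apply_loss(phy, base_present, cfg)

    families <- tibble(
      family_id = fam_id,
      class = classes,
      origin = origin,
      donor_group = donor,
      fungal_homologs = fungal_hom,
      domain = domain,
      fusion_partner_domain = NA_character_
    )

    # choose a native fusion-partner domain (from a shared family) per transfer
    shared_pool <- fam_id[classes == "shared"]
    if (length(hgt_ids) && cfg$fusion_rate > 0 && length(shared_pool)) {
      partner_fam <- sample(shared_pool, length(hgt_ids), replace = TRUE)
      families$fusion_partner_domain[hgt_ids] <-
        families$domain[match(partner_fam, families$family_id)]
    }

    genes <- build_genes(families, present, lineage, grp, cfg)
    arch <- build_architectures(genes, families, cfg)

    structure(
      list(
        genes = genes,
        ledger = structure(list(families = families, architectures = arch),
                           class = "truth_ledger")
      ),
      class = "synth_families"
    )
  })
}

# Thin presence patterns according to the configured loss model.
apply_loss <- function(phy, base_present, cfg) {
  n <- length(base_present)
  if (cfg$loss_rate == 0) return(base_present)
  if (cfg$loss_model == "taxon") {
    lapply(base_present, function(taxa) {
      taxa[runif(length(taxa)) >= cfg$loss_rate]
    })
  } else {
    ntip <- length(phy$tip.label)
    nedge <- nrow(phy$edge)
    # leaf survives iff no loss event on any edge of its root-to-leaf path
    paths <- lapply(seq_len(ntip), function(tp) {
      which(phy$edge[, 2] %in% c(tp, phangorn::Ancestors(phy, tp, "all")))
    })
    lapply(base_present, function(taxa) {
      lost_edge <- runif(nedge) < cfg$loss_rate
      tips <- match(taxa, phy$tip.label)
      keep <- !vapply(paths[tips], function(p) any(lost_edge[p]), logical(1))
      taxa[keep]
    })
  }
}

build_genes <- function(families, present, lineage, grp, cfg) {
  fam_rep <- rep.int(families$family_id, lengths(present))
  taxon <- unlist(present, use.names = FALSE)
  genes <- tibble(
    protein_id = paste0(taxon, "|", fam_rep, "|g1"),
    taxon_id = taxon,
    family_id = fam_rep,
    is_variant = FALSE
  )
  # redundant transcript variants: recipient copies only
  if (cfg$redundancy_rate > 0) {
    rec <- genes$taxon_id %in% grp$recipient
    dup <- rec & runif(nrow(genes)) < cfg$redundancy_rate
    if (any(dup)) {
      variants <- genes[dup, ]
      variants$protein_id <- sub("\\|g1$", "|g2", variants$protein_id)
      variants$is_variant <- TRUE
      genes <- bind_rows(genes, variants)
    }
  }
  genes <- left_join(genes, lineage, by = "taxon_id")
  genes <- arrange(genes, .data$family_id, .data$taxon_id, .data$protein_id)
  select(genes, "protein_id", "taxon_id", "group", "family_id", "is_variant")
}

FUSION_DOMAIN_LEN <- 100L

build_architectures <- function(genes, families, cfg) {
  fam <- families[match(genes$family_id, families$family_id), ]
  arch <- tibble(
    protein_id = genes$protein_id,
    domain = fam$domain,
    start = 1L,
    end = cfg$seq_length
  )
  fused <- fam$class == "hgt" & !is.na(fam$fusion_partner_domain) &
    genes$group == "recipient" & runif(nrow(genes)) < cfg$fusion_rate
  if (any(fused)) {
    extra <- tibble(
      protein_id = genes$protein_id[fused],
      domain = fam$fusion_partner_domain[fused],
      start = cfg$seq_length + 1L,
      end = cfg$seq_length + FUSION_DOMAIN_LEN
    )
    arch <- bind_rows(arch, extra)
  }
  arch <- arrange(arch, .data$protein_id, .data$start)
  arch
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d families (%s); %d domain instances\n",
              nrow(x$families),
              paste(sprintf("%d %s", table(x$families$class),
                            names(table(x$families$class))), collapse = ", "),
              nrow(x$architectures)))
  invisible(x)
}
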