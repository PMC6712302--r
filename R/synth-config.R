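#' Configuration for the synthetic comparative-genomics generator
#'
#' Bundles every knob of the synthetic dataset: taxon counts per lineage
#' group, gene-family birth/death behaviour, the number of planted
#' recipient-unique families, recipient-lost families and inter-kingdom
#' transfers, transcript-variant redundancy, and domain-fusion behaviour.
#' Defaults emulate the study conditions of a 26-recipient (anaerobic gut
#' fungi) / 5-outgroup (chytrid) comparison with bacterial, animal and plant
#' donor groups.
#'
#' @param n_recipient_taxa Number of recipient-lineage taxa (default 26).
#' @param n_outgroup_taxa Number of outgroup taxa (default 5).
#' @param n_other_fungi_taxa Number of additional non-recipient fungal taxa
#'   (default 3); these participate in the fungal side of the alien filter.
#' @param n_donor_taxa Named integer vector of taxon counts per candidate
#'   donor group; names drawn from `bacteria`, `animal`, `plant`, `archaea`,
#'   `protist`. Default: 4 each of bacteria, animal, plant.
#' @param n_families Total number of gene families to simulate.
#' @param family_birth_rate Probability that a background family originates on
#'   a non-root branch rather than at the root (in `[0,1]`). Families born on
#'   a branch exist only in the subtree below it.
#' @param loss_rate Loss probability in `[0,1]`; interpretation depends on
#'   `loss_model`.
#' @param loss_model `"taxon"` (default): each (family, taxon) copy is dropped
#'   independently with probability `loss_rate`, emulating per-assembly
#'   (especially transcriptome) incompleteness. `"subtree"`: classical
#'   phylogenetic loss — each branch below a family's origin suffers a loss
#'   event with probability `loss_rate`, silencing the whole descendant
#'   subtree, so a leaf keeps the family with probability
#'   `(1 - loss_rate)^depth`.
#' @param n_planted_hgt Number of planted horizontally transferred families.
#' @param n_planted_unique_domains Number of planted recipient-unique families
#'   (origin on the recipient stem).
#' @param n_planted_lost_domains Number of planted recipient-lost families
#'   (origin at the root, killed on the recipient stem).
#' @param hgt_fungal_homolog_frac Fraction of planted transfers that also have
#'   distant homologs in the non-recipient fungal taxa (so presence/absence
#'   alone cannot reveal them; the similarity screen still can).
#' @param redundancy_rate Probability that a recipient gene gains a
#'   near-identical (>90% identity) redundant transcript variant.
#' @param fusion_rate Probability that a recipient copy of a transferred
#'   family carries a 3' native-domain fusion.
#' @param decoy_rate Expected number of decoy domain rows (above the E-value
#'   analysis cutoff) per protein in the emitted domain table.
#' @param seq_length Protein length (columns) simulated per family.
#' @param seed Integer seed; identical configurations (including seed) yield
#'   byte-identical outputs.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_recipient_taxa = 4, n_outgroup_taxa = 2,
#'                   n_families = 20, seed = 1)
#' cfg$n_families
#' @export
sim_config <- function(n_recipient_taxa = 26L,
                       n_outgroup_taxa = 5L,
                       n_other_fungi_taxa = 3L,
                       n_donor_taxa = c(bacteria = 4L, animal = 4L, plant = 4L),
                       n_families = 100L,
                       family_birth_rate = 0,
                       loss_rate = 0,
                       loss_model = c("taxon", "subtree"),
                       n_planted_hgt = 0L,
                       n_planted_unique_domains = 0L,
                       n_planted_lost_domains = 0L,
                       hgt_fungal_homolog_frac = 0.5,
                       redundancy_rate = 0,
                       fusion_rate = 0,
                       decoy_rate = 0,
                       seq_length = 120L,
                       seed = 1L) {
  loss_model <- match.arg(loss_model)
  chk_count <- function(x, field, min = 0L) {
    if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
      stop_config(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_prob <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop_config(field, "must be a probability in [0, 1]")
    }
  }
  chk_count(n_recipient_taxa, "n_recipient_taxa", 2L)
  chk_count(n_outgroup_taxa, "n_outgroup_taxa", 2L)
  chk_count(n_other_fungi_taxa, "n_other_fungi_taxa", 0L)
  chk_count(n_families, "n_families", 1L)
  chk_count(n_planted_hgt, "n_planted_hgt")
  chk_count(n_planted_unique_domains, "n_planted_unique_domains")
  chk_count(n_planted_lost_domains, "n_planted_lost_domains")
  chk_count(seq_length, "seq_length", 30L)
  chk_prob(family_birth_rate, "family_birth_rate")
  chk_prob(loss_rate, "loss_rate")
  chk_prob(hgt_fungal_homolog_frac, "hgt_fungal_homolog_frac")
  chk_prob(redundancy_rate, "redundancy_rate")
  chk_prob(fusion_rate, "fusion_rate")
  if (decoy_rate < 0) stop_config("decoy_rate", "must be >= 0")
  if (length(n_donor_taxa)) {
    bad <- setdiff(names(n_donor_taxa),
                   c("bacteria", "animal", "plant", "archaea", "protist"))
    if (length(bad) || is.null(names(n_donor_taxa))) {
      stop_config("n_donor_taxa", "must be named with donor group labels")
    }
    for (g in names(n_donor_taxa)) chk_count(n_donor_taxa[[g]], paste0("n_donor_taxa$", g))
    n_donor_taxa <- n_donor_taxa[n_donor_taxa > 0]
  }
  n_planted <- n_planted_hgt + n_planted_unique_domains + n_planted_lost_domains
  if (n_planted > n_families) {
    stop_config("n_planted_hgt", paste(
      "+ n_planted_unique_domains + n_planted_lost_domains exceeds n_families"))
  }
  if (n_planted_hgt > 0L && length(n_donor_taxa) == 0L) {
    stop_config("n_donor_taxa", "must include at least one donor group when planting transfers")
  }
  chk_count(seed, "seed")
  structure(
    list(
      n_recipient_taxa = as.integer(n_recipient_taxa),
      n_outgroup_taxa = as.integer(n_outgroup_taxa),
      n_other_fungi_taxa = as.integer(n_other_fungi_taxa),
      n_donor_taxa = vapply(as.list(n_donor_taxa), as.integer, integer(1)),
      n_families = as.integer(n_families),
      family_birth_rate = family_birth_rate,
      loss_rate = loss_rate,
      loss_model = loss_model,
      n_planted_hgt = as.integer(n_planted_hgt),
      n_planted_unique_domains = as.integer(n_planted_unique_domains),
      n_planted_lost_domains = as.integer(n_planted_lost_domains),
      hgt_fungal_homolog_frac = hgt_fungal_homolog_frac,
      redundancy_rate = redundancy_rate,
      fusion_rate = fusion_rate,
      decoy_rate = decoy_rate,
      seq_length = as.integer(seq_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  taxa: %d recipient, %d outgroup, %d other fungi; donors: %s\n",
              x$n_recipient_taxa, x$n_outgroup_taxa, x$n_other_fungi_taxa,
              if (length(x$n_donor_taxa)) {
                paste(sprintf("%s=%d", names(x$n_donor_taxa), x$n_donor_taxa),
                      collapse = ", ")
              } else "none"))
  cat(sprintf("  families: %d (planted: %d hgt, %d unique, %d lost)\n",
              x$n_families, x$n_planted_hgt, x$n_planted_unique_domains,
              x$n_planted_lost_domains))
  cat(sprintf("  loss_rate: %g (%s), redundancy: %g, fusion: %g, seed: %d\n",
              x$loss_rate, x$loss_model, x$redundancy_rate, x$fusion_rate,
              x$seed))
  invisible(x)
}

# All taxon labels + group assignment implied by a config.
config_lineage <- function(cfg) {
  lab <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  groups <- list(
    recipient = lab("REC", cfg$n_recipient_taxa),
    outgroup = lab("OUT", cfg$n_outgroup_taxa),
    other_fungi = lab("OFU", cfg$n_other_fungi_taxa)
  )
  prefixes <- c(bacteria = "BAC", animal = "ANI", plant = "PLA",
                archaea = "ARC", protist = "PRO")
  for (g in names(cfg$n_donor_taxa)) {
    groups[[g]] <- lab(prefixes[[g]], cfg$n_donor_taxa[[g]])
  }
  groups <- groups[lengths(groups) > 0]
  tibble(
    taxon_id = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}
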