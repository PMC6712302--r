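#' Group-wise best-hit scores for recipient genes
#'
#' For every query gene, records the best bitscore (and subject) per
#' non-recipient lineage group among its hits; subjects belonging to the
#' recipient group itself are ignored ("excluding the AGF themselves").
#' Genes with no surviving hit get a row of `NA` scores.
#'
#' @param hits Hit tibble (12-column dialect; [load_hits()] output works).
#' @param lineage Lineage map tibble (`taxon_id`, `group`).
#' @param genes Optional character vector of query genes to report (defaults
#'   to all queries present in `hits`); lets callers include recipient genes
#'   that hit nothing.
#' @param taxon_of Function mapping protein ids to taxon ids (default: text
#'   before the first `|`).
#' @return Tibble: `gene_id`, then `best_<group>` and `subject_<group>`
#'   columns for each non-recipient group in the lineage map.
#' @export
group_best_scores <- function(hits, lineage, genes = NULL,
                              taxon_of = function(x) sub("\\|.*$", "", x)) {
  lineage <- validate_lineage(lineage)
  groups <- setdiff(unique(lineage$group), "recipient")
  h <- hits |>
    mutate(subject_taxon = taxon_of(.data$sseqid)) |>
    left_join(lineage, by = c(subject_taxon = "taxon_id")) |>
    filter(!is.na(.data$group), .data$group != "recipient")
  best <- h |>
    group_by(gene_id = .data$qseqid, .data$group) |>
    dplyr::slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
    ungroup() |>
    dplyr::transmute(.data$gene_id, .data$group, best = .data$bitscore,
                     subject = .data$sseqid)
  genes <- genes %||% sort(unique(hits$qseqid))
  out <- tibble(gene_id = genes)
  for (g in groups) {
    b <- filter(best, .data$group == g)
    out[[paste0("best_", g)]] <- b$best[match(genes, b$gene_id)]
    out[[paste0("subject_", g)]] <- b$subject[match(genes, b$gene_id)]
  }
  out
}

#' Alien similarity filter
#'
#' Flags a gene as a transfer candidate when its best hit in any non-fungal
#' group outscores its best hit in the non-recipient fungal groups; an
#' absent homolog scores 0, so a gene with non-fungal homologs and *no*
#' fungal homolog at all gets the strongest possible margin — absence of
#' homologs across the fungi is itself a strong signal of foreign origin.
#' The margin is `max(non-fungal best) - max(fungal best)` and the donor
#' hypothesis is the argmax non-fungal group.
#'
#' @param scores Tibble from [group_best_scores()].
#' @param fungal_groups Groups forming the fungal side (default `outgroup`,
#'   `other_fungi`).
#' @param nonfungal_groups Groups competing as donors (default: `bacteria`,
#'   `animal`, `plant`, `archaea`, `protist`, intersected with the columns
#'   present); per-group toggles are applied by dropping names here.
#' @return `scores` with `best_fungal`, `best_nonfungal`, `alien_margin`,
#'   `alien_flag`, `donor_hypothesis` appended.
#' @export
alien_filter <- function(scores,
                         fungal_groups = c("outgroup", "other_fungi"),
                         nonfungal_groups = c("bacteria", "animal", "plant",
                                              "archaea", "protist")) {
  col_of <- function(g) paste0("best_", g)
  fg <- fungal_groups[col_of(fungal_groups) %in% names(scores)]
  ng <- nonfungal_groups[col_of(nonfungal_groups) %in% names(scores)]
  if (length(ng) == 0L) {
    stop("no non-fungal group score columns found", call. = FALSE)
  }
  score_mat <- function(gs) {
    m <- as.matrix(scores[, col_of(gs), drop = FALSE])
    m[is.na(m)] <- 0
    m
  }
  nf <- score_mat(ng)
  ff <- if (length(fg)) score_mat(fg) else
    matrix(0, nrow(scores), 1)
  best_nf <- apply(nf, 1, max)
  best_ff <- apply(ff, 1, max)
  donor <- ng[apply(nf, 1, which.max)]
  margin <- best_nf - best_ff
  flag <- margin > 0
  scores |>
    mutate(
      best_fungal = best_ff,
      best_nonfungal = best_nf,
      alien_margin = margin,
      alien_flag = flag,
      donor_hypothesis = ifelse(flag, donor, NA_character_)
    )
}

#' Combine two screening strategies into a single candidate ranking
#'
#' Borda combination: each strategy contributes a within-strategy rank
#' (higher score = better = rank 1); the combined rank is the mean of the
#' two. A candidate missing one strategy's score is assigned that strategy's
#' worst rank + 1 and flagged. Ties on the combined rank break by
#' `alien_margin` descending, then `gene_id` ascending, so the order is a
#' deterministic total order.
#'
#' @param candidates Tibble with `gene_id` and `alien_margin` (typically the
#'   flagged rows of [alien_filter()] output).
#' @param score_a,score_b Numeric vectors (aligned with `candidates`) of the
#'   two strategies' scores; larger is better.
#' @return `candidates` ordered by combined rank, with `rank_a`, `rank_b`,
#'   `combined_rank`, `missing_strategy`, `screen_rank` appended.
#' @export
rank_candidates <- function(candidates, score_a, score_b) {
  n <- nrow(candidates)
  stopifnot(length(score_a) == n, length(score_b) == n)
  rank_of <- function(s) {
    r <- rep(NA_real_, n)
    ok <- !is.na(s)
    r[ok] <- rank(-s[ok], ties.method = "min")
    worst <- if (any(ok)) max(r[ok]) else 0
    r[!ok] <- worst + 1
    r
  }
  ra <- rank_of(score_a)
  rb <- rank_of(score_b)
  out <- candidates |>
    mutate(
      rank_a = ra,
      rank_b = rb,
      combined_rank = (ra + rb) / 2,
      missing_strategy = is.na(score_a) | is.na(score_b)
    ) |>
    arrange(.data$combined_rank, desc(.data$alien_margin), .data$gene_id) |>
    mutate(screen_rank = row_number())
  out
}

#' Per-candidate dossier joining similarity, domain and fusion evidence
#'
#' Joins alien-flagged genes with recipient-unique domain labels and fusion
#' evidence. A candidate carrying a recipient-unique domain plus a fused
#' native domain lands in the `"high-confidence"` tier (architecture argues
#' the gene truly resides in the recipient genome); a candidate carrying a
#' recipient-unique domain only is `"unique-domain"`; the rest are
#' `"similarity-only"`. Unflagged genes are absent from the report.
#'
#' @param candidates [alien_filter()] output (optionally ranked).
#' @param arch Architecture tibble from [architectures()] (may be empty).
#' @param domain_classes [classify_domains()] output (may be NULL).
#' @return Tibble: candidate columns plus `unique_domains`, `fusion_partners`,
#'   `tier`.
#' @export
summarize_candidates <- function(candidates, arch = NULL, domain_classes = NULL) {
  flagged <- filter(candidates, .data$alien_flag)
  uniq_doms <- if (!is.null(domain_classes)) {
    domain_classes$item_id[domain_classes$label == "unique_recipient"]
  } else {
    character(0)
  }
  native_doms <- if (!is.null(domain_classes)) {
    domain_classes$item_id[domain_classes$label %in%
                             c("shared", "enriched_recipient")]
  } else {
    character(0)
  }
  per_gene_domains <- function(gene) {
    if (is.null(arch)) return(character(0))
    arch$domain_name[arch$protein_id == gene]
  }
  fus <- if (!is.null(arch)) {
    detect_fusions(arch, uniq_doms, native_doms)
  } else {
    tibble(protein_id = character(0), native_domain = character(0))
  }
  flagged |>
    mutate(
      unique_domains = vapply(.data$gene_id, function(g) {
        paste(intersect(per_gene_domains(g), uniq_doms), collapse = ";")
      }, character(1)),
      fusion_partners = vapply(.data$gene_id, function(g) {
        paste(unique(fus$native_domain[fus$protein_id == g]), collapse = ";")
      }, character(1)),
      tier = dplyr::case_when(
        nzchar(.data$unique_domains) & nzchar(.data$fusion_partners) ~
          "high-confidence",
        nzchar(.data$unique_domains) ~ "unique-domain",
        TRUE ~ "similarity-only"
      )
    )
}
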