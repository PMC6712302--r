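#' Classification thresholds for shared / unique / lost / enriched rules
#'
#' Defaults reproduce the motivating study's permissive rules for 26
#' recipient and 5 outgroup taxa exactly: a family is *shared* if missing in
#' at most 5 of the 26 recipients and at most 1 of the 5 outgroups;
#' *unique to the recipient* if absent from every outgroup but kept by at
#' least 21 of the 26 recipients; *lost in the recipient* if absent from all
#' recipients but present in at least 4 of the 5 outgroups. When the actual
#' group sizes differ from 26/5 the absolute defaults are rescaled
#' proportionally (missing allowances rounded down, presence requirements
#' rounded up), so the defaults generalize while matching the study at
#' 26/5. Enrichment is descriptive: recipient mean copy number at least
#' `enrichment_fold` times the outgroup mean, both positive.
#'
#' @param max_missing_recipient_shared,max_missing_outgroup_shared Shared
#'   rule: maximum missing taxa per group (defaults 5 and 1).
#' @param min_present_recipient_unique Unique rule: minimum recipient taxa
#'   with the item (default 21, inclusive).
#' @param min_present_outgroup_lost Lost rule: minimum outgroup taxa with the
#'   item (default 4).
#' @param enrichment_fold Fold-change on group means for the descriptive
#'   `enriched_recipient` label (default 4).
#' @param domain_evalue Independent E-value cutoff for domain hits
#'   (default 1e-2).
#' @param homolog_evalue Cutoff used when screening group-wise homolog hit
#'   tables (default 1e-3).
#' @param cdd_evalue Cutoff used for domain-name confirmation searches
#'   (default 1e-5; recorded for provenance, not applied by this package).
#' @param rescale Rescale the four absolute counts when group sizes differ
#'   from 26/5 (default TRUE).
#' @return Object of class `hgt_thresholds` (named list).
#' @export
classification_thresholds <- function(max_missing_recipient_shared = 5L,
                                      max_missing_outgroup_shared = 1L,
                                      min_present_recipient_unique = 21L,
                                      min_present_outgroup_lost = 4L,
                                      enrichment_fold = 4,
                                      domain_evalue = 1e-2,
                                      homolog_evalue = 1e-3,
                                      cdd_evalue = 1e-5,
                                      rescale = TRUE) {
  if (domain_evalue <= 0 || homolog_evalue <= 0 || cdd_evalue <= 0) {
    stop_config("domain_evalue", "E-value cutoffs must be > 0")
  }
  structure(
    list(
      max_missing_recipient_shared = as.integer(max_missing_recipient_shared),
      max_missing_outgroup_shared = as.integer(max_missing_outgroup_shared),
      min_present_recipient_unique = as.integer(min_present_recipient_unique),
      min_present_outgroup_lost = as.integer(min_present_outgroup_lost),
      enrichment_fold = enrichment_fold,
      domain_evalue = domain_evalue,
      homolog_evalue = homolog_evalue,
      cdd_evalue = cdd_evalue,
      rescale = isTRUE(rescale),
      ref_n_recipient = 26L,
      ref_n_outgroup = 5L
    ),
    class = "hgt_thresholds"
  )
}

# Effective thresholds for actual group sizes.
effective_thresholds <- function(thr, n_recipient, n_outgroup) {
  out <- thr
  if (thr$rescale &&
      (n_recipient != thr$ref_n_recipient || n_outgroup != thr$ref_n_outgroup)) {
    out$max_missing_recipient_shared <-
      floor(thr$max_missing_recipient_shared / thr$ref_n_recipient * n_recipient)
    out$max_missing_outgroup_shared <-
      floor(thr$max_missing_outgroup_shared / thr$ref_n_outgroup * n_outgroup)
    out$min_present_recipient_unique <-
      ceiling(thr$min_present_recipient_unique / thr$ref_n_recipient * n_recipient)
    out$min_present_outgroup_lost <-
      ceiling(thr$min_present_outgroup_lost / thr$ref_n_outgroup * n_outgroup)
  }
  out
}

#' Build a per-taxon copy-number matrix
#'
#' Rows are domains (from a [parse_domtbl()] hit table) or gene families
#' (from a membership tibble with `family_id`); columns are the taxa of the
#' lineage map. A cell counts domain hits (every hit of a domain on any
#' protein of the taxon counts as a copy) or family members from that taxon.
#' Items with no hit in any taxon have no row.
#'
#' @param x Tibble of domain hits (`domain_name`, `taxon_id`) or family
#'   members (`family_id`, `taxon_id`).
#' @param lineage Lineage map tibble (`taxon_id`, `group`).
#' @return Integer matrix, rows = items, columns = all lineage taxa.
#' @export
build_count_matrix <- function(x, lineage) {
  lineage <- validate_lineage(lineage)
  item_col <- if ("domain_name" %in% names(x)) "domain_name" else "family_id"
  unknown <- setdiff(unique(x$taxon_id), lineage$taxon_id)
  if (length(unknown)) {
    stop(sprintf("hits reference taxa absent from the lineage map: %s",
                 paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  items <- sort(unique(x[[item_col]]))
  mat <- matrix(0L, nrow = length(items), ncol = nrow(lineage),
                dimnames = list(items, lineage$taxon_id))
  if (nrow(x)) {
    tab <- table(factor(x[[item_col]], levels = items),
                 factor(x$taxon_id, levels = lineage$taxon_id))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Classify gene families as shared / unique / lost in the recipient lineage
#'
#' Applies the permissive presence/absence rules (see
#' [classification_thresholds()]) to a family count matrix. Precedence when
#' rules overlap: unique > lost > shared > unclassified.
#'
#' @param mat Count matrix from [build_count_matrix()].
#' @param lineage Lineage map tibble.
#' @param thresholds A [classification_thresholds()] object.
#' @return Tibble: `item_id`, `label` (one of `shared`, `unique_recipient`,
#'   `lost_recipient`, `absent_everywhere`, `unclassified`),
#'   `n_present_recipient`, `n_present_outgroup`, `copies_recipient`,
#'   `copies_outgroup`.
#' @export
classify_families <- function(mat, lineage,
                              thresholds = classification_thresholds()) {
  lineage <- validate_lineage(lineage)
  ev <- classification_evidence(mat, lineage)
  n_r <- sum(lineage$group == "recipient")
  n_o <- sum(lineage$group == "outgroup")
  thr <- effective_thresholds(thresholds, n_r, n_o)
  label <- dplyr::case_when(
    ev$n_present_recipient + ev$n_present_outgroup + ev$n_present_other == 0 ~
      "absent_everywhere",
    ev$n_present_outgroup == 0 &
      ev$n_present_recipient >= thr$min_present_recipient_unique ~
      "unique_recipient",
    ev$n_present_recipient == 0 &
      ev$n_present_outgroup >= thr$min_present_outgroup_lost ~
      "lost_recipient",
    (n_r - ev$n_present_recipient) <= thr$max_missing_recipient_shared &
      (n_o - ev$n_present_outgroup) <= thr$max_missing_outgroup_shared ~
      "shared",
    TRUE ~ "unclassified"
  )
  mutate(ev, label = label, .after = "item_id")
}

#' Classify Pfam domains as shared / unique / lost / enriched
#'
#' Like [classify_families()], but the unique rule requires zero copies in
#' *every* non-recipient fungal taxon supplied (outgroups and other fungi) —
#' a domain held only by the recipient lineage and, say, bacteria is still
#' unique among fungi, which is exactly the signature of the transferred
#' domains in the motivating study. Domains failing unique/lost but with
#' recipient mean copy number at least `enrichment_fold` times the outgroup
#' mean (both positive) are labelled `enriched_recipient`; the remainder
#' fall through the shared rule.
#'
#' @inheritParams classify_families
#' @return Tibble as for [classify_families()], with the additional label
#'   `enriched_recipient` and columns `mean_copies_recipient`,
#'   `mean_copies_outgroup`.
#' @export
classify_domains <- function(mat, lineage,
                             thresholds = classification_thresholds()) {
  lineage <- validate_lineage(lineage)
  ev <- classification_evidence(mat, lineage)
  n_r <- sum(lineage$group == "recipient")
  n_o <- sum(lineage$group == "outgroup")
  thr <- effective_thresholds(thresholds, n_r, n_o)
  fungal_nonrec <- lineage$taxon_id[lineage$group %in% c("outgroup", "other_fungi")]
  copies_fungal_nonrec <- row_sums_for(mat, fungal_nonrec)
  mean_r <- ev$copies_recipient / n_r
  mean_o <- ev$copies_outgroup / n_o
  label <- dplyr::case_when(
    ev$n_present_recipient + ev$n_present_outgroup + ev$n_present_other == 0 ~
      "absent_everywhere",
    copies_fungal_nonrec == 0 &
      ev$n_present_recipient >= thr$min_present_recipient_unique ~
      "unique_recipient",
    ev$n_present_recipient == 0 &
      ev$n_present_outgroup >= thr$min_present_outgroup_lost ~
      "lost_recipient",
    mean_r >= thr$enrichment_fold * mean_o & mean_r > 0 & mean_o > 0 ~
      "enriched_recipient",
    (n_r - ev$n_present_recipient) <= thr$max_missing_recipient_shared &
      (n_o - ev$n_present_outgroup) <= thr$max_missing_outgroup_shared ~
      "shared",
    TRUE ~ "unclassified"
  )
  ev |>
    mutate(label = label, .after = "item_id") |>
    mutate(mean_copies_recipient = mean_r, mean_copies_outgroup = mean_o)
}

classification_evidence <- function(mat, lineage) {
  rec <- lineage$taxon_id[lineage$group == "recipient"]
  outg <- lineage$taxon_id[lineage$group == "outgroup"]
  other <- setdiff(lineage$taxon_id, c(rec, outg))
  tibble(
    item_id = rownames(mat),
    n_present_recipient = row_present_for(mat, rec),
    n_present_outgroup = row_present_for(mat, outg),
    n_present_other = row_present_for(mat, other),
    copies_recipient = row_sums_for(mat, rec),
    copies_outgroup = row_sums_for(mat, outg)
  )
}

row_present_for <- function(mat, taxa) {
  if (length(taxa) == 0L) return(rep(0L, nrow(mat)))
  as.integer(rowSums(mat[, taxa, drop = FALSE] > 0))
}

row_sums_for <- function(mat, taxa) {
  if (length(taxa) == 0L) return(rep(0L, nrow(mat)))
  as.integer(rowSums(mat[, taxa, drop = FALSE]))
}

#' Natural-log transform of a copy-number matrix for heatmap display
#'
#' Returns `ln(count + 1)` (so absence maps to 0 and the transform is
#' strictly monotone in the count), with rows ordered by classification
#' label and then name when a classification is supplied.
#'
#' @param mat Count matrix.
#' @param classification Optional tibble from [classify_domains()] /
#'   [classify_families()] used for row ordering.
#' @return Numeric matrix of the same shape.
#' @export
heatmap_matrix <- function(mat, classification = NULL) {
  out <- log(mat + 1)
  if (!is.null(classification)) {
    ord <- classification[order(classification$label, classification$item_id), ]
    out <- out[ord$item_id[ord$item_id %in% rownames(out)], , drop = FALSE]
  }
  out
}
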