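#' Run the full screening pipeline
#'
#' Orchestrates the stages in dependency order: (optional) synthetic-data
#' generation, per-assembly dereplication of redundant transcript variants,
#' similarity-graph construction and Markov clustering of the fungal
#' proteomes, per-taxon family and domain count matrices with
#' shared/unique/lost classification, the group-wise alien similarity
#' screen with Borda rank combination, and gene-tree diagnostics
#' (monophyly, sister-lineage donor, AU test of the vertical-alternative
#' topology) for flagged candidates. Every stage's row counts and label
#' tallies are logged into a machine-readable run report.
#'
#' @param config A list (see [run_config()]) or path to a YAML file.
#' @return An object of class `run_report` (named list; also written as
#'   `report.json` under the configured output directory).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config(yaml::read_yaml(config))
  config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$demo) {
    cfg <- do.call(sim_config, config$sim)
    ds <- simulate_dataset(cfg)
    paths <- write_synth_dataset(ds, file.path(out_dir, "data"))
    config$paths <- list(
      hits_fungal = paths$hits_fungal,
      hits_refs = paths$hits_refs,
      proteins = paths$proteins,
      domtbl = paths$domtbl,
      lineage = paths$lineage,
      alignments = file.path(out_dir, "data", "alignments")
    )
  } else {
    missing <- names(config$paths)[!vapply(config$paths, file.exists, logical(1))]
    missing <- setdiff(missing, "alignments")
    if (length(missing)) {
      stop(sprintf("missing input(s): %s", paste(
        sprintf("%s (%s)", missing,
                unlist(config$paths[missing])), collapse = "; ")), call. = FALSE)
    }
  }
  lineage <- read_lineage_map(config$paths$lineage)
  thresholds <- do.call(classification_thresholds, config$thresholds)
  report <- list(schema_version = "1.0", demo = config$demo,
                 seed = config$seed)

  ## ---- cluster stage: dereplicate per assembly, then MCL ----
  seqs <- read_fasta(config$paths$proteins)
  fungal_taxa <- lineage$taxon_id[lineage$group %in%
                                    c("recipient", "outgroup", "other_fungi")]
  taxon_of <- function(ids) sub("\\|.*$", "", ids)
  fungal_seqs <- seqs[taxon_of(names(seqs)) %in% fungal_taxa]
  derep_members <- dplyr::bind_rows(lapply(
    split(fungal_seqs, taxon_of(names(fungal_seqs))),
    function(s) dereplicate(s, identity = config$cluster$derep_identity)$members
  ))
  reps <- unique(derep_members$representative)
  report$derep <- list(order = "dereplication before clustering, per assembly",
                       n_proteins = length(fungal_seqs),
                       n_representatives = length(reps))

  hits <- load_hits(config$paths$hits_fungal,
                    evalue_cutoff = config$cluster$evalue_cutoff)
  report$hits_fungal <- list(n_rows = nrow(hits),
                             n_dropped_evalue = attr(hits, "n_dropped_evalue"),
                             n_malformed = attr(hits, "n_malformed"))
  hits <- filter(hits, .data$qseqid %in% reps, .data$sseqid %in% reps)
  graph <- build_graph(hits, proteins = reps,
                       bbh_filter = config$cluster$bbh_filter)
  fams <- mcl(graph, inflation = config$cluster$inflation,
              max_iter = config$cluster$max_iter,
              tol = config$cluster$convergence_tol)
  members <- mutate(fams$membership, taxon_id = taxon_of(.data$protein_id))
  report$mcl <- list(n_families = length(unique(members$family_id)),
                     n_iter = fams$n_iter, converged = fams$converged)

  ## ---- family and domain classification ----
  fungal_lineage <- filter(lineage, .data$taxon_id %in% fungal_taxa)
  fam_mat <- build_count_matrix(members, fungal_lineage)
  fam_classes <- classify_families(fam_mat, fungal_lineage, thresholds)
  readr::write_tsv(fam_classes, file.path(out_dir, "family_classification.tsv"))

  dom_hits <- parse_domtbl(config$paths$domtbl,
                           evalue_cutoff = thresholds$domain_evalue)
  dom_mat <- build_count_matrix(dom_hits, lineage)
  dom_classes <- classify_domains(dom_mat, lineage, thresholds)
  readr::write_tsv(dom_classes, file.path(out_dir, "domain_classification.tsv"))
  heat <- heatmap_matrix(dom_mat, dom_classes)
  readr::write_tsv(as_tibble(heat, rownames = "item_id"),
                   file.path(out_dir, "heatmap_matrix.tsv"))
  arch <- architectures(dom_hits)
  readr::write_tsv(arch, file.path(out_dir, "architectures.tsv"))

  report$families <- as.list(table(fam_classes$label))
  report$domains <- as.list(table(dom_classes$label))

  ## ---- HGT screen ----
  ref_hits <- load_hits(config$paths$hits_refs,
                        evalue_cutoff = thresholds$homolog_evalue)
  rec_prots <- names(seqs)[taxon_of(names(seqs)) %in%
                             lineage$taxon_id[lineage$group == "recipient"]]
  scores <- group_best_scores(ref_hits, lineage, genes = sort(rec_prots))
  flagged <- alien_filter(scores)
  # strategy A: alien bitscore margin; strategy B: best non-fungal identity
  nonfungal <- ref_hits |>
    mutate(subject_group = lineage$group[match(taxon_of(.data$sseqid),
                                               lineage$taxon_id)]) |>
    filter(!.data$subject_group %in% c("recipient", "outgroup", "other_fungi"),
           !is.na(.data$subject_group))
  pid <- if (nrow(nonfungal)) {
    nonfungal |>
      group_by(gene_id = .data$qseqid) |>
      summarise(best_pident = max(.data$pident), .groups = "drop")
  } else {
    tibble(gene_id = character(0), best_pident = numeric(0))
  }
  cand <- filter(flagged, .data$alien_flag)
  cand <- rank_candidates(cand, cand$alien_margin,
                          pid$best_pident[match(cand$gene_id, pid$gene_id)])
  dossier <- summarize_candidates(cand, arch, dom_classes)
  readr::write_tsv(dossier, file.path(out_dir, "hgt_candidates.tsv"))
  report$screen <- list(
    n_queries = nrow(scores),
    n_flagged = nrow(cand),
    tiers = as.list(table(dossier$tier))
  )

  ## ---- gene-tree diagnostics for flagged candidates ----
  tree_diag <- candidate_tree_diagnostics(
    cand, lineage, config$paths$alignments, config$seed,
    support_threshold = config$treetest$support_threshold,
    nboot_tree = config$treetest$nboot_tree,
    nboot_au = config$treetest$nboot_au
  )
  if (nrow(tree_diag)) {
    readr::write_tsv(tree_diag, file.path(out_dir, "tree_diagnostics.tsv"))
  }
  report$treetest <- list(
    n_candidate_families = nrow(tree_diag),
    n_monophyletic = sum(tree_diag$monophyletic),
    donors = as.list(table(tree_diag$donor))
  )

  ## ---- summary tallies ----
  cand_fams <- unique(tree_diag$family)
  unique_fams <- fam_classes$item_id[fam_classes$label == "unique_recipient"]
  flagged_members <- members$family_id[members$protein_id %in% dossier$gene_id]
  report$summary <- list(
    n_unique_families = length(unique_fams),
    n_unique_families_excluding_candidates =
      length(setdiff(unique_fams, unique(flagged_members))),
    n_lost_families = sum(fam_classes$label == "lost_recipient"),
    n_hgt_candidate_families = length(cand_fams),
    top_candidates = head(dossier$gene_id, 10)
  )

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 8,
                       pretty = TRUE)
  structure(c(report, list(out_dir = out_dir, report_path = report_path)),
            class = "run_report")
}

#' Demo pipeline run on a synthetic dataset
#'
#' Convenience wrapper: simulates a dataset with planted unique, lost and
#' transferred families and runs [run_pipeline()] on it end to end.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory.
#' @param n_families Number of gene families to simulate.
#' @param n_planted_unique,n_planted_lost,n_planted_hgt Planted counts.
#' @param ... Further [sim_config()] fields.
#' @return The `run_report`.
#' @export
run_demo <- function(seed = 7L, out_dir = tempfile("hgtscan_demo_"),
                     n_families = 60L, n_planted_unique = 3L,
                     n_planted_lost = 2L, n_planted_hgt = 2L, ...) {
  run_pipeline(run_config(list(
    demo = TRUE,
    seed = seed,
    out_dir = out_dir,
    sim = c(list(n_families = n_families,
                 n_planted_unique_domains = n_planted_unique,
                 n_planted_lost_domains = n_planted_lost,
                 n_planted_hgt = n_planted_hgt,
                 redundancy_rate = 0.1,
                 fusion_rate = 0.5,
                 seed = seed), list(...))
  )))
}

#' Normalize and validate a pipeline configuration
#'
#' Fills defaults for every stage: similarity cutoffs (all-vs-all 1e-5,
#' homolog search 1e-3, domain scan 1e-2), MCL inflation 1.5, >90%
#' dereplication identity, the 5/26, 1/5, 21/26, 4/5 classification rules,
#' and the donor-call support threshold 80.
#'
#' @param config Named list; recognized top-level fields: `demo`, `seed`,
#'   `out_dir`, `paths` (hits_fungal, hits_refs, proteins, domtbl, lineage,
#'   alignments), `sim`, `cluster`, `thresholds`, `treetest`.
#' @return Validated config list.
#' @export
run_config <- function(config) {
  defaults <- list(
    demo = FALSE,
    seed = 1L,
    out_dir = "hgtscan_out",
    paths = list(),
    sim = list(),
    cluster = list(evalue_cutoff = 1e-5, inflation = 1.5, max_iter = 200L,
                   convergence_tol = 1e-6, derep_identity = 0.90,
                   bbh_filter = FALSE),
    thresholds = list(),
    treetest = list(support_threshold = 80, nboot_tree = 100L,
                    nboot_au = 500L)
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) {
          config[[nm]][[sub]] <- defaults[[nm]][[sub]]
        }
      }
    }
  }
  if (!config$demo && length(config$paths) == 0L) {
    stop("non-demo runs require `paths`", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  config
}

# Gene-tree diagnostics for each distinct candidate family: recipient-clade
# monophyly, sister-lineage donor call, and (when distant fungal homologs
# are in the alignment) an AU test of the forced-vertical topology.
candidate_tree_diagnostics <- function(cand, lineage, aln_dir, seed,
                                       support_threshold = 80,
                                       nboot_tree = 100L, nboot_au = 500L) {
  empty <- tibble(family = character(0), n_tips = integer(0),
                  monophyletic = logical(0), stem_support = numeric(0),
                  donor = character(0), p_au_constrained = numeric(0))
  if (nrow(cand) == 0L || is.null(aln_dir) || !dir.exists(aln_dir)) {
    return(empty)
  }
  files <- list.files(aln_dir, pattern = "\\.afa$", full.names = TRUE)
  if (length(files) == 0L) return(empty)
  alns <- lapply(files, read_fasta)
  names(alns) <- sub("\\.afa$", "", basename(files))
  prot_index <- tibble(
    family = rep(names(alns), vapply(alns, length, integer(1))),
    protein_id = unlist(lapply(alns, names), use.names = FALSE)
  )
  fams <- sort(unique(prot_index$family[prot_index$protein_id %in% cand$gene_id]))
  groups_of <- setNames(lineage$group, lineage$taxon_id)
  out <- lapply(seq_along(fams), function(i) {
    f <- fams[i]
    aln <- alns[[f]]
    if (length(aln) < 4L) {
      return(tibble(family = f, n_tips = length(aln), monophyletic = NA,
                    stem_support = NA_real_, donor = NA_character_,
                    p_au_constrained = NA_real_))
    }
    tip_groups <- groups_of[sub("\\|.*$", "", names(aln))]
    names(tip_groups) <- names(aln)
    rec_tips <- names(tip_groups)[tip_groups == "recipient"]
    tr <- infer_gene_tree(aln, nboot = nboot_tree,
                          seed = derive_seed(seed, 5000L + i))
    mono <- is_monophyletic(tr, rec_tips)
    donor <- NA_character_
    support <- mono$support
    if (mono$monophyletic && length(rec_tips) < length(aln)) {
      sl <- sister_lineage(tr, rec_tips, tip_groups,
                           support_threshold = support_threshold)
      donor <- sl$donor
      support <- sl$support
    }
    # AU test: observed tree vs the tree constrained to donor-group
    # monophyly (i.e. the transferred copies no longer nested inside the
    # donor lineage); small p rejects the un-nested alternative.
    p_au <- NA_real_
    donor_tips <- if (!is.na(donor) && donor %in% tip_groups) {
      names(tip_groups)[tip_groups == donor]
    } else {
      character(0)
    }
    if (mono$monophyletic && length(donor_tips) >= 2L &&
        length(rec_tips) >= 2L &&
        !is_monophyletic(tr, donor_tips)$monophyletic) {
      constrained <- suppressMessages(constrain_monophyly(
        tr, donor_tips, alignment = aln))
      ll <- site_loglik_matrix(aln, list(observed = tr,
                                         constrained = constrained))
      au <- au_test(ll, nboot = nboot_au, seed = derive_seed(seed, 6000L + i))
      p_au <- au$table$p_au[au$table$topology == "constrained"]
    }
    tibble(family = f, n_tips = length(aln),
           monophyletic = mono$monophyletic,
           stem_support = support, donor = donor, p_au_constrained = p_au)
  })
  bind_rows(out)
}

read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  families: %s\n",
              paste(sprintf("%s=%s", names(x$families), x$families),
                    collapse = ", ")))
  cat(sprintf("  screen: %d flagged of %d queries; %d candidate families\n",
              x$screen$n_flagged, x$screen$n_queries,
              x$summary$n_hgt_candidate_families))
  cat(sprintf("  report: %s\n", x$report_path))
  invisible(x)
}

#' Heatmap of ln-transformed domain copy numbers
#'
#' @param heat Matrix from [heatmap_matrix()].
#' @param lineage Optional lineage map used to order and annotate taxa.
#' @return A ggplot object (tiles: domains x taxa, fill = ln(copies + 1)).
#' @export
plot_domain_heatmap <- function(heat, lineage = NULL) {
  df <- as_tibble(heat, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "taxon_id", values_to = "ln_copies")
  if (!is.null(lineage)) {
    df$taxon_id <- factor(df$taxon_id, levels = lineage$taxon_id)
  }
  df$item_id <- factor(df$item_id, levels = rev(rownames(heat)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon_id, y = .data$item_id,
                                   fill = .data$ln_copies)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "ln(copies + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
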