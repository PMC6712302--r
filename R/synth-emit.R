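#' Simulate a complete synthetic comparative-genomics dataset
#'
#' Runs [simulate_species_tree()], [evolve_families()] and
#' [evolve_sequences()] for every family and assembles the result into a
#' single object carrying the proteomes, per-family alignments and the truth
#' ledger. Identical configurations (including seed) give byte-identical
#' downstream files.
#'
#' @param cfg A [sim_config()].
#' @param sequences If `FALSE`, skip sequence simulation (presence/absence
#'   and the domain table are still available — much faster when only the
#'   classification layer is exercised).
#' @return An object of class `synth_dataset`: list with `cfg`, `tree`,
#'   `genes`, `ledger`, `sequences` (named character vector), `alignments`
#'   (list of named character vectors, by family).
#' @examples
#' ds <- simulate_dataset(sim_config(n_recipient_taxa = 4,
#'                                   n_outgroup_taxa = 2,
#'                                   n_families = 5, seed = 1))
#' length(ds$sequences)
#' @export
simulate_dataset <- function(cfg, sequences = TRUE) {
  tree <- simulate_species_tree(cfg)
  fam <- evolve_families(tree, cfg)
  seqs <- character(0)
  alns <- list()
  if (sequences) {
    present <- unique(fam$genes$family_id)
    res <- lapply(present, function(f) evolve_sequences(tree, fam, f, cfg))
    names(res) <- present
    seqs <- setNames(
      unlist(lapply(res, function(r) r$sequences$sequence), use.names = FALSE),
      unlist(lapply(res, function(r) r$sequences$protein_id), use.names = FALSE)
    )
    alns <- lapply(res, `[[`, "alignment")
  }
  structure(
    list(cfg = cfg, tree = tree, genes = fam$genes, ledger = fam$ledger,
         sequences = seqs, alignments = alns),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d taxa, %d families, %d proteins, seed %d\n",
              nrow(x$tree$lineage), nrow(x$ledger$families), nrow(x$genes),
              x$cfg$seed))
  invisible(x)
}

#' @export
tidy.synth_dataset <- function(x, ...) x$ledger$families

#' @export
glance.synth_dataset <- function(x, ...) {
  tab <- table(x$ledger$families$class)
  tibble(
    n_taxa = nrow(x$tree$lineage),
    n_families = nrow(x$ledger$families),
    n_proteins = nrow(x$genes),
    n_shared = sum(x$ledger$families$class == "shared"),
    n_unique = sum(x$ledger$families$class == "unique"),
    n_lost = sum(x$ledger$families$class == "lost"),
    n_hgt = sum(x$ledger$families$class == "hgt"),
    seed = x$cfg$seed
  )
}

#' Emit a 12-column similarity hit table from protein sequences
#'
#' Stands in for an all-vs-all BLASTp run. Candidate pairs are found with an
#' exact-word prescreen (sampled 6-mers at fixed positions, analogous to
#' BLAST word seeding; reliable above ~65% identity); identities are then
#' computed ungapped over the common prefix (the synthetic sequences are
#' co-linear). The synthetic bitscore is a documented deterministic function
#' of the alignment: `bitscore = lambda * matches - mu * mismatches`
#' (defaults `lambda = 2`, `mu = 1`), and
#' `evalue = K * m * n * 2^-bitscore` with `K = 0.1` and `m`, `n` the
#' sequence lengths — any monotone surrogate suffices, since downstream
#' filters use score order only. Ordered pairs with bitscore below
#' `floor_bits` are not reported; self-hits are reported (as BLAST does).
#'
#' @param sequences Named character vector of protein sequences, or a tibble
#'   with columns `protein_id`, `sequence`.
#' @param floor_bits Reporting floor on the synthetic bitscore (default 50).
#' @param lambda,mu,K Parameters of the score/E-value transform.
#' @param self_hits Include each sequence's self comparison (default TRUE).
#' @return Tibble with BLAST `-outfmt 6` columns: `qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore`.
#' @examples
#' emit_hits(c(a = "ACDEFGHIKLMNPQRSTVWY", a2 = "ACDEFGHIKLMNPQRSTVWY"),
#'           floor_bits = 10)
#' @export
emit_hits <- function(sequences, floor_bits = 50, lambda = 2, mu = 1,
                      K = 0.1, self_hits = TRUE) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$protein_id)
  }
  ids <- names(sequences)
  if (length(sequences) < 2L && !(self_hits && length(sequences) == 1L)) {
    if (length(sequences) < 1L) stop("need at least one sequence", call. = FALSE)
  }
  lens <- nchar(sequences)
  raws <- lapply(unname(sequences), charToRaw)
  pairs <- candidate_pairs(unname(sequences))
  n_pairs <- nrow(pairs)
  match_n <- integer(n_pairs)
  aln_n <- integer(n_pairs)
  if (n_pairs > 0L) {
    for (k in seq_len(n_pairs)) {
      mm <- prefix_matches(raws[[pairs[k, 1]]], raws[[pairs[k, 2]]])
      match_n[k] <- mm[1]
      aln_n[k] <- mm[2]
    }
  }
  bits <- lambda * match_n - mu * (aln_n - match_n)
  keep <- bits >= floor_bits
  pairs <- pairs[keep, , drop = FALSE]
  match_n <- match_n[keep]
  aln_n <- aln_n[keep]
  bits <- bits[keep]

  if (self_hits) {
    qi <- c(pairs[, 1], pairs[, 2], seq_along(ids))
    si <- c(pairs[, 2], pairs[, 1], seq_along(ids))
    mts <- c(match_n, match_n, lens)
    aln <- c(aln_n, aln_n, lens)
    bts <- c(bits, bits, lambda * lens)
  } else {
    qi <- c(pairs[, 1], pairs[, 2])
    si <- c(pairs[, 2], pairs[, 1])
    mts <- c(match_n, match_n)
    aln <- c(aln_n, aln_n)
    bts <- c(bits, bits)
  }
  out <- tibble(
    qseqid = unname(ids[qi]),
    sseqid = unname(ids[si]),
    pident = unname(round(100 * mts / pmax(aln, 1L), 2)),
    length = unname(aln),
    mismatch = unname(aln - mts),
    gapopen = 0L,
    qstart = 1L,
    qend = unname(aln),
    sstart = 1L,
    send = unname(aln),
    evalue = unname(K * lens[qi] * lens[si] * 2^(-bts)),
    bitscore = unname(bts)
  )
  arrange(out, .data$qseqid, .data$sseqid)
}

#' Emit a HMMER3-style per-domain table from the truth ledger
#'
#' One row per (protein, domain instance), with envelope coordinates taken
#' from the true architectures; independent E-values for true domains are
#' sampled strictly below the analysis cutoff (1e-2), and optional decoy rows
#' (random protein/domain pairs) strictly above it, so cutoff filtering is
#' exercised. Column layout follows `hmmscan --domtblout` (22 columns +
#' description; comment lines start with `#`).
#'
#' @param ledger A `truth_ledger` (from [evolve_families()]).
#' @param decoy_rate Expected decoy rows per protein (default from the
#'   generating config is applied by [write_synth_dataset()]).
#' @param seed Integer seed for the sampled E-values.
#' @return Tibble with columns `target_name`, `target_acc`, `tlen`,
#'   `query_name`, `query_acc`, `qlen`, `full_evalue`, `full_score`,
#'   `full_bias`, `dom_n`, `dom_of`, `c_evalue`, `i_evalue`, `dom_score`,
#'   `dom_bias`, `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `env_from`,
#'   `env_to`, `acc`, `description`.
#' @export
emit_domtbl <- function(ledger, decoy_rate = 0, seed = 1L) {
  stopifnot(inherits(ledger, "truth_ledger"))
  arch <- ledger$architectures
  with_seed(seed, {
    n <- nrow(arch)
    ieval <- 10^(-runif(n, 2.5, 40))  # true rows: always below the 1e-2 cutoff
    rows <- tibble(
      target_name = arch$domain,
      target_acc = paste0(arch$domain, ".1"),
      tlen = arch$end - arch$start + 1L,
      query_name = arch$protein_id,
      query_acc = "-",
      qlen = NA_integer_,
      full_evalue = ieval,
      full_score = round(runif(n, 30, 300), 1),
      full_bias = 0,
      dom_n = 1L,
      dom_of = 1L,
      c_evalue = ieval / 2,
      i_evalue = ieval,
      dom_score = round(runif(n, 30, 300), 1),
      dom_bias = 0,
      hmm_from = 1L,
      hmm_to = arch$end - arch$start + 1L,
      ali_from = arch$start,
      ali_to = arch$end,
      env_from = arch$start,
      env_to = arch$end,
      acc = 0.99,
      description = "-"
    )
    # per-protein counts for dom_n/dom_of and qlen
    rows <- rows |>
      group_by(.data$query_name) |>
      mutate(dom_n = row_number(), dom_of = n(),
             qlen = max(.data$env_to)) |>
      ungroup()
    if (decoy_rate > 0) {
      prots <- unique(arch$protein_id)
      n_dec <- stats::rpois(1, decoy_rate * length(prots))
      if (n_dec > 0) {
        dl <- 40L
        dp <- sample(prots, n_dec, replace = TRUE)
        qlen <- rows$qlen[match(dp, rows$query_name)]
        dstart <- pmax(1L, as.integer(runif(n_dec, 1, pmax(2, qlen - dl))))
        deval <- 10^runif(n_dec, -1.9, 1)  # strictly above the 1e-2 cutoff
        dec <- tibble(
          target_name = sprintf("PF_DECOY%02d", sample.int(20L, n_dec, TRUE)),
          target_acc = "-", tlen = dl,
          query_name = dp, query_acc = "-", qlen = qlen,
          full_evalue = deval, full_score = round(runif(n_dec, 5, 15), 1),
          full_bias = 0, dom_n = 1L, dom_of = 1L,
          c_evalue = deval, i_evalue = deval,
          dom_score = round(runif(n_dec, 5, 15), 1), dom_bias = 0,
          hmm_from = 1L, hmm_to = dl,
          ali_from = dstart, ali_to = dstart + dl - 1L,
          env_from = dstart, env_to = dstart + dl - 1L,
          acc = 0.5, description = "decoy"
        )
        rows <- bind_rows(rows, dec)
      }
    }
    arrange(rows, .data$query_name, .data$env_from, .data$target_name)
  })
}

#' Write a synthetic dataset to disk in standard file dialects
#'
#' Emits: `proteins.faa` (all proteomes, FASTA), `lineage.tsv`
#' (taxon-to-group map), `hits_fungal.tsv` (all-vs-all similarity rows
#' restricted to the fungal taxa — the clustering input), `hits_refs.tsv`
#' (recipient queries against all non-recipient subjects — the HGT-screen
#' input), `scan.domtbl` (HMMER3-style domain table), `ledger_families.tsv`,
#' `ledger_architectures.tsv` and `ledger.json` (the truth ledger), and one
#' aligned FASTA per transferred family under `alignments/`.
#'
#' @param ds A [simulate_dataset()] result (with sequences).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synth_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  if (length(ds$sequences) == 0L) {
    stop("dataset was simulated without sequences", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  paths <- list(
    proteins = file.path(dir, "proteins.faa"),
    lineage = file.path(dir, "lineage.tsv"),
    hits_fungal = file.path(dir, "hits_fungal.tsv"),
    hits_refs = file.path(dir, "hits_refs.tsv"),
    domtbl = file.path(dir, "scan.domtbl"),
    ledger_families = file.path(dir, "ledger_families.tsv"),
    ledger_architectures = file.path(dir, "ledger_architectures.tsv"),
    ledger_json = file.path(dir, "ledger.json"),
    tree = file.path(dir, "species_tree.nwk")
  )
  write_fasta(ds$sequences, paths$proteins)
  readr::write_tsv(ds$tree$lineage, paths$lineage)
  writeLines(ds$tree$newick, paths$tree)

  hits <- emit_hits(ds$sequences)
  fungal_taxa <- ds$tree$lineage$taxon_id[
    ds$tree$lineage$group %in% c("recipient", "outgroup", "other_fungi")]
  rec_taxa <- ds$tree$lineage$taxon_id[ds$tree$lineage$group == "recipient"]
  taxon_of <- function(ids) sub("\\|.*$", "", ids)
  fungal <- hits[taxon_of(hits$qseqid) %in% fungal_taxa &
                   taxon_of(hits$sseqid) %in% fungal_taxa, ]
  refs <- hits[taxon_of(hits$qseqid) %in% rec_taxa &
                 !(taxon_of(hits$sseqid) %in% rec_taxa), ]
  readr::write_tsv(fungal, paths$hits_fungal, col_names = FALSE)
  readr::write_tsv(refs, paths$hits_refs, col_names = FALSE)

  dt <- emit_domtbl(ds$ledger, decoy_rate = ds$cfg$decoy_rate,
                    seed = derive_seed(ds$cfg$seed, 303L))
  write_domtbl(dt, paths$domtbl)

  readr::write_tsv(ds$ledger$families, paths$ledger_families)
  readr::write_tsv(ds$ledger$architectures, paths$ledger_architectures)
  jsonlite::write_json(
    list(families = ds$ledger$families,
         architectures = ds$ledger$architectures),
    paths$ledger_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  hgt_fams <- ds$ledger$families$family_id[ds$ledger$families$class == "hgt"]
  for (f in intersect(hgt_fams, names(ds$alignments))) {
    p <- file.path(dir, "alignments", paste0(f, ".afa"))
    write_fasta(ds$alignments[[f]], p)
    paths[[paste0("aln_", f)]] <- p
  }
  invisible(paths)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 80L)
}

# Serialize an emit_domtbl() tibble in hmmscan --domtblout layout.
write_domtbl <- function(tbl, path) {
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  body <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    tbl$target_name, tbl$target_acc, tbl$tlen, tbl$query_name, tbl$query_acc,
    tbl$qlen, tbl$full_evalue, tbl$full_score, tbl$full_bias, tbl$dom_n,
    tbl$dom_of, tbl$c_evalue, tbl$i_evalue, tbl$dom_score, tbl$dom_bias,
    tbl$hmm_from, tbl$hmm_to, tbl$ali_from, tbl$ali_to, tbl$env_from,
    tbl$env_to, tbl$acc, tbl$description
  )
  writeLines(c(header, body, "#"), path)
}
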