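small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_recipient_taxa = 4, n_outgroup_taxa = 2, n_other_fungi_taxa = 2,
         n_donor_taxa = c(bacteria = 3, animal = 3, plant = 3),
         n_families = 10, seed = 42),
    list(...))
  do.call(sim_config, args)
}

test_that("species tree: smallest valid configuration and monophyly", {
  cfg <- sim_config(n_recipient_taxa = 2, n_outgroup_taxa = 2,
                    n_other_fungi_taxa = 0, n_donor_taxa = integer(0),
                    n_families = 1, seed = 1)
  tr <- simulate_species_tree(cfg)
  expect_s3_class(tr$phylo, "phylo")
  expect_equal(length(tr$phylo$tip.label), 4L)
  rec <- tr$lineage$taxon_id[tr$lineage$group == "recipient"]
  expect_true(oracle_is_monophyletic(tr$phylo, rec))
})

test_that("species tree generation is deterministic given the seed", {
  cfg <- small_cfg()
  expect_identical(simulate_species_tree(cfg)$newick,
                   simulate_species_tree(cfg)$newick)
  cfg2 <- small_cfg(seed = 43)
  expect_false(identical(simulate_species_tree(cfg)$newick,
                         simulate_species_tree(cfg2)$newick))
})

test_that("26+5 tree has 31 fungal leaves and a long recipient stem", {
  cfg <- sim_config(n_recipient_taxa = 26, n_outgroup_taxa = 5,
                    n_other_fungi_taxa = 0, n_donor_taxa = integer(0),
                    n_families = 1, seed = 7)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$phylo$tip.label), 31L)
  rec <- tr$lineage$taxon_id[tr$lineage$group == "recipient"]
  expect_true(oracle_is_monophyletic(tr$phylo, rec))
  expect_gte(oracle_stem_ratio(tr$phylo, rec), 5)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(n_recipient_taxa = 1), "n_recipient_taxa")
  expect_error(sim_config(loss_rate = 1.5), "loss_rate")
  expect_error(sim_config(n_families = 5, n_planted_hgt = 6),
               "exceeds n_families")
  expect_error(sim_config(n_planted_hgt = 1, n_donor_taxa = integer(0)),
               "n_donor_taxa")
})

test_that("no-loss limit: families occupy all taxa below their origin", {
  cfg <- small_cfg(n_planted_unique_domains = 3, n_planted_lost_domains = 2,
                   n_planted_hgt = 2, loss_rate = 0)
  tr <- simulate_species_tree(cfg)
  fam <- evolve_families(tr, cfg)
  genes <- fam$genes[!fam$genes$is_variant, ]
  led <- fam$ledger$families
  n_rec <- cfg$n_recipient_taxa
  counts <- table(genes$family_id, genes$group)
  # planted unique: all recipients, zero outgroups
  for (f in led$family_id[led$class == "unique"]) {
    expect_equal(unname(counts[f, "recipient"]), n_rec)
    expect_equal(unname(counts[f, "outgroup"]), 0L)
  }
  # planted lost: zero recipients, all outgroups
  for (f in led$family_id[led$class == "lost"]) {
    expect_equal(unname(counts[f, "recipient"]), 0L)
    expect_equal(unname(counts[f, "outgroup"]), cfg$n_outgroup_taxa)
  }
  # shared: everywhere
  for (f in led$family_id[led$class == "shared"]) {
    expect_equal(sum(counts[f, ]), nrow(tr$lineage))
  }
})

test_that("ledger conservation: every family once, labels from the vocabulary", {
  cfg <- small_cfg(n_planted_unique_domains = 2, n_planted_lost_domains = 2,
                   n_planted_hgt = 3)
  fam <- evolve_families(simulate_species_tree(cfg), cfg)
  led <- fam$ledger$families
  expect_equal(nrow(led), cfg$n_families)
  expect_false(anyDuplicated(led$family_id) > 0)
  expect_true(all(led$class %in% c("shared", "unique", "lost", "hgt")))
  # every emitted gene belongs to exactly one ledger family
  expect_true(all(fam$genes$family_id %in% led$family_id))
})

test_that("subtree loss matches the closed-form path-survival probability", {
  cfg <- sim_config(n_recipient_taxa = 8, n_outgroup_taxa = 4,
                    n_other_fungi_taxa = 0, n_donor_taxa = integer(0),
                    n_families = 1000, loss_rate = 0.1,
                    loss_model = "subtree", seed = 5)
  tr <- simulate_species_tree(cfg)
  fam <- evolve_families(tr, cfg)
  depths <- oracle_leaf_depths(tr$phylo)
  names(depths) <- tr$phylo$tip.label
  present <- table(factor(fam$genes$taxon_id[!fam$genes$is_variant],
                          levels = tr$lineage$taxon_id))
  for (tx in tr$lineage$taxon_id) {
    p <- (1 - cfg$loss_rate)^depths[[tx]]
    expect_lt(abs(present[[tx]] - 1000 * p),
              3 * sqrt(1000 * p * (1 - p)) + 1e-9)
  }
})

test_that("zero branch lengths give identical sequences across taxa", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  seqs <- withr::with_seed(1, hgtscan:::simulate_core_sequences(tr, 80))
  expect_length(unique(seqs), 1L)
})

test_that("redundant variants keep at least 90% of core positions", {
  cfg <- small_cfg(redundancy_rate = 1, seq_length = 100)
  ds <- simulate_dataset(cfg)
  genes <- ds$genes
  vars <- genes[genes$is_variant, ]
  expect_gt(nrow(vars), 0)
  for (i in seq_len(nrow(vars))) {
    parent <- sub("\\|g2$", "|g1", vars$protein_id[i])
    ident <- pair_identity(
      substr(ds$sequences[[parent]], 1, 100),
      substr(ds$sequences[[vars$protein_id[i]]], 1, 100))
    expect_gte(ident * 100, 90)
  }
})

test_that("transferred genes are closer to the donor than to outgroup fungi", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_recipient_taxa = 4, n_outgroup_taxa = 3,
                      n_other_fungi_taxa = 0,
                      n_donor_taxa = c(bacteria = 3),
                      n_families = 2, n_planted_hgt = 1,
                      hgt_fungal_homolog_frac = 1, seed = 100 + s)
    ds <- simulate_dataset(cfg)
    hgt_fam <- ds$ledger$families$family_id[ds$ledger$families$class == "hgt"]
    aln <- ds$alignments[[hgt_fam]]
    grp <- sub("[0-9]+\\|.*$", "", names(aln))
    rec <- aln[grp == "REC"]
    don <- aln[grp == "BAC"]
    outf <- aln[grp == "OUT"]
    mean_id <- function(a, b) {
      mean(outer(seq_along(a), seq_along(b), Vectorize(function(i, j) {
        pair_identity(a[[i]], b[[j]])
      })))
    }
    if (mean_id(rec, don) > mean_id(rec, outf)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("emit_hits: self-comparison, score floor and formula", {
  s <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  h <- emit_hits(c(x = s, y = s), floor_bits = 10)
  self <- h[h$qseqid == "x" & h$sseqid == "x", ]
  expect_equal(self$pident, 100)
  expect_equal(self$bitscore, 2 * 100)  # lambda * matches, maximal for length
  cross <- h[h$qseqid == "x" & h$sseqid == "y", ]
  expect_equal(cross$pident, 100)
  expect_equal(cross$evalue, 0.1 * 100 * 100 * 2^-200)
  # unrelated random sequences fall below the floor
  set.seed(1)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  r1 <- paste(sample(aa, 100, TRUE), collapse = "")
  r2 <- paste(sample(aa, 100, TRUE), collapse = "")
  h2 <- emit_hits(c(a = r1, b = r2), floor_bits = 50, self_hits = FALSE)
  expect_equal(nrow(h2), 0L)
})

test_that("emit_hits bitscore strictly decreases with planted mutations", {
  base <- strsplit(paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = ""), "")[[1]]
  bits <- vapply(seq(0, 50, by = 10), function(k) {
    mut <- base
    if (k > 0) mut[seq_len(k)] <- ifelse(base[seq_len(k)] == "A", "C", "A")
    h <- emit_hits(c(a = paste(base, collapse = ""),
                     b = paste(mut, collapse = "")),
                   floor_bits = -1000, self_hits = FALSE)
    h$bitscore[h$qseqid == "a"]
  }, numeric(1))
  expect_true(all(diff(bits) < 0))
})

test_that("emit_domtbl preserves architecture order and separates decoys", {
  cfg <- small_cfg(n_planted_hgt = 2, fusion_rate = 1, loss_rate = 0)
  fam <- evolve_families(simulate_species_tree(cfg), cfg)
  dt <- emit_domtbl(fam$ledger, decoy_rate = 2, seed = 9)
  fused <- fam$ledger$architectures |>
    dplyr::count(protein_id) |>
    dplyr::filter(n == 2)
  expect_gt(nrow(fused), 0)
  p <- fused$protein_id[1]
  rows <- dt[dt$query_name == p & dt$description != "decoy", ]
  expect_equal(nrow(rows), 2L)
  expect_lt(rows$env_from[1], rows$env_from[2])
  foreign <- fam$ledger$families$domain[
    fam$ledger$families$family_id == sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", p)]
  expect_equal(rows$target_name[1], foreign)  # foreign domain is 5'
  decoys <- dt[dt$description == "decoy", ]
  expect_gt(nrow(decoys), 0)
  expect_true(all(decoys$i_evalue > 1e-2))
})

test_that("domtbl round-trips through parse_domtbl when decoys are filtered", {
  cfg <- small_cfg(n_planted_hgt = 2, fusion_rate = 0.7, redundancy_rate = 0.3)
  fam <- evolve_families(simulate_species_tree(cfg), cfg)
  dt <- emit_domtbl(fam$ledger, decoy_rate = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".domtbl")
  hgtscan:::write_domtbl(dt, path)
  got <- parse_domtbl(path)  # 1e-2 cutoff removes all decoys
  got <- got[order(got$protein_id, got$env_start), ]
  want <- fam$ledger$architectures[
    order(fam$ledger$architectures$protein_id,
          fam$ledger$architectures$start), ]
  expect_equal(got$protein_id, want$protein_id)
  expect_equal(got$domain_name, want$domain)
  expect_equal(got$env_start, want$start)
  expect_equal(got$env_end, want$end)
})

test_that("identical configurations give byte-identical emitted files", {
  cfg <- small_cfg(n_planted_hgt = 1, redundancy_rate = 0.3, fusion_rate = 0.5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synth_dataset(simulate_dataset(cfg), d1)
  write_synth_dataset(simulate_dataset(cfg), d2)
  for (f in c("proteins.faa", "hits_fungal.tsv", "hits_refs.tsv",
              "scan.domtbl", "species_tree.nwk", "ledger_families.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
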