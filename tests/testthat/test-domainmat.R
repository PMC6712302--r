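lineage_26_5 <- function(n_other = 0) {
  tibble::tibble(
    taxon_id = c(sprintf("REC%02d", 1:26), sprintf("OUT%02d", 1:5),
                 if (n_other > 0) sprintf("OFU%02d", seq_len(n_other))),
    group = c(rep("recipient", 26), rep("outgroup", 5),
              rep("other_fungi", n_other))
  )
}

# count matrix with a given number of presence-1 cells per group
presence_row <- function(lineage, n_rec, n_out, n_other = 0, copies = 1L) {
  m <- matrix(0L, 1, nrow(lineage), dimnames = list("D1", lineage$taxon_id))
  rec <- lineage$taxon_id[lineage$group == "recipient"]
  outg <- lineage$taxon_id[lineage$group == "outgroup"]
  oth <- lineage$taxon_id[lineage$group == "other_fungi"]
  if (n_rec > 0) m[1, rec[seq_len(n_rec)]] <- copies
  if (n_out > 0) m[1, outg[seq_len(n_out)]] <- copies
  if (n_other > 0) m[1, oth[seq_len(n_other)]] <- copies
  m
}

test_that("parse_domtbl applies the 1e-2 cutoff and skips comments", {
  tmpl <- "%s PF1.1 100 prot%d|x - 120 %g 50.0 0.0 1 1 %g %g 50.0 0.0 1 100 1 100 1 100 0.99 -"
  path <- withr::local_tempfile()
  writeLines(c("# comment line",
               sprintf(tmpl, "DomA", 1, 5e-3, 5e-3, 5e-3),
               sprintf(tmpl, "DomB", 2, 0.05, 0.05, 0.05),
               "#"), path)
  h <- parse_domtbl(path)
  expect_equal(h$domain_name, "DomA")   # 5e-3 kept, 0.05 dropped
  expect_equal(h$env_start, 1L)

  onlycomments <- withr::local_tempfile()
  writeLines(c("# a", "# b"), onlycomments)
  expect_equal(nrow(parse_domtbl(onlycomments)), 0L)

  bad <- withr::local_tempfile()
  writeLines("too few fields", bad)
  expect_error(parse_domtbl(bad), "line 1")
})

test_that("count matrix counts hits per taxon and rejects unknown taxa", {
  lin <- lineage_26_5()
  hits <- tibble::tibble(
    domain_name = c("CBM_10", "CBM_10", "CBM_10", "Other"),
    taxon_id = c("REC01", "REC01", "REC01", "OUT01")
  )
  m <- build_count_matrix(hits, lin)
  expect_equal(m["CBM_10", "REC01"], 3L)
  expect_equal(m["Other", "OUT01"], 1L)
  expect_equal(sum(m), 4L)
  expect_equal(nrow(m), 2L)   # absent domains have no row
  expect_error(
    build_count_matrix(dplyr::mutate(hits, taxon_id = "NOPE"), lin),
    "NOPE")
})

test_that("family classification follows the 5/26, 1/5, 21/26, 4/5 rules", {
  lin <- lineage_26_5()
  cases <- list(
    list(n_rec = 22, n_out = 0, want = "unique_recipient"),
    list(n_rec = 0, n_out = 4, want = "lost_recipient"),
    list(n_rec = 21, n_out = 4, want = "shared"),
    list(n_rec = 10, n_out = 0, want = "unclassified"),
    list(n_rec = 20, n_out = 0, want = "unclassified"),  # 20 < 21
    list(n_rec = 0, n_out = 3, want = "unclassified"),   # 3 < 4
    list(n_rec = 26, n_out = 5, want = "shared"),
    list(n_rec = 0, n_out = 0, want = "absent_everywhere")
  )
  for (cs in cases) {
    got <- classify_families(presence_row(lin, cs$n_rec, cs$n_out), lin)
    expect_equal(got$label, cs$want,
                 label = sprintf("rec=%d out=%d", cs$n_rec, cs$n_out))
  }
})

test_that("domain classification: fungal-wide uniqueness and enrichment", {
  lin <- lineage_26_5(n_other = 3)
  # 24/26 recipients, nothing in outgroups or other fungi -> unique
  expect_equal(classify_domains(presence_row(lin, 24, 0), lin)$label,
               "unique_recipient")
  # present in other fungi blocks uniqueness
  expect_equal(classify_domains(presence_row(lin, 24, 0, n_other = 1), lin)$label,
               "unclassified")
  # absent from recipients, 5/5 outgroups -> lost
  expect_equal(classify_domains(presence_row(lin, 0, 5), lin)$label,
               "lost_recipient")
  # recipient mean 8 vs outgroup mean 1 at fold 4 -> enriched
  m <- presence_row(lin, 26, 5)
  rec <- lin$taxon_id[lin$group == "recipient"]
  m[1, rec] <- 8L
  expect_equal(classify_domains(m, lin)$label, "enriched_recipient")
})

test_that("thresholds rescale proportionally for other group sizes", {
  thr <- hgtscan:::effective_thresholds(classification_thresholds(), 13, 10)
  expect_equal(thr$max_missing_recipient_shared, 2L)   # floor(5/26*13)
  expect_equal(thr$max_missing_outgroup_shared, 2L)    # floor(1/5*10)
  expect_equal(thr$min_present_recipient_unique, 11L)  # ceiling(21/26*13)
  expect_equal(thr$min_present_outgroup_lost, 8L)      # ceiling(4/5*10)
  thr26 <- hgtscan:::effective_thresholds(classification_thresholds(), 26, 5)
  expect_equal(thr26$min_present_recipient_unique, 21L)
})

test_that("classification is invariant to column order and duplicated hits", {
  lin <- lineage_26_5()
  hits <- tibble::tibble(
    domain_name = rep("D", 23), taxon_id = sprintf("REC%02d", 1:23))
  m1 <- build_count_matrix(hits, lin)
  lin_shuffled <- lin[rev(seq_len(nrow(lin))), ]
  m2 <- build_count_matrix(hits, lin_shuffled)
  expect_equal(classify_domains(m1, lin)$label,
               classify_domains(m2, lin_shuffled)$label)
  hits_dup <- dplyr::distinct(rbind(hits, hits))
  m3 <- build_count_matrix(hits_dup, lin)
  expect_equal(classify_domains(m3, lin)$label,
               classify_domains(m1, lin)$label)
})

test_that("heatmap transform is ln(count+1), monotone, and label-ordered", {
  m <- matrix(c(0L, 1L, 7L, 3L), 2, 2,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  h <- heatmap_matrix(m)
  expect_equal(h["a", "t1"], 0)
  expect_equal(h["b", "t1"], log(2))
  counts <- 0:20
  vals <- log(counts + 1)
  expect_true(all(diff(vals) > 0))
  cls <- tibble::tibble(item_id = c("a", "b"),
                        label = c("unique_recipient", "lost_recipient"))
  h2 <- heatmap_matrix(m, cls)
  expect_equal(rownames(h2), c("b", "a"))  # lost sorts before unique
})

test_that("architectures merge same-domain overlaps and order by start", {
  hits <- tibble::tibble(
    protein_id = rep("p1", 3),
    taxon_id = "t", domain_accession = "-",
    i_evalue = 1e-5, score = 50,
    domain_name = c("Cthe_2159", "Cthe_2159", "TPH"),
    env_start = c(10L, 150L, 250L),
    env_end = c(200L, 220L, 340L)
  )
  a <- architectures(hits)
  expect_equal(nrow(a), 2L)  # overlapping Cthe_2159 envelopes merged
  expect_equal(a$env_start, c(10L, 250L))
  expect_equal(a$env_end, c(220L, 340L))
  expect_equal(a$domain_name[a$position == 1], "Cthe_2159")
})

test_that("fusion detection flags foreign+native architectures with side", {
  arch <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p2", "p3"),
    domain_name = c("Cthe_2159", "TPH", "Gal_Lectin", "Glyco_transf_34", "solo"),
    env_start = c(10L, 250L, 300L, 50L, 1L),
    env_end = c(200L, 340L, 400L, 150L, 90L),
    position = c(1L, 2L, 2L, 1L, 1L)
  )
  fus <- detect_fusions(arch,
                        foreign_domains = c("Cthe_2159", "Gal_Lectin"),
                        native_domains = c("TPH", "Glyco_transf_34"))
  expect_equal(nrow(fus), 2L)
  p1 <- fus[fus$protein_id == "p1", ]
  expect_equal(p1$native_side, "3prime")   # eukaryotic domain 3' of Cthe_2159
  p2 <- fus[fus$protein_id == "p2", ]
  expect_equal(p2$native_side, "5prime")   # Glyco_transf_34 flanking 5'
  expect_false("p3" %in% fus$protein_id)   # single-domain: no fusion
})

test_that("labels partition matrix rows exactly once", {
  cfg <- sim_config(n_families = 40, n_planted_unique_domains = 4,
                    n_planted_lost_domains = 4, n_planted_hgt = 4,
                    loss_rate = 0.1, seed = 77)
  ds <- simulate_dataset(cfg, sequences = FALSE)
  lin <- ds$tree$lineage
  m <- build_count_matrix(ds$genes, lin)
  cl <- classify_families(m, lin)
  expect_equal(nrow(cl), nrow(m))
  expect_false(anyDuplicated(cl$item_id) > 0)
  expect_equal(sum(table(cl$label)), nrow(m))
})
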