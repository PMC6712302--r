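test_that("parse_newick reads supports, polytomies, and rejects imbalance", {
  tr <- parse_newick("((A:0.1,B:0.1)98:0.1,C:0.2);")
  expect_true("98" %in% tr$node.label)
  poly <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(poly$Nnode, 1L)
  expect_error(parse_newick("((A,B),C;"), "unbalanced")
  expect_error(parse_newick("(A,B)),C;"), "position")
  expect_error(parse_newick("((A,B),A);"), "duplicate")
})

test_that("newick round-trip preserves the bipartition set", {
  set.seed(10)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    txt <- ape::write.tree(tr)
    back <- parse_newick(txt)
    b1 <- oracle_bipartitions(tr)
    b2 <- oracle_bipartitions(back)
    norm <- function(b, tips) {
      sides <- lapply(b, function(s) {
        comp <- sort(setdiff(tips, s))
        if (paste(s, collapse = "") < paste(comp, collapse = "")) s else comp
      })
      unique(sides[order(vapply(sides, paste, "", collapse = ","))])
    }
    tips <- sort(tr$tip.label)
    expect_equal(norm(b1, tips), norm(b2, tips))
  }
})

test_that("monophyly agrees with examples and exhaustive bipartition search", {
  tr <- parse_newick("((a1:1,a2:1)90:1,(b1:1,b2:1)80:1);")
  expect_true(is_monophyletic(tr, c("a1", "a2"))$monophyletic)
  expect_false(is_monophyletic(tr, c("a1", "b1"))$monophyletic)
  expect_error(is_monophyletic(tr, "nope"), "unknown")

  set.seed(21)
  for (i in 1:10) {
    tr <- ape::rtree(12)
    taxa <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(is_monophyletic(tr, taxa)$monophyletic,
                 oracle_is_monophyletic(tr, taxa),
                 label = sprintf("tree %d, taxa {%s}", i,
                                 paste(taxa, collapse = ",")))
  }
})

test_that("monophyly is invariant to leaf order and rerooting", {
  tr <- parse_newick("(((a1:1,a2:1)95:1,a3:1)88:1,(b1:1,(b2:1,b3:1)70:1)60:1);")
  taxa <- c("a1", "a2", "a3")
  base <- is_monophyletic(tr, taxa)$monophyletic
  expect_true(base)
  for (tip in c("b1", "b2", "b3")) {
    rt <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(is_monophyletic(rt, taxa)$monophyletic, base)
  }
  expect_equal(is_monophyletic(tr, rev(taxa))$monophyletic, base)
})

test_that("sister lineage reports donor, support, and threshold behaviour", {
  groups <- c(AGF1 = "recipient", AGF2 = "recipient",
              BacX = "bacteria", BacY = "bacteria", Fun1 = "other_fungi")
  tr <- parse_newick("(((AGF1:0.1,AGF2:0.1)98:0.3,(BacX:0.1,BacY:0.1)95:0.1)90:0.4,Fun1:0.8);")
  sl <- sister_lineage(tr, c("AGF1", "AGF2"), groups)
  expect_equal(sl$donor, "bacteria")
  expect_equal(sl$support, 98)

  tr_low <- parse_newick("(((AGF1:0.1,AGF2:0.1)50:0.3,(BacX:0.1,BacY:0.1)95:0.1)90:0.4,Fun1:0.8);")
  expect_equal(sister_lineage(tr_low, c("AGF1", "AGF2"), groups)$donor,
               "unresolved")

  groups2 <- c(groups, Ani1 = "animal")
  tr_tie <- parse_newick("(((AGF1:0.1,AGF2:0.1)99:0.3,(BacX:0.1,Ani1:0.1)95:0.1)90:0.4,Fun1:0.8);")
  expect_equal(sister_lineage(tr_tie, c("AGF1", "AGF2"), groups2)$donor,
               "ambiguous")
  expect_error(sister_lineage(tr, c("AGF1", "BacX"), groups), "monophyletic")
})

test_that("single-leaf and two-leaf likelihoods match closed forms", {
  m <- subst_model()
  tr1 <- ape::read.tree(text = "(A:0.0);")
  ll1 <- site_loglik(c(A = "AC"), tr1, m)
  expect_equal(ll1, rep(log(1 / 20), 2))  # equilibrium frequency per site

  t <- 0.37
  tr2 <- ape::read.tree(text = sprintf("(A:%f,B:0);", t))
  p_same <- 1 / 20 + (19 / 20) * exp(-20 / 19 * t)
  p_diff <- (1 / 20) * (1 - exp(-20 / 19 * t))
  ll2 <- site_loglik(c(A = "AA", B = "AC"), tr2, m)
  expect_equal(ll2[1], log(p_same / 20), tolerance = 1e-10)
  expect_equal(ll2[2], log(p_diff / 20), tolerance = 1e-10)
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  fixtures <- c(
    "(A:0.2,B:0.4);",
    "((A:0.1,B:0.3):0.2,C:0.5);",
    "((A:0.15,B:0.05):0.1,(C:0.3,D:0.2):0.25);",
    "(A:0.1,B:0.2,(C:0.3,D:0.1):0.15);",                 # basal polytomy
    "(((A:0.1,B:0.1):0.1,C:0.2):0.1,(D:0.3,E:0.1):0.2);" # 5 leaves
  )
  for (txt in fixtures) {
    tr <- ape::read.tree(text = txt)
    aln <- random_aln(tr$tip.label, 6, seed = nchar(txt))
    got <- site_loglik(aln, tr, subst_model())
    want <- oracle_site_loglik(aln, tr)
    expect_equal(got, want, tolerance = 1e-8, label = txt)
  }
})

test_that("discrete-Gamma mixture brackets the single-rate likelihood", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.1,D:0.4):0.2);")
  aln <- random_aln(tr$tip.label, 20, seed = 3)
  ll1 <- sum(site_loglik(aln, tr, subst_model()))
  llg <- sum(site_loglik(aln, tr, subst_model(gamma_categories = 4,
                                              gamma_shape = 0.8)))
  expect_true(is.finite(llg))
  expect_false(isTRUE(all.equal(ll1, llg)))
  rates <- hgtscan:::discrete_gamma_rates(0.8, 4)
  expect_equal(mean(rates), 1, tolerance = 1e-9)
  expect_true(all(diff(rates) > 0))
})

test_that("constraining an already-monophyletic group is the identity", {
  tr <- parse_newick("(((a1:1,a2:1):1,b1:1):1,b2:1);")
  expect_message(out <- constrain_monophyly(tr, c("a1", "a2")), "unchanged")
  expect_identical(out, tr)
})

test_that("an intruder is regrafted outside the group", {
  tr <- parse_newick("((((g1:0.1,x1:0.1):0.1,g2:0.1):0.1,g3:0.1):0.2,(o1:0.1,o2:0.1):0.2);")
  out <- constrain_monophyly(tr, c("g1", "g2", "g3"))
  expect_true(is_monophyletic(out, c("g1", "g2", "g3"))$monophyletic)
  expect_setequal(out$tip.label, tr$tip.label)
})

test_that("constrained likelihood never beats the unconstrained tree", {
  for (s in 1:3) {
    cfg <- sim_config(n_recipient_taxa = 4, n_outgroup_taxa = 2,
                      n_other_fungi_taxa = 2,
                      n_donor_taxa = c(bacteria = 3),
                      n_families = 2, n_planted_hgt = 1,
                      hgt_fungal_homolog_frac = 1, seed = 400 + s)
    ds <- simulate_dataset(cfg)
    f <- ds$ledger$families$family_id[ds$ledger$families$class == "hgt"]
    aln <- ds$alignments[[f]]
    tr <- infer_gene_tree(aln, nboot = 10, seed = s)
    donor_tips <- grep("^BAC", names(aln), value = TRUE)
    if (is_monophyletic(tr, donor_tips)$monophyletic) next
    con <- suppressMessages(constrain_monophyly(tr, donor_tips,
                                                alignment = aln))
    expect_true(is_monophyletic(con, donor_tips)$monophyletic)
    expect_lte(sum(site_loglik(aln, con)), sum(site_loglik(aln, tr)))
  }
})

test_that("AU test: symmetric topologies sit near p = 0.5", {
  set.seed(5)
  row <- rnorm(120)
  ll <- rbind(t1 = row, t2 = row)
  res <- au_test(ll, nboot = 1000, seed = 11)
  expect_true(all(abs(res$table$p_au - 0.5) < 0.05))
})

test_that("AU test rejects a site-wise dominated topology; naive RELL agrees", {
  set.seed(6)
  good <- rnorm(100)
  ll <- rbind(best = good, worse = good - 10)
  res <- au_test(ll, nboot = 1000, seed = 3)
  p_worse <- res$table$p_au[res$table$topology == "worse"]
  expect_lt(p_worse, 0.05)
  expect_true(res$table$degenerate[res$table$topology == "worse"])
  bp <- oracle_rell_bp(ll, nboot = 1000, seed = 3)
  expect_lt(bp[2], 0.05)  # independent single-scale RELL also rejects
  expect_gte(res$table$p_au[res$table$topology == "best"], p_worse)
})

test_that("AU p-values stay in [0, 1] across random likelihood matrices", {
  for (s in 1:50) {
    set.seed(s)
    ll <- matrix(rnorm(3 * 40, sd = 2), nrow = 3)
    res <- au_test(ll, nboot = 200, seed = s)
    expect_true(all(res$table$p_au >= 0 & res$table$p_au <= 1))
    best <- which.max(rowSums(ll))
    expect_gte(res$table$p_au[best], min(res$table$p_au))
  }
})

test_that("AU test validates its inputs", {
  expect_error(au_test(matrix(rnorm(20), 1, 20)), "2 topologies")
  expect_error(au_test(matrix(rnorm(10), 2, 5)), "10 sites")
  bad <- matrix(c(rnorm(19), Inf), 2, 10)
  expect_error(au_test(bad), "finite")
})
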