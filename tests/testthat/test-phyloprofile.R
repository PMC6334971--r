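test_that("species trees parse, validate and round trip", {
  t2 <- readSpeciesTree("(A,B);")
  expect_equal(sort(t2$tip.label), c("A", "B"))
  t4 <- readSpeciesTree("((A,B),(C,D));")
  expect_equal(length(t4$tip.label), 4)
  expect_equal(t4$Nnode, 3)
  expect_true(all(nzchar(t4$node.label)))      # internal nodes labelled
  # round trip preserves topology
  back <- readSpeciesTree(newickString(t4))
  expect_true(ape::all.equal.phylo(t4, back, use.edge.length = FALSE))
  expect_error(readSpeciesTree("((A,B);"), "invalid")
  expect_error(readSpeciesTree("(A,A);"), "duplicate")
})

test_that("profiles validate their state alphabet and taxa", {
  tr <- readSpeciesTree("((A,B),(C,D));")
  m <- matrix(c("1", "0", "?", "1"), 1, 4,
              dimnames = list("X", c("A", "B", "C", "D")))
  expect_silent(phyloProfile(m, tr))
  bad <- m; bad[1, 1] <- "2"
  expect_error(phyloProfile(bad, tr), "entries")
  mm <- m; colnames(mm)[1] <- "NOTATAXON"
  expect_error(phyloProfile(mm, tr), "missing from the tree")
  # TSV round trip
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(m), tf, sep = "\t", quote = FALSE)
  expect_equal(readPhyloProfile(tf), phyloProfile(m))
})

test_that("Dollo maps the excavate-style two-loss history and edge cases", {
  tr <- readSpeciesTree("((Cme,(Tva,Gin)),((Egr,Sin),Tbr));")
  prof <- phyloProfile(matrix(
    c("1", "0", "0", "1", "1", "0"), 1, 6,
    dimnames = list("Tom7", c("Cme", "Tva", "Gin", "Egr", "Sin", "Tbr"))),
    tr)
  gm <- dolloMap(tr, prof, "Tom7")
  expect_equal(gm$gainNode, tr$node.label[1])      # gain at the root
  expect_equal(gm$nLosses, 2)                      # (Tva,Gin) clade + Tbr
  expect_true("Tbr" %in% gm$lossEdges)
  expect_equal(gm$leafStates[c("Cme", "Egr", "Sin")],
               c(Cme = "1", Egr = "1", Sin = "1"))

  # present everywhere: single gain, no loss
  all1 <- phyloProfile(matrix("1", 1, 6,
                              dimnames = list("Tom40", tr$tip.label)), tr)
  gmAll <- dolloMap(tr, all1, "Tom40")
  expect_equal(gmAll$nLosses, 0)
  expect_equal(gmAll$gainNode, tr$node.label[1])

  # present in a single leaf: gain on that leaf edge
  one <- phyloProfile(matrix(c("0", "1", "0", "0", "0", "0"), 1, 6,
                             dimnames = list("X", tr$tip.label)), tr)
  gmOne <- dolloMap(tr, one, "X")
  expect_equal(gmOne$gainNode, "Tva")
  expect_equal(gmOne$nLosses, 0)

  # absent everywhere: zero events
  none <- phyloProfile(matrix("0", 1, 6,
                              dimnames = list("Z", tr$tip.label)), tr)
  expect_equal(dolloMap(tr, none, "Z")$nGains, 0)
})

test_that("Dollo losses are minimal over all single-gain scenarios (small trees)", {
  trees <- c("((A,B),(C,D));", "(((A,B),C),(D,(E,F)));",
             "((Cme,(Tva,Gin)),((Egr,Sin),Tbr));")
  withr::with_seed(181, for (nwk in trees) {
    tr <- readSpeciesTree(nwk)
    n <- length(tr$tip.label)
    for (code in 0:(2^n - 1)) {
      present <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
      if (!any(present)) next
      prof <- phyloProfile(matrix(ifelse(present, "1", "0"), 1, n,
                                  dimnames = list("X", tr$tip.label)), tr)
      gm <- dolloMap(tr, prof, "X")
      expect_equal(gm$nLosses, oracleDolloMin(tr, present))
      # reconstructed leaf states reproduce the observed profile
      expect_equal(unname(gm$leafStates), ifelse(present, "1", "0"))
    }
  })
})

test_that("uncertain leaves are free and resolve toward fewer losses", {
  tr <- readSpeciesTree("((A,B),(C,D));")
  prof <- phyloProfile(matrix(c("1", "?", "0", "1"), 1, 4,
                              dimnames = list("X", tr$tip.label)), tr)
  gm <- dolloMap(tr, prof, "X")
  expect_equal(gm$nLosses, 1)      # only the C edge; B may stay present
  expect_equal(gm$lossEdges, "C")
})

test_that("adding a present leaf never lowers the gain node", {
  tr <- readSpeciesTree("(((A,B),(C,D)),((E,F),(G,H)));")
  mkProf <- function(states) {
    m <- matrix(states, 1, length(states),
                dimnames = list("X", names(states)))
    phyloProfile(m, tr)
  }
  base <- c(A = "1", B = "1", C = "0", D = "0", E = "0", F = "0",
            G = "0", H = "0")
  gm1 <- dolloMap(tr, mkProf(base), "X")
  wider <- base; wider["G"] <- "1"
  gm2 <- dolloMap(tr, mkProf(wider), "X")
  ch <- tomseek:::.childList(tr)
  under <- function(lbl) tomseek:::.leavesUnder(
    tr, tomseek:::.nodeNumber(tr, lbl), ch, length(tr$tip.label))
  expect_true(all(under(gm1$gainNode) %in% under(gm2$gainNode)))
})

test_that("profile reports tabulate events with totals and flags", {
  sim <- simTreeProfile(191)
  rep_ <- profileReport(sim$tree, sim$profile)
  expect_equal(rep_$component[nrow(rep_)], "TOTAL")
  expect_equal(rep_$nLosses[nrow(rep_)],
               sum(rep_$nLosses[-nrow(rep_)]))
  # inferred loss counts match the canonical simulated histories
  for (cp in rownames(sim$profile)) {
    expect_equal(rep_$nLosses[rep_$component == cp],
                 length(sim$truth[[cp]]$lossEdges))
  }
  # uncertain-only component is flagged with zero events
  tr <- readSpeciesTree("((A,B),(C,D));")
  prof <- phyloProfile(matrix("?", 1, 4,
                              dimnames = list("U", tr$tip.label)), tr)
  ru <- profileReport(tr, prof)
  expect_equal(ru$note[1], "uncertain-only")
  expect_equal(ru$nGains[1], 0)
  # empty profile
  prof0 <- matrix(character(), 0, 4,
                  dimnames = list(NULL, tr$tip.label))
  expect_equal(nrow(profileReport(tr, phyloProfile(prof0, tr))), 0)
})
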