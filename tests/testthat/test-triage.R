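test_that("Venn regions decompose exactly", {
  v <- vennRegions(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                        C = "3"))
  expect_equal(v$count[v$signature == "A&B&C"], 1)
  expect_identical(v$members[v$signature == "A&B&C"][[1]], "3")
  expect_equal(sum(v$count), 4)            # |union|
  # disjoint sets: all intersection regions empty
  vd <- vennRegions(list(A = c("a", "b"), B = c("c")))
  expect_equal(vd$count[vd$signature == "A&B"], 0)
  expect_error(vennRegions(list(c("a"), c("b"))), "names")
  expect_error(vennRegions(list(A = "a")), "2 or 3")
})

test_that("Venn decomposition is a partition matching a signature oracle", {
  withr::with_seed(111, {
    for (rep in 1:20) {
      uni <- sprintf("ACC%04d", 1:300)
      sets <- list(A = sample(uni, sample(0:200, 1)),
                   B = sample(uni, sample(0:200, 1)),
                   C = sample(uni, sample(0:200, 1)))
      v <- vennRegions(sets)
      allMembers <- unlist(v$members)
      expect_equal(sum(v$count), length(unique(unlist(sets))))
      expect_false(anyDuplicated(allMembers) > 0)
      # per-accession signature oracle
      for (acc in sample(unique(unlist(sets)), min(20, sum(v$count)))) {
        sig <- paste(names(sets)[vapply(sets, function(s) acc %in% s,
                                        logical(1))], collapse = "&")
        expect_true(acc %in% v$members[v$signature == sig][[1]])
      }
    }
  })
})

test_that("triage tiers candidates by condition support and is order-invariant", {
  cl <- c("T1", "T2", "RCPT", "X1")
  nat <- c("T1", "T2", "X2")
  mem <- c("T1", "T2", "RCPT", "M1")
  anchors <- c(T1 = "tail_anchored", T2 = "polytopic",
               RCPT = "tail_anchored")
  tr <- triageCandidates(cl, nat, mem, anchors)
  expect_equal(tr$accession[tr$tier == 1], c("T1", "T2"))
  expect_equal(tr$accession[tr$tier == 2], "RCPT")   # crosslink-only
  expect_equal(tr$anchor[tr$accession == "RCPT"], "tail_anchored")
  # shuffling the inputs does not change the result
  tr2 <- triageCandidates(rev(cl), sample(nat), sample(mem), anchors)
  expect_equal(tr, tr2)
  # empty enrichment
  expect_equal(nrow(triageCandidates(character(), character(), mem)), 0)
})

test_that("tiering mirrors the planted complex on a synthetic run", {
  pr <- simProteome(121, nDecoys = 20)
  members <- pr$truth$id[pr$truth$family != "decoy"]
  loose <- pr$truth$id[pr$truth$family == "tom36like"][2:3]
  tight <- setdiff(members, loose)
  tr <- triageCandidates(crosslinkEnriched = members,
                         nativeEnriched = tight,
                         membraneProteome = members)
  expect_setequal(tr$accession[tr$tier == 1], tight)
  expect_setequal(tr$accession[tr$tier == 2], loose)
})

domainSetup <- local({
  hsAln <- simFamilyAlignment(131, "hsp20Domain", n = 10, rate = 0.08)
  tprAln <- simFamilyAlignment(132, "tprDomain", n = 10, rate = 0.08)
  hs <- buildProfileHMM(hsAln)
  tp <- buildProfileHMM(tprAln)
  list(hmms = list(Hsp20 = hs, TPR = tp),
       cals = list(Hsp20 = calibrateEvalues(hs, 100, 100, seed = 133),
                   TPR = calibrateEvalues(tp, 100, 100, seed = 134)))
})

test_that("domain architecture renders Hsp20-TPR(3)-TMD on planted receptors", {
  pr <- simProteome(141, nDecoys = 0)
  ids <- recordIds(pr$records)
  for (id in pr$truth$id[pr$truth$family == "tom36like"]) {
    s <- as.character(pr$records[[match(id, ids)]])
    ac <- classifyAnchor(s, predictTmds(s))
    res <- classifyArchitecture(s, domainSetup$hmms, domainSetup$cals, ac)
    expect_equal(res$architecture, "Hsp20-TPR(3)-TMD")
    # spans never overlap
    d <- res$domains[order(res$domains$start), ]
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("TPR-only constructs and random decoys classify as expected", {
  tpl <- syntheticTemplates()
  tprOnly <- paste0(strrep("D", 10), tpl$tprDomain, "GS", tpl$tprDomain,
                    strrep("D", 10))
  res <- classifyArchitecture(tprOnly, domainSetup$hmms, domainSetup$cals,
                              NULL)
  expect_equal(res$architecture, "TPR(2)")

  withr::with_seed(151, {
    otherCount <- sum(vapply(1:100, function(i) {
      res <- classifyArchitecture(randSeq(150), domainSetup$hmms,
                                  domainSetup$cals, NULL)
      res$architecture == "other"
    }, logical(1)))
  })
  expect_gte(otherCount, 95)
})

test_that("Tom22 feature checks follow the TMD motif rules", {
  # TMD begins L W S T L S ... with S at W+4 and P in the core
  tmd <- paste0("LWSTLS", strrep("L", 8), "P", strrep("L", 10))
  s <- paste0(strrep("D", 30), tmd, "KR")
  span <- IRanges::IRanges(31, 31 + nchar(tmd) - 1)
  f <- tom22Features(s, span)
  expect_true(f$hasCtermTmd)
  expect_true(f$trpAtMotifPos2)
  expect_true(f$hydroxylatedRunAfterTrp)
  expect_true(f$serAtPlus4)
  expect_true(f$proInTmd)
  expect_true(f$passesAll)

  # W -> A breaks the tryptophan flag
  sA <- sub("LWSTLS", "LASTLS", s, fixed = TRUE)
  fA <- tom22Features(sA, span)
  expect_false(fA$trpAtMotifPos2)
  expect_false(fA$passesAll)

  # removing the proline breaks only that flag
  sP <- gsub("P", "L", s, fixed = TRUE)
  fP <- tom22Features(sP, span)
  expect_false(fP$proInTmd)
  expect_true(fP$trpAtMotifPos2)
  expect_false(fP$passesAll)

  # no TMD at all
  f0 <- tom22Features(strrep("D", 50), IRanges::IRanges())
  expect_false(f0$hasCtermTmd)
  expect_false(f0$passesAll)
})

test_that("the planted Tom22-like protein passes all feature checks", {
  for (seed in c(161, 162, 163)) {
    pr <- simProteome(seed, nDecoys = 0)
    t22 <- pr$truth[pr$truth$family == "tom22like", ]
    s <- as.character(pr$records[[match(t22$id, recordIds(pr$records))]])
    span <- IRanges::IRanges(t22$tmdStart, nchar(s) - 2L)
    expect_true(tom22Features(s, span)$passesAll)
    expect_equal(round(molecularWeight(syntheticTemplates()$tom22), 1), 6.4)
  }
})
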