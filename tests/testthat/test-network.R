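test_that("local alignment reproduces the textbook score and a naive DP", {
  expect_equal(localAlignmentScore("HEAGAWGHEE", "PAWHEAE", "BLOSUM50",
                                   gapOpen = 0, gapExtend = 8), 28)
  # dual route: package (Biostrings) vs hand-written DP on random pairs
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  withr::with_seed(171, {
    for (i in 1:15) {
      a <- randSeq(sample(8:25, 1)); b <- randSeq(sample(8:25, 1))
      expect_equal(localAlignmentScore(a, b, "BLOSUM62", 11, 1),
                   oracleSW(a, b, B62, 11, 1))
    }
  })
})

test_that("similarity edges carry Karlin-Altschul p-values and drop weak pairs", {
  recs <- Biostrings::AAStringSet(c(a = strrep("MKLVANDEQW", 5),
                                    b = strrep("MKLVANDEQW", 5),
                                    c = withr::with_seed(170, randSeq(50))))
  e <- pairwiseSimilarity(recs, keepP = 1.0000001)
  expect_true(all(e$id1 < e$id2))                  # canonical, no self edges
  ab <- e[e$id1 == "a" & e$id2 == "b", ]
  expect_equal(ab$pValue, min(e$pValue))           # identical pair strongest
  expect_true(all(e$pValue > 0 & e$pValue <= 1))
  expect_true(all(e$attraction >= 0))
  expect_error(pairwiseSimilarity(recs[1]), "at least 2")

  # unrelated natural-composition 100-mers usually fall above p = 0.1
  dropped <- withr::with_seed(172, {
    sum(vapply(1:100, function(i) {
      r <- Biostrings::AAStringSet(setNames(
        c(randSeq(100, ROBFREQS), randSeq(100, ROBFREQS)), c("x", "y")))
      nrow(pairwiseSimilarity(r)) == 0
    }, logical(1)))
  })
  expect_gte(dropped, 90)
})

test_that("top edge fraction matches a sort-based oracle with stable ties", {
  withr::with_seed(173, {
    edges <- data.frame(id1 = sprintf("n%02d", 1:10),
                        id2 = sprintf("n%02d", 2:11),
                        attraction = sample(c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9)))
    t2 <- topEdgeFraction(edges, 0.2)
    expect_equal(nrow(t2), 2)
    ord <- order(-edges$attraction, edges$id1, edges$id2)
    expect_equal(t2, edges[ord[1:2], ], ignore_attr = TRUE)
    expect_equal(nrow(topEdgeFraction(edges, 1)), 10)
    expect_error(topEdgeFraction(edges, 0))
  })
})

test_that("connected components equal a flood-fill oracle", {
  # edgeless graph: all singletons
  none <- data.frame(id1 = character(), id2 = character())
  expect_equal(unname(networkComponents(none, paste0("n", 1:5))), 1:5)
  withr::with_seed(174, {
    for (rep in 1:20) {
      n <- sample(5:100, 1)
      nodes <- sprintf("v%03d", 1:n)
      ne <- sample(0:(2 * n), 1)
      edges <- data.frame(id1 = sample(nodes, ne, replace = TRUE),
                          id2 = sample(nodes, ne, replace = TRUE))
      edges <- edges[edges$id1 != edges$id2, ]
      got <- networkComponents(edges, nodes)
      ref <- oracleComponents(edges, nodes)
      # same partition (labels may differ): compare co-membership
      expect_true(all((outer(got, got, "==") ==
                       outer(ref, ref, "=="))))
      # idempotent and order-invariant
      got2 <- networkComponents(edges[sample(nrow(edges)), , drop = FALSE],
                                nodes)
      expect_identical(got, got2)
    }
  })
})

test_that("layout is seeded, translation-equivariant, and pulls linked nodes together", {
  edges1 <- data.frame(id1 = "a", id2 = "b", attraction = 50)
  # single node stays at its initial position
  lone <- networkLayout(data.frame(id1 = character(), id2 = character(),
                                   attraction = numeric()),
                        "solo", nIter = 100, seed = 4)
  init <- withSeed(4, matrix(runif(2), 1, 2))
  expect_equal(c(lone$x, lone$y), c(init[1, 1], init[1, 2]))

  l1 <- networkLayout(edges1, c("a", "b"), nIter = 2000, seed = 7)
  l2 <- networkLayout(edges1, c("a", "b"), nIter = 2000, seed = 7)
  expect_identical(l1, l2)                      # deterministic under seed

  init2 <- withSeed(7, matrix(runif(4), 2, 2))
  d0 <- sqrt(sum((init2[1, ] - init2[2, ])^2))
  d1 <- sqrt((l1$x[1] - l1$x[2])^2 + (l1$y[1] - l1$y[2])^2)
  expect_lt(d1, d0)                             # attraction dominates

  # translation equivariance, up to floating-point drift over iterations
  shifted <- networkLayout(edges1, c("a", "b"), nIter = 2000, seed = 7,
                           init = init2 + 5)
  expect_equal(shifted$x, l1$x + 5, tolerance = 1e-4)
  expect_equal(shifted$y, l1$y + 5, tolerance = 1e-4)
})

test_that("a planted family forms its own cluster at a stringent cutoff", {
  fam <- simFamilyAlignment(99, "barrel", n = 16, rate = 0.15)
  names(fam) <- paste0("FAM", 1:16)
  pr <- simProteome(3, nDecoys = 20, background = "robinson")
  dec <- pr$records[pr$truth$family == "decoy"]
  recs <- Biostrings::AAStringSet(c(as.character(fam), as.character(dec)))
  e <- pairwiseSimilarity(recs, keepP = 1e-4)
  comp <- networkComponents(e, names(recs))
  expect_equal(length(unique(comp[1:16])), 1)   # one family component
  expect_false(any(comp[17:36] == comp[[1]]))   # decoys excluded
})
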