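test_that("profile construction follows the occupancy and pseudocount rules", {
  # single ungapped sequence: one match state per column, emissions peaked
  aln <- Biostrings::AAStringSet(c(s = "MKLVANDEQW"))
  hmm <- buildProfileHMM(aln)
  expect_equal(nMatch(hmm), 10)
  peaks <- colnames(hmm@matchEmissions)[apply(hmm@matchEmissions, 1,
                                              which.max)]
  expect_equal(paste(peaks, collapse = ""), "MKLVANDEQW")

  # a column that is 75% gaps fails a 0.5 occupancy threshold
  aln4 <- Biostrings::AAStringSet(c(a = "MK-V", b = "M--V",
                                    c = "M--V", d = "MK-V"))
  hmm4 <- buildProfileHMM(aln4, occupancyThreshold = 0.5)
  expect_equal(nMatch(hmm4), 3)   # columns 1, 2 (50%), 4; column 3 dropped

  # probability conservation is enforced by the class validity
  expect_true(isVirtualClass("ProfileHMM") == FALSE)
  expect_true(all(abs(rowSums(hmm4@matchEmissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm4@transM) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm4@transI) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm4@transD) - 1) < 1e-9))

  # no qualifying column
  gappy <- Biostrings::AAStringSet(c(a = "A---", b = "-A--", c = "--A-",
                                     d = "---A"))
  expect_error(buildProfileHMM(gappy, occupancyThreshold = 0.5),
               "occupancy")
})

test_that("a one-match-state model scores by the closed form", {
  aln <- Biostrings::AAStringSet(c(s = "A"))
  hmm <- buildProfileHMM(aln)
  expect_equal(nMatch(hmm), 1)
  # entry log2(1/1) = 0 and M1 -> E with probability 1, so the score is
  # exactly the emission log-odds
  for (a in c("A", "W", "G")) {
    closed <- unname(log2(hmm@matchEmissions[1, a]) -
                       log2(hmmBackground(hmm)[a]))
    expect_equal(viterbiScore(hmm, a), closed, tolerance = 1e-12)
    expect_equal(forwardScore(hmm, a), closed, tolerance = 1e-12)
  }
})

test_that("Viterbi and forward match exhaustive path enumeration on toy models", {
  withr::with_seed(31, {
    for (m in 1:3) {
      for (rep in 1:3) {
        hmm <- randomToyHmm(m)
        for (L in 1:4) {
          s <- randSeq(L)
          ref <- oracleEnumeratePaths(hmm, s)
          expect_equal(viterbiScore(hmm, s), ref$viterbi, tolerance = 1e-9)
          expect_equal(forwardScore(hmm, s), ref$forward, tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("forward is at least Viterbi and scoring ignores record order", {
  withr::with_seed(32, {
    for (i in 1:25) {
      hmm <- randomToyHmm(sample(2:6, 1))
      s <- randSeq(sample(3:30, 1))
      expect_gte(forwardScore(hmm, s), viterbiScore(hmm, s) - 1e-12)
    }
  })
  aln <- simFamilyAlignment(21, "barrel", n = 8, rate = 0.1)
  hmm <- buildProfileHMM(aln)
  cal <- calibrateEvalues(hmm, nDecoys = 60, decoyLength = 80, seed = 3)
  pr <- simProteome(22, nDecoys = 10)
  hitsA <- searchProteome(hmm, pr$records, cal)
  perm <- withr::with_seed(5, sample(length(pr$records)))
  hitsB <- searchProteome(hmm, pr$records[perm], cal)
  expect_equal(as.data.frame(hitsA), as.data.frame(hitsB))
  expect_true(all(diff(hitsA$bitScore) <= 1e-9))   # ranked non-increasing
})

test_that("a training sequence outscores its own residue shuffles", {
  aln <- simFamilyAlignment(41, "barrel", n = 24, rate = 0.1)
  hmm <- buildProfileHMM(aln)
  s <- as.character(aln[[1]])
  sc <- forwardScore(hmm, s)
  wins <- withr::with_seed(42, {
    sum(vapply(1:100, function(i) {
      shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      sc > forwardScore(hmm, shuf)
    }, logical(1)))
  })
  expect_gte(wins, 95)
})

test_that("decoy calibration is reproducible and self-consistent", {
  aln <- simFamilyAlignment(51, "barrel", n = 12, rate = 0.1)
  hmm <- buildProfileHMM(aln)
  c1 <- calibrateEvalues(hmm, nDecoys = 200, decoyLength = 120, seed = 9)
  c2 <- calibrateEvalues(hmm, nDecoys = 200, decoyLength = 120, seed = 9)
  expect_equal(c1@mu, c2@mu)
  expect_equal(c1@lambda, c2@lambda)
  expect_gt(c1@lambda, 0)

  # re-score the same decoy population: about one decoy should reach E <= 1
  tabs <- tomseek:::.hmmLogTables(hmm)
  scores <- withSeed(9, vapply(1:200, function(i) {
    s <- paste(sample(names(hmmBackground(hmm)), 120, replace = TRUE,
                      prob = hmmBackground(hmm)), collapse = "")
    forwardScore(hmm, s)
  }, numeric(1)))
  ev <- evalueFromScore(c1, scores, dbSize = 200)
  expect_lte(sum(ev <= 1), 4)

  # a flat profile yields degenerate (zero-variance) decoy scores
  flat <- new("ProfileHMM", nMatch = 2L,
              matchEmissions = matrix(1 / 20, 2, 20,
                                      dimnames = list(NULL, tomseek:::AA_ALPHABET)),
              insertEmissions = matrix(1 / 20, 2, 20,
                                       dimnames = list(NULL, tomseek:::AA_ALPHABET)),
              transM = rbind(c(0.4, 0.05, 0.05, 0.5), c(0, 0, 0, 1)),
              transI = rbind(c(0.5, 0.5), c(1, 0)),
              transD = rbind(c(1, 0), c(1, 0)),
              background = setNames(rep(1 / 20, 20), tomseek:::AA_ALPHABET))
  expect_error(calibrateEvalues(flat, nDecoys = 50, decoyLength = 1,
                                seed = 1), "degenerate")
})

test_that("a planted family member is retrieved first from a decoy proteome", {
  aln <- simFamilyAlignment(61, "barrel", n = 24, rate = 0.1)
  hmm <- buildProfileHMM(aln)
  cal <- calibrateEvalues(hmm, nDecoys = 100, decoyLength = 150, seed = 8)
  pr <- simProteome(62, nDecoys = 100,
                    families = defaultFamilies()["tom40"])
  keep <- c(which(pr$truth$id == "TOM40_01"),
            which(pr$truth$family == "decoy"))
  hits <- searchProteome(hmm, pr$records[keep], cal)
  expect_equal(hits$id[1], "TOM40_01")
  expect_lt(hits$evalue[1], 1e-3)
  # empty proteome
  expect_equal(nrow(searchProteome(hmm, Biostrings::AAStringSet(), cal)), 0)
})
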