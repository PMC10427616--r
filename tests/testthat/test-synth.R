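# The synthetic benchmark generator and curation machinery.

test_that("toy complexes are deterministic, Cn-symmetric and have the
           requested geometry", {
  cx <- makeToyComplex(3, 24, seed = 11)
  cx2 <- makeToyComplex(3, 24, seed = 11)
  expect_identical(cx@atoms, cx2@atoms)
  expect_equal(nChains(cx), 3L)
  expect_equal(cx@symmetryOrder, 3L)
  expect_equal(chainLength(cx, "A"), 24L)
  # identical sequences across chains
  expect_equal(chainSequence(cx, "A"), chainSequence(cx, "B"))
  # different seed, different sequence/coordinates
  expect_false(identical(makeToyComplex(3, 24, seed = 12)@atoms, cx@atoms))
  expect_error(makeToyComplex(0, 24), "nChains")
  expect_error(makeToyComplex(2, 10), "L must")
})

test_that("monomers have no inter-chain contacts and C3 bundles have a
           cyclically symmetric union map", {
  mono <- makeToyComplex(1, 24, seed = 13)
  expect_equal(nChains(mono), 1L)
  cx <- makeToyComplex(3, 24, seed = 14)
  cm <- interchainContactMap(cx)
  expect_gt(sum(cm@union), 0)
  # cyclic chain permutation leaves the union map unchanged
  a <- cx@atoms
  a$chain <- c(A = "B", B = "C", C = "A")[a$chain]
  a <- a[order(a$chain), ]
  cx2 <- new("ComplexStructure", atoms = a, chains = c("A", "B", "C"),
             symmetryOrder = 3L)
  expect_identical(interchainContactMap(cx2)@union, cm@union)
})

test_that("the membrane-like regime packs tighter than the soluble regime", {
  sol <- makeToyComplex(2, 30, seed = 15, regime = "soluble")
  tmp <- makeToyComplex(2, 30, seed = 15, regime = "tmp")
  expect_gt(sum(interchainContactMap(tmp)@union),
            sum(interchainContactMap(sol)@union))
})

test_that("synthetic MSAs honour their degenerate parameter limits", {
  cx <- fxC3()
  frozen <- makeSyntheticMsa(cx, depth = 20, mutationRate = 0,
                             couplingStrength = 0, seed = 16)
  X <- msaMatrix(frozen)
  expect_true(all(X == matrix(X[1, ], nrow(X), ncol(X), byrow = TRUE)))
  expect_equal(computeMeff(frozen), 1.0)
  expect_equal(paste(X[1, ], collapse = ""), chainSequence(cx))
  expect_error(makeSyntheticMsa(cx, depth = 1), "depth")
  # determinism
  a <- makeSyntheticMsa(cx, depth = 30, seed = 17)
  b <- makeSyntheticMsa(cx, depth = 30, seed = 17)
  expect_identical(msaMatrix(a), msaMatrix(b))
})

test_that("with strong coupling most top DCA pairs are true interface
           pairs; with no coupling the hit count drops to chance", {
  cx <- fxC3()
  strong <- makeSyntheticMsa(cx, depth = 500, mutationRate = 0.4,
                             couplingStrength = 0.9, seed = 18)
  pairs <- attr(strong, "coupledPairs")
  apc <- meanFieldDca(strong)@apc
  idx <- which(upper.tri(apc), arr.ind = TRUE)
  top10 <- idx[order(-apc[idx])[1:10], , drop = FALSE]
  key <- paste(pairs[, 1], pairs[, 2])
  hitsStrong <- sum(paste(top10[, 1], top10[, 2]) %in% key)
  expect_gte(hitsStrong, 5L)
  null <- makeSyntheticMsa(cx, depth = 500, mutationRate = 0.4,
                           couplingStrength = 0, seed = 18)
  apc0 <- meanFieldDca(null)@apc
  top10n <- idx[order(-apc0[idx])[1:10], , drop = FALSE]
  hitsNull <- sum(paste(top10n[, 1], top10n[, 2]) %in% key)
  expect_lt(hitsNull, hitsStrong)
})

test_that("surrogate language-model features carry the truth exactly at
           zero noise and validate against the ingestion contract", {
  cx <- fxC3()
  truth <- interchainContactMap(cx)
  lm0 <- makeSurrogateLmFeatures(cx, truth, noise = 0, seed = 19,
                                 signalChannels = c(2L, 7L))
  expect_equal(lm0@attentions[, , 2L], truth@union + 0)
  expect_equal(lm0@attentions[, , 7L], truth@union + 0)
  expect_false(isTRUE(all.equal(lm0@attentions[, , 1L], truth@union + 0)))
  # shapes validated by the ingestion path
  lm <- ingestLmFeatures(lm0@embedding, lm0@attentions, chainLength(cx))
  expect_s4_class(lm, "LMFeatures")
  # determinism
  lmA <- makeSurrogateLmFeatures(cx, truth, noise = 1, seed = 20)
  lmB <- makeSurrogateLmFeatures(cx, truth, noise = 1, seed = 20)
  expect_identical(lmA@attentions, lmB@attentions)
  expect_error(makeSurrogateLmFeatures(cx, truth, signalChannels = 200L),
               "1..144")
})

test_that("benchmark splits have the configured sizes, disjoint ids and a
           byte-identical regeneration", {
  cfg <- list(nSolTrain = 3L, nSolValid = 2L, nTmpTrain = 2L,
              nTmpValid = 1L, nTmpTest = 2L, Lmin = 24L, Lmax = 28L,
              msaDepth = 40L)
  bm <- buildTransferBenchmark(cfg, seed = 21)
  expect_length(bm@solubleTrain, 3L)
  expect_length(bm@solubleValid, 2L)
  expect_length(bm@tmpTrain, 2L)
  expect_length(bm@tmpValid, 1L)
  expect_length(bm@tmpTest, 2L)
  ids <- vapply(c(bm@solubleTrain, bm@solubleValid, bm@tmpTrain,
                  bm@tmpValid, bm@tmpTest), function(t) t@id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  Ls <- vapply(bm@tmpTest, function(t) t@L, integer(1))
  expect_true(all(Ls >= 24L & Ls <= 28L))
  bm2 <- buildTransferBenchmark(cfg, seed = 21)
  expect_identical(bm2@tmpTest[[1L]]@bundle@complex,
                   bm@tmpTest[[1L]]@bundle@complex)
  expect_identical(bm2@manifest, bm@manifest)
  expect_error(buildTransferBenchmark(list(nSolTrain = 0L), seed = 1),
               "split size")
})

test_that("the two regimes differ in the configured interface statistics", {
  cfg <- list(nSolTrain = 4L, nSolValid = 1L, nTmpTrain = 4L,
              nTmpValid = 1L, nTmpTest = 1L, Lmin = 24L, Lmax = 28L,
              msaDepth = 30L)
  bm <- buildTransferBenchmark(cfg, seed = 22)
  solContacts <- vapply(bm@solubleTrain, function(t)
    sum(t@truth@union) / t@L, numeric(1))
  tmpContacts <- vapply(bm@tmpTrain, function(t)
    sum(t@truth@union) / t@L, numeric(1))
  # tighter packing + more chains give denser interfaces in the tmp regime
  expect_gt(mean(tmpContacts), mean(solContacts))
})

test_that("curation accepts compliant complexes and reports each failed
           criterion", {
  cx <- makeToyComplex(3, 48, seed = 23, regime = "tmp")
  rule <- curationRule(minInterfaceArea = 150, minInterfaceContacts = 10L,
                       maxMonomerLength = 100L)
  ok <- applyCuration(cx, rule)
  expect_true(ok$accept)
  expect_length(ok$reasons, 0L)
  # symmetry-order mismatch
  wrongSym <- makeToyComplex(3, 48, seed = 23, regime = "tmp")
  wrongSym@symmetryOrder <- 4L
  expect_true("symmetry_order" %in% applyCuration(wrongSym, rule)$reasons)
  # over-long monomer
  longRule <- curationRule(minInterfaceArea = 150,
                           minInterfaceContacts = 10L,
                           maxMonomerLength = 40L)
  expect_true("monomer_length" %in% applyCuration(cx, longRule)$reasons)
  # missing symmetry annotation errors when the rule is enabled
  noSym <- makeToyComplex(2, 48, seed = 24)
  noSym@symmetryOrder <- NA_integer_
  expect_error(applyCuration(noSym, rule), "symmetry annotation")
  expect_true(applyCuration(noSym, curationRule(
    minInterfaceArea = 150, minInterfaceContacts = 10L,
    requireSymmetryMatch = FALSE))$accept)
})

test_that("small or separated interfaces are rejected with the right
           reasons", {
  cx <- makeToyComplex(2, 48, seed = 25)
  # pull chain B away: area and contact count collapse
  a <- cx@atoms
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 30
  far <- new("ComplexStructure", atoms = a, chains = cx@chains,
             symmetryOrder = 2L)
  res <- applyCuration(far, curationRule(minInterfaceArea = 150,
                                         minInterfaceContacts = 10L))
  expect_false(res$accept)
  expect_true(all(c("interface_area", "contact_count") %in% res$reasons))
  # divergent chain sequences violate the identity rule
  mut <- cx@atoms
  selB <- mut$chain == "B"
  mut$resname[selB] <- ifelse(mut$resname[selB] == "ALA", "TRP", "ALA")
  div <- new("ComplexStructure", atoms = mut, chains = cx@chains,
             symmetryOrder = 2L)
  expect_true("chain_identity" %in%
                applyCuration(div, curationRule(minInterfaceArea = 150,
                                                minInterfaceContacts = 10L)
                              )$reasons)
})

test_that("curation decisions depend on content, not atom order", {
  cx <- makeToyComplex(3, 48, seed = 26, regime = "tmp")
  rule <- curationRule(minInterfaceArea = 150, minInterfaceContacts = 10L)
  r1 <- applyCuration(cx, rule)
  # reorder atoms within each residue (content identical)
  a <- cx@atoms
  a <- a[order(match(a$chain, cx@chains), a$resno, a$atom), ]
  rownames(a) <- NULL
  cx2 <- new("ComplexStructure", atoms = a, chains = cx@chains,
             symmetryOrder = 3L)
  r2 <- applyCuration(cx2, rule)
  expect_equal(r1, r2)
})

test_that("greedy clustering handles the identity extremes and matches a
           brute-force threshold oracle", {
  same <- rep(strrep("ACDEFGHIKL", 3), 5)
  cl <- greedyCluster(same, identity = 0.30)
  expect_equal(max(cl), 1L)
  set.seed(27)
  distinct <- vapply(1:6, function(i)
    paste(sample(tmcontact:::AA1, 30, TRUE), collapse = ""), character(1))
  cl2 <- greedyCluster(distinct, identity = 0.99)
  expect_equal(max(cl2), 6L)
  # seeded families: greedy cover oracle over the all-pairs identity graph
  mkFam <- function(base, n, mut) {
    vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      flip <- runif(length(s)) < mut
      s[flip] <- sample(tmcontact:::AA1, sum(flip), TRUE)
      paste(s, collapse = "")
    }, character(1))
  }
  base1 <- paste(sample(tmcontact:::AA1, 40, TRUE), collapse = "")
  base2 <- paste(sample(tmcontact:::AA1, 40, TRUE), collapse = "")
  seqs <- c(mkFam(base1, 4, 0.1), mkFam(base2, 4, 0.1))
  got <- greedyCluster(seqs, identity = 0.5)
  oracle <- integer(length(seqs)); reps <- integer(0)
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (ci in seq_along(reps))
      if (tmcontact:::.seqIdentity(seqs[i], seqs[reps[ci]]) >= 0.5) {
        hit <- ci; break
      }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    oracle[i] <- hit
  }
  expect_equal(as.integer(got), oracle)
  expect_error(greedyCluster(character(0)), "empty")
  expect_error(greedyCluster(c("ACD", "")), "empty sequence")
})
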