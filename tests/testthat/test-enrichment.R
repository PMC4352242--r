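test_that("annotation unions merge samples into tissue groups", {
  cfg <- enrichmentConfig()
  u <- tissueUnion(list(c("a", "b"), c("b", "c")),
                   tissues = c("brain", "brain"), cfg)
  expect_identical(u$brain, c("a", "b", "c"))
  # ovary and testis merge into gonad under the default grouping
  u2 <- tissueUnion(list("x", "y"), tissues = c("ovary", "testis"), cfg)
  expect_identical(u2$gonad, c("x", "y"))
  # an empty sample contributes nothing
  u3 <- tissueUnion(list(c("a"), character(0)),
                    tissues = c("liver", "liver"), cfg)
  expect_identical(u3$liver, "a")
  expect_error(tissueUnion(list("a"), tissues = "kidney", cfg), "kidney")
})

test_that("tissue-enriched and shared sets partition as expected", {
  groups <- list(g1 = c("a", "b"), g2 = c("b", "c"), g3 = "b")
  te <- tissueEnriched(groups)
  expect_identical(te$enriched$g1, "a")
  expect_identical(te$enriched$g2, "c")
  expect_length(te$enriched$g3, 0)
  expect_identical(te$shared, "b")
  # enriched sets are pairwise disjoint and disjoint from shared
  allEnriched <- unlist(te$enriched)
  expect_false(anyDuplicated(allEnriched) > 0)
  expect_length(intersect(allEnriched, te$shared), 0)
  expect_error(tissueEnriched(list(g1 = "a")), "two groups")
})

test_that("species enrichment applies the >=8 / zero-in-each rule exactly", {
  a <- c(t1 = 10, t2 = 8, t3 = 7, t4 = 20, t5 = 9)
  b1 <- c(t1 = 0, t2 = 0, t3 = 0, t4 = 0, t5 = 1)
  b2 <- c(t1 = 0, t2 = 1, t3 = 0, t4 = 0, t5 = 0)
  got <- speciesEnriched(a, b1, b2)
  # t1: 10/0/0 enriched; t2: 8/0/1 fails zero-in-each; t3: below threshold;
  # t4 passes; t5 fails dataset 1
  expect_identical(got, c("t1", "t4"))
  # laxer any-dataset reading admits t2 and t5
  lax <- speciesEnriched(a, b1, b2, enrichmentConfig(anyDataset = TRUE))
  expect_identical(lax, c("t1", "t2", "t4", "t5"))
  # raising the threshold never adds transcripts
  strict <- speciesEnriched(a, b1, b2,
                            enrichmentConfig(minReadsSpeciesA = 15))
  expect_true(all(strict %in% got))
  # a transcript missing from a matrix is an error
  expect_error(speciesEnriched(a, b1[-1], b2), "t1")
})

test_that("planted species-A-only transcripts are recovered from simulated counts", {
  cfg <- simConfig(nGenes = 30, lengthRange = c(400, 800),
                   speciesAOnlyFraction = 0.2, jcDistance = 0.09,
                   coverageTarget = 20, seed = 21)
  sim <- generateTranscriptome(cfg)
  aOnly <- aOnlySet(sim$truth)
  B <- evolveOrthologs(sim$transcripts, cfg@jcDistance, seed = 22,
                       exclude = aOnly, idMap = orthologMap(sim$truth))
  exprAll <- rowSums(expressionLevel(sim$truth))
  names(exprAll) <- rownames(expressionLevel(sim$truth))
  exprB <- setNames(exprAll[names(orthologMap(sim$truth))],
                    unname(orthologMap(sim$truth)))
  idx <- buildIndex(sim$transcripts, 31)
  cross <- mapperConfig(k = 15, maxMismatchRate = 0.12)
  crossIdx <- buildIndex(sim$transcripts, 15)
  rA <- simulateReads(sim$transcripts, sim$truth, "brain", cfg)
  countsA <- countAndCoverage(as.character(rA$mate1),
                              as.character(rA$mate2), idx)
  countsB <- lapply(1:2, function(i) {
    r <- simulateReads(B, sim$truth, "brain", cfg, seed = 30 + i,
                       expression = exprB)
    countAndCoverage(as.character(r$mate1), as.character(r$mate2),
                     crossIdx, cross)
  })
  se <- speciesEnriched(countsA, countsB[[1]], countsB[[2]])
  # planted A-only genes with comfortable read support are recovered
  supported <- aOnly[rowSums(counts(countsA))[aOnly] >= 16]
  expect_gte(length(supported), 1)
  expect_gte(mean(supported %in% se), 0.95)
})

test_that("hypergeometric over-representation and BH correction are exact", {
  population <- sprintf("g%02d", 1:20)
  study <- population[1:5]
  termMap <- data.frame(
    gene = c(population[c(1, 2, 3, 4, 6)]),
    term = "T1")
  res <- goOverrepresentation(study, population, termMap)
  # N=20, K=5, n=5, k=4: p = (C(5,4) C(15,1) + C(5,5) C(15,0)) / C(20,5)
  expect_equal(res$p[res$term == "T1"], 76 / 15504)
  # study = population: p = 1 for every term
  resAll <- goOverrepresentation(population, population, termMap)
  expect_true(all(resAll$p == 1))
  expect_error(goOverrepresentation(c(study, "zz"), population, termMap),
               "zz")
})

test_that("BH adjustment follows the step-up formula and is monotone", {
  pop <- sprintf("g%02d", 1:30)
  # three disjoint terms engineered to give raw p of increasing strength
  termMap <- rbind(
    data.frame(gene = pop[1:4], term = "A"),
    data.frame(gene = c(pop[1:3], pop[10]), term = "B"),
    data.frame(gene = c(pop[1:2], pop[11:12]), term = "C"))
  res <- goOverrepresentation(pop[1:5], pop, termMap)
  expect_identical(res$p_adj,
                   p.adjust(setNames(res$p, res$term), method = "BH"),
                   ignore_attr = TRUE)
  expect_true(all(diff(res$p_adj) >= 0))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(res$p_adj >= res$p))
})
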