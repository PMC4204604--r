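test_that("generateGenome honours lengths, contigs and determinism", {
  g <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
  expect_s4_class(g, "BisGenome")
  expect_length(g, 2L)
  expect_equal(sum(width(genomeSequences(g))), 2500)
  g2 <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
  expect_identical(as.character(genomeSequences(g)),
                   as.character(genomeSequences(g2)))
  g3 <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 8)
  expect_false(identical(as.character(genomeSequences(g)),
                         as.character(genomeSequences(g3))))

  expect_error(generateGenome(1, 1000, c(0.3, 0.5), 500, seed = 1),
               "nRegions")
  expect_error(generateGenome(2, 50, c(0.3, 0.5), 500, seed = 1),
               "regionLength")
  expect_error(generateGenome(2, 1000, c(0, 0.5), 500, seed = 1),
               "gcGradient")
})

test_that("realized GC of a flat-gradient genome matches its target", {
  g <- generateGenome(10, 10000, c(0.30, 0.30), 500, seed = 42)
  main <- as.character(genomeSequences(g)[["chr_sim"]])
  expect_lt(abs(gcContent(main) - 0.30), 0.02)
})

test_that("cytosine contexts follow the CG/CHG/CHH definitions", {
  g <- literalGenome(c(main = "ACGT", ctrl = "AAAT"))
  s <- cytosineSites(g)
  plus <- s[strand(s) == "+" & seqnames(s) == "main"]
  expect_equal(start(plus), 2L)
  expect_equal(as.character(mcols(plus)$context), "CG")

  g2 <- literalGenome(c(main = "ACAGT", ctrl = "AAAT"))
  s2 <- cytosineSites(g2)
  plus2 <- s2[strand(s2) == "+" & seqnames(s2) == "main"]
  expect_equal(start(plus2), 2L)
  expect_equal(as.character(mcols(plus2)$context), "CHG")

  # minus strand: the G at position 3 of ACGT is a CG-context C
  minus <- s[strand(s) == "-" & seqnames(s) == "main"]
  expect_equal(start(minus), 3L)
  expect_equal(as.character(mcols(minus)$context), "CG")
})

test_that("generateMethylome assigns region probabilities, control is 0", {
  g <- generateGenome(2, 1000, c(0.3, 0.5), 500, seed = 7)
  m <- cbind(CG = c(1, 0.5), CHG = c(0.8, 0.2), CHH = c(0.1, 0))
  truth <- generateMethylome(g, m)
  # every C on the stated strand really is a C
  seqs <- genomeSequences(g)
  base <- mapply(function(ctg, pos) substring(as.character(seqs[[ctg]]),
                                              pos, pos),
                 as.character(seqnames(truth)), start(truth))
  expect_true(all(ifelse(strand(truth) == "+", base == "C", base == "G")))
  # control contig all zero
  expect_true(all(mcols(truth)$prob[
    as.character(seqnames(truth)) == controlContig(g)] == 0))
  # region/context assignment
  reg <- genomeRegions(g)
  r1 <- truth[seqnames(truth) == "chr_sim" & start(truth) <= 1000]
  expect_true(all(mcols(r1)$prob ==
    m[1, as.character(mcols(r1)$context)]))
  r2 <- truth[seqnames(truth) == "chr_sim" & start(truth) > 1000]
  expect_true(all(mcols(r2)$prob ==
    m[2, as.character(mcols(r2)$context)]))
  # all-zero triples give an all-zero methylome
  t0 <- generateMethylome(g, cbind(CG = c(0, 0), CHG = c(0, 0),
                                   CHH = c(0, 0)))
  expect_true(all(mcols(t0)$prob == 0))
  expect_error(generateMethylome(g, m[1, , drop = FALSE]), "one row per")
})

test_that("simulateFragments respects bounds and contig weighting", {
  g <- literalGenome(c(main = strrep("ACGT", 25), ctrl = strrep("AT", 50)))
  expect_length(readSequences(simulateFragments(g, 0, 50, seed = 1)), 0L)
  p <- simulateFragments(g, 500, 50, seed = 1)
  o <- fragmentOrigins(p)
  expect_true(all(o$start >= 1L & o$start <= 51L))
  expect_error(simulateFragments(g, 10, 101, seed = 1), "exceeds")

  gw <- generateGenome(9, 10000, c(0.4, 0.4), 10000, seed = 3)
  pw <- simulateFragments(gw, 10000, 50, seed = 4)
  frac2 <- mean(fragmentOrigins(pw)$contig == controlContig(gw))
  expect_lt(abs(frac2 - 0.10), 0.01)
})

test_that("minus-strand fragments carry the reverse-complemented sequence", {
  g <- literalGenome(c(main = "ACGTACGTAC", ctrl = "ATATATATAT"))
  p <- simulateFragments(g, 200, 4, seed = 5)
  o <- fragmentOrigins(p)
  i <- which(o$strand == "-" & o$contig == "main")[1]
  ref <- substring("ACGTACGTAC", o$start[i], o$start[i] + 3L)
  expect_equal(readSequences(p)[i],
               as.character(reverseComplement(DNAString(ref))))
})

test_that("bisulfiteConvert realizes forced and null outcomes exactly", {
  pool <- newFragmentPool("main", 1, "+", "ACGCT")
  truth <- literalTruth("main", c(2, 4), "+", c("CG", "CHH"), c(1, 0))
  out <- bisulfiteConvert(pool, truth, 0, seed = 1)
  expect_equal(readSequences(out), "ACGTT")
  expect_true(out@converted)

  # C-free fragments pass through unchanged
  poolN <- newFragmentPool("main", 1, "+", "AGGT")
  outN <- bisulfiteConvert(poolN, literalTruth("main", integer(), "+",
                                               character(), numeric()),
                           0.01, seed = 1)
  expect_equal(readSequences(outN), "AGGT")

  # a fragment C without a truth record is a consistency error
  expect_error(bisulfiteConvert(newFragmentPool("main", 1, "+", "ACGCT"),
                                literalTruth("main", 2, "+", "CG", 1),
                                0, seed = 1),
               "consistency")
})

test_that("non-conversion retains the expected number of cytosines", {
  seqn <- strrep("CA", 10000)  # 10,000 CHH cytosines on the plus strand
  pool <- newFragmentPool("main", 1, "+", seqn)
  truth <- literalTruth("main", seq(1, 19999, by = 2), "+", "CHH", 0)
  out <- bisulfiteConvert(pool, truth, 0.005, seed = 11)
  retained <- lengths(regmatches(readSequences(out),
                                 gregexpr("C", readSequences(out))))
  expect_gte(retained, 50 - 15)
  expect_lte(retained, 50 + 15)
})

test_that("conversion never increases GC and is seed-deterministic", {
  g <- generateGenome(4, 1000, c(0.3, 0.5), 500, seed = 2)
  truth <- generateMethylome(g, defaultMeth <- cbind(
    CG = c(0.9, 0.6, 0.3, 0.1), CHG = c(0.7, 0.4, 0.2, 0.05),
    CHH = c(0.3, 0.2, 0.1, 0.02)))
  pool <- simulateFragments(g, 500, 80, seed = 3)
  c1 <- bisulfiteConvert(pool, truth, 0.01, seed = 4)
  c2 <- bisulfiteConvert(pool, truth, 0.01, seed = 4)
  expect_identical(readSequences(c1), readSequences(c2))
  expect_true(all(gcContent(readSequences(c1)) <=
                  gcContent(readSequences(pool))))
})

test_that("amplification weights follow (1 + e(g))^cycles", {
  prof <- enzymeProfile("two-point", baseEfficiency = 0.7,
                        gcCoefficient = 1)
  # fragments at GC 0.7 and 0.3 have e = 0.9 and 0.5
  pool <- newFragmentPool(c("m", "m"), c(1, 11), c("+", "+"),
                          c("GGGGGGGAAA", "GGGAAAAAAA"))
  expect_equal(amplificationEfficiency(prof, c(0.7, 0.3)), c(0.9, 0.5))

  lib <- amplifyAndSample(pool, prof, 15, 100000, seed = 9)
  share <- mean(readSequences(lib) == "GGGGGGGAAA")
  expect_lt(abs(share - 1.9^15 / (1.9^15 + 1.5^15)), 0.002)

  # cycles = 0: uniform regardless of efficiency
  lib0 <- amplifyAndSample(pool, prof, 0, 100000, seed = 9)
  expect_lt(abs(mean(readSequences(lib0) == "GGGGGGGAAA") - 0.5), 0.005)

  # constant efficiency: uniform regardless of cycles
  flat <- enzymeProfile("flat", baseEfficiency = 1, gcCoefficient = 0)
  libF <- amplifyAndSample(pool, flat, 15, 100000, seed = 9)
  expect_lt(abs(mean(readSequences(libF) == "GGGGGGGAAA") - 0.5), 0.005)

  emptyPool <- simulateFragments(
    literalGenome(c(main = "ACGTACGT", ctrl = "ATATATAT")), 0, 4, seed = 1)
  expect_error(amplifyAndSample(emptyPool, prof, 4, 10, seed = 1), "empty")
  lA <- amplifyAndSample(pool, prof, 8, 500, seed = 3)
  lB <- amplifyAndSample(pool, prof, 8, 500, seed = 3)
  expect_identical(readSequences(lA), readSequences(lB))
  expect_identical(fragmentOrigins(lA), fragmentOrigins(lB))
})

test_that("enzyme presets exist and saturation clamps efficiency flat", {
  expect_equal(enzymeProfile("kapa-like")@gcCoefficient, 0)
  expect_equal(enzymeProfile("pfu-like")@gcCoefficient, 0.8)
  epi <- enzymeProfile("epimark-like")
  expect_equal(epi@saturationGC, 0.6)
  expect_equal(amplificationEfficiency(epi, 0.8),
               amplificationEfficiency(epi, 0.6))
  expect_lt(amplificationEfficiency(epi, 0.4),
            amplificationEfficiency(epi, 0.6))
  expect_error(enzymeProfile("nope"), "preset")
})

test_that("with zero GC coefficient read counts are exchangeable over GC", {
  # chi-square of per-GC-decile read counts against pool proportions:
  # non-significant at alpha = 0.01 in >= 95% of 100 seeded runs
  g <- generateGenome(4, 2000, c(0.3, 0.5), 1000, seed = 21)
  truth <- generateMethylome(g, cbind(CG = c(0.9, 0.6, 0.3, 0.1),
                                      CHG = c(0.7, 0.4, 0.2, 0.05),
                                      CHH = c(0.3, 0.2, 0.1, 0.02)))
  pool <- simulateFragments(g, 2000, 80, seed = 22)
  pool <- bisulfiteConvert(pool, truth, 0.005, seed = 23)
  gc <- gcContent(readSequences(pool))
  breaks <- unique(quantile(gc, probs = seq(0, 1, 0.1)))
  bin <- cut(gc, breaks, include.lowest = TRUE)
  flat <- enzymeProfile("kapa-like")
  ok <- vapply(1:100, function(s) {
    lib <- amplifyAndSample(pool, flat, 8, 5000, seed = 1000 + s)
    obs <- table(bin[match(readSequences(lib), readSequences(pool))])
    suppressWarnings(chisq.test(obs, p = as.numeric(table(bin)) /
                                  length(gc))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("methylated-window read share is non-decreasing in cycles", {
  g <- generateGenome(4, 2000, c(0.34, 0.40), 1000, seed = 31)
  truth <- generateMethylome(g, cbind(CG = c(0.9, 0.9, 0.1, 0.1),
                                      CHG = c(0.7, 0.7, 0.05, 0.05),
                                      CHH = c(0.3, 0.3, 0.02, 0.02)))
  shares <- sapply(1:20, function(s) {
    pool <- simulateFragments(g, 2000, 80, seed = 300 + s)
    pool <- bisulfiteConvert(pool, truth, 0.005, seed = 600 + s)
    vapply(c(4, 8, 15), function(cyc) {
      lib <- amplifyAndSample(pool, enzymeProfile("pfu-like"), cyc, 5000,
                              seed = 900 + s)
      o <- fragmentOrigins(lib)
      mean(o$contig == "chr_sim" & o$start <= 4000)
    }, numeric(1))
  })
  m <- rowMeans(shares)
  expect_lte(m[1], m[2])
  expect_lte(m[2], m[3])
})
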