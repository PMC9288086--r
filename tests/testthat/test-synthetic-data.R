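test_that("annotation generation honours class counts, lengths and determinism", {
  n <- c(GH = 258, CE = 52, AA = 57, PL = 6, GT = 97, `non-CAZyme` = 30)
  ann <- generateAnnotation(n, seed = 7)
  expect_equal(nrow(ann), 500)
  expect_equal(as.integer(table(ann$enzyme_class)[names(n)]), unname(n))
  expect_equal(sum(ann$enzyme_class != "non-CAZyme"), 470)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$length_bp >= 600 & ann$length_bp <= 6000))
  # non-CAZyme genes never carry an enzyme functional group
  expect_true(all(ann$functional_group[ann$enzyme_class == "non-CAZyme"] %in%
                  c("other", "unknown")))
  expect_identical(ann, generateAnnotation(n, seed = 7))
  expect_equal(nrow(generateAnnotation(c(GH = 0), seed = 1)), 0)
  expect_error(generateAnnotation(c(GH = -1), seed = 1), "non-negative")
})

test_that("design is the full factorial plus per-strain baselines", {
  d3 <- generateDesign(3)
  expect_equal(nrow(d3), 60)  # 2*3*3*3 + 2*3
  expect_equal(nrow(generateDesign(2)), 40)  # 2*3*3*2 + 2*2 by enumeration
  expect_false(anyDuplicated(d3$sample_id) > 0)
  expect_true(all(d3$time_h[d3$carbon == "baseline_glucose"] == 0))
  expect_true(all(d3$time_h[d3$carbon != "baseline_glucose"] %in% c(4, 24, 72)))
  reps <- table(d3$strain, d3$carbon, d3$time_h)
  expect_true(all(reps[reps > 0] >= 2))
  expect_error(generateDesign(1), ">= 2")
})

test_that("planted architecture respects the group invariants", {
  fx <- smallExperiment(seed = 3)
  arch <- fx$arch
  expect_silent(validObject(arch))
  fc <- plantedLog2FC(arch)
  grp <- trueGroups(arch)
  # knockout silencing and CS-level forcing
  for (g in names(grp[grp == "XYR1_SPECIFIC"]))
    expect_true(all(fc[g, "xyr1_KO", , ] == 0))
  for (g in names(grp[grp == "XYR1_CS_CO"])) {
    cs <- fc[g, "WT", "no_carbon", 1]
    expect_true(all(abs(fc[g, "xyr1_KO", , ] - cs) < 1e-12))
    expect_true(all(fc[g, "WT", c("avicel", "xylan"), ] > cs))
  }
  for (g in names(grp[grp == "CS_CONTROLLED"]))
    expect_equal(length(unique(as.vector(fc[g, , , ]))), 1)
  for (g in names(grp[grp == "NON_INDUCIBLE"]))
    expect_true(all(fc[g, , , ] == 0))
  # knockout-silenced genes sit below the expression floor at baseline
  expect_true(all(baselineMeans(arch)[names(grp[grp == "XYR1_SPECIFIC"])] < 2))
  # all-zero group sizes -> everything non-inducible
  arch0 <- plantArchitecture(fx$ann, c(CS_CONTROLLED = 0), seed = 1)
  expect_true(all(trueGroups(arch0) == "NON_INDUCIBLE"))
  expect_error(plantArchitecture(fx$ann, c(CS_CONTROLLED = 10000), seed = 1),
               "oversubscribe")
})

test_that("count simulation matches its planted means", {
  # Poisson limit: dispersion 0, mean 100
  draws <- lignoReg:::.nbDraw(10000, 100, 0)
  expect_true(mean(draws) > 97 && mean(draws) < 103)
  # NB marginal mean within 3 standard errors at n = 10000
  set.seed(11)
  mu <- 50; disp <- 0.05
  nb <- lignoReg:::.nbDraw(10000, mu, disp)
  se <- sqrt(mu + disp * mu^2) / sqrt(10000)
  expect_lt(abs(mean(nb) - mu), 3 * se)

  fx <- smallExperiment(seed = 5)
  counts <- SummarizedExperiment::assay(fx$x, "counts")
  expect_true(all(counts >= 0))
  des <- fx$des; arch <- fx$arch
  # planted log2FC ~3 recovered from replicate-mean counts within 20%
  grp <- trueGroups(arch)
  g <- names(grp[grp == "CS_CONTROLLED"])[1]
  lfc <- plantedLog2FC(arch)[g, "WT", "avicel", "24h"]
  base_cols <- des$sample_id[des$strain == "WT" & des$carbon == "baseline_glucose"]
  ind_cols <- des$sample_id[des$strain == "WT" & des$carbon == "avicel" & des$time_h == 24]
  ratio <- mean(counts[g, ind_cols]) / mean(counts[g, base_cols])
  expect_lt(abs(ratio / 2^lfc - 1), 0.35)
  # non-inducible genes show no systematic shift across carbons
  ni <- names(grp[grp == "NON_INDUCIBLE" & names(grp) %in%
                  fx$ann$gene_id[fx$ann$enzyme_class != "non-CAZyme"]])
  r <- rowMeans(counts[ni, ind_cols, drop = FALSE]) /
       rowMeans(counts[ni, base_cols, drop = FALSE])
  expect_lt(abs(median(r) - 1), 0.25)
  # determinism
  x2 <- simulateCounts(arch, des, 2e7, seed = 5 + 1000, annotation = fx$ann)
  expect_identical(counts, SummarizedExperiment::assay(x2, "counts"))
})

test_that("secretome simulation reproduces planted levels and ratios", {
  truth <- data.frame(protein_id = c("a", "b", "c"),
                      functional_group = "cellulase", is_cazyme = TRUE,
                      n_peptides = c(5, 3, 4),
                      AIEP_level = c(1000, 0, 300),
                      XIEP_level = c(100, 50, 300))
  pep <- simulateSecretome(truth, noise_cv = 0.2, seed = 9)
  expect_true(all(pep$area >= 0))
  # zero planted level -> all-zero areas
  expect_true(all(pep$area[pep$protein_id == "b" & pep$condition == "AIEP"] == 0))
  # summed peptide areas recover the planted level within noise
  ab <- SummarizedExperiment::assay(proteinAbundance(pep), "abundance")
  expect_lt(abs(mean(ab["a", grepl("AIEP", colnames(ab))]) / 1000 - 1), 0.3)
  # a 10-fold planted protein yields a downstream ratio in [5, 20]
  # (no median step: a 3-protein table has no stable median)
  en <- enrichmentCall(proteinAbundance(pep))
  expect_true(en$mean_ratio[en$protein_id == "a"] > 5 &&
              en$mean_ratio[en$protein_id == "a"] < 20)
  expect_identical(pep, simulateSecretome(truth, noise_cv = 0.2, seed = 9))
})

test_that("activity curves are logistic with the documented kinetics", {
  act <- simulateActivity(3.84, noise_cv = 0, seed = 1)
  one <- act[act$replicate == 1, ]
  expect_false(is.unsorted(one$activity_U_per_mL))  # noiseless: monotone
  pf <- plateauFraction(one$activity_U_per_mL)
  expect_gt(pf$fraction[one$time_h == 16], 0.95)
  expect_true(abs(pf$fraction[one$time_h == 9] - 0.6) < 0.05)
  zero <- simulateActivity(0, seed = 1)
  expect_true(all(zero$activity_U_per_mL == 0))
})
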