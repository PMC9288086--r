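test_that("protein abundance sums peptides and is order-invariant", {
  pep <- data.frame(
    peptide_id = c("p1", "p2", "p3", "q1", "p1", "p2", "p3", "q1"),
    protein_id = c("A", "A", "A", "B", "A", "A", "A", "B"),
    sample_id = rep(c("s1", "s2"), each = 4),
    condition = rep(c("AIEP", "XIEP"), each = 4),
    replicate = 1,
    area = c(3, 5, 2, 7, 1, 1, 1, 0))
  ab <- SummarizedExperiment::assay(proteinAbundance(pep), "abundance")
  expect_equal(ab["A", "s1"], 10)
  expect_equal(ab["B", "s2"], 0)
  perm <- pep[sample(nrow(pep)), ]
  expect_equal(SummarizedExperiment::assay(proteinAbundance(perm), "abundance"), ab)
  bad <- pep; bad$protein_id[4] <- "A"  # q1 would map to both A and B
  expect_error(proteinAbundance(bad), "more than one protein")
})

test_that("median normalization equalizes medians and is scale invariant", {
  # 5-protein toy table with sample medians 10 and 20: grand median 15,
  # scale factors 1.5 and 0.75
  m <- cbind(s1 = c(2, 6, 10, 14, 30), s2 = c(4, 12, 20, 28, 60))
  norm <- medianNormalize(m)
  expect_equal(apply(norm, 2, median), c(s1 = 15, s2 = 15))
  expect_equal(norm[, "s1"], c(2, 6, 10, 14, 30) * 1.5)
  # already-equal medians: unchanged
  eq <- cbind(s1 = c(1, 5, 9), s2 = c(2, 5, 40))
  expect_equal(medianNormalize(eq), eq)
  # common rescaling of the input does not change the output
  set.seed(41)
  r <- matrix(rlnorm(50, 3, 1), 10, 5,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:5)))
  expect_equal(medianNormalize(r * 7), medianNormalize(r) * 7)
  # zeros stay zero
  r[1, ] <- 0
  expect_true(all(medianNormalize(r)[1, ] == 0))
  r0 <- r; r0[, 3] <- 0
  expect_error(medianNormalize(r0), "all-zero")
})

test_that("relative abundances sum to 100 and flag the strict >1% cutoff", {
  truth <- defaultSecretomeTruth(seed = 2)
  pep <- simulateSecretome(truth, 0.2, seed = 2)
  se <- medianNormalize(proteinAbundance(pep))
  rel <- relativeAbundance(se)
  expect_equal(unname(colSums(rel$per_sample)), rep(100, 6), tolerance = 1e-9)
  # the planted dominant exoglucanase is flagged highly abundant in AIEP
  expect_gt(max(rel$per_condition$AIEP), 10)
  expect_true(rel$per_condition$high_AIEP[which.max(rel$per_condition$AIEP)])
  # boundary: exactly 1.00% is not flagged (strict >)
  m <- cbind(s1 = c(1, 99), s2 = c(1, 99))
  rownames(m) <- c("low", "hi")
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m),
    colData = S4Vectors::DataFrame(condition = c("AIEP", "AIEP"),
                                   row.names = colnames(m)))
  r2 <- relativeAbundance(se2, high_cutoff_pct = 1)
  expect_false(r2$per_condition$high_AIEP[r2$per_condition$protein_id == "low"])
  # N equal proteins -> each 100/N
  m3 <- matrix(5, 4, 2, dimnames = list(paste0("p", 1:4), c("a", "b")))
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m3),
    colData = S4Vectors::DataFrame(condition = c("AIEP", "XIEP"),
                                   row.names = c("a", "b")))
  expect_true(all(relativeAbundance(se3)$per_sample == 25))
})

test_that("enrichment calls are correct at the boundaries and antisymmetric", {
  truth <- defaultSecretomeTruth(seed = 3)
  pep <- simulateSecretome(truth, 0.2, seed = 3)
  se <- medianNormalize(proteinAbundance(pep))
  en <- enrichmentCall(se)
  # swapping the condition labels inverts ratios and swaps classes exactly
  se_sw <- se
  cd <- SummarizedExperiment::colData(se_sw)
  cd$condition <- ifelse(cd$condition == "AIEP", "XIEP", "AIEP")
  SummarizedExperiment::colData(se_sw) <- cd
  en_sw <- enrichmentCall(se_sw)
  expect_equal(en_sw$mean_ratio, 1 / en$mean_ratio, tolerance = 1e-12)
  expect_equal(en_sw$p_value, en$p_value, tolerance = 1e-12)
  map <- c(AIEP_enriched = "XIEP_enriched", XIEP_enriched = "AIEP_enriched",
           no_difference = "no_difference")
  expect_identical(unname(map[en$class]), en_sw$class)
  # identical replicate sets: ratio 1, no difference
  m <- matrix(rep(c(5, 6, 7), 2), 1, 6,
              dimnames = list("p", paste0("s", 1:6)))
  se_id <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m),
    colData = S4Vectors::DataFrame(condition = rep(c("AIEP", "XIEP"), each = 3),
                                   row.names = colnames(m)))
  en_id <- enrichmentCall(se_id)
  expect_equal(en_id$mean_ratio, 1)
  expect_identical(en_id$class, "no_difference")
  # all-zero denominator: capped ratio, still called
  m0 <- rbind(p = c(100, 110, 90, 0, 0, 0), q = c(5, 6, 7, 5, 6, 7))
  colnames(m0) <- paste0("s", 1:6)
  se0 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m0),
    colData = S4Vectors::DataFrame(condition = rep(c("AIEP", "XIEP"), each = 3),
                                   row.names = colnames(m0)))
  en0 <- enrichmentCall(se0)
  expect_lte(en0$mean_ratio[1], 1000)
  expect_identical(en0$class[1], "AIEP_enriched")
})

test_that("group summary tabulates the nine groups and partitions the calls", {
  calls <- data.frame(protein_id = paste0("c", 1:4),
                      mean_ratio = c(2.42, 3.1, 5.88, 1.05),
                      p_value = c(0.001, 0.002, 0.001, 0.6),
                      class = c("AIEP_enriched", "AIEP_enriched",
                                "AIEP_enriched", "no_difference"))
  ann <- data.frame(protein_id = paste0("c", 1:4), functional_group = "chitinase")
  s <- groupRatioSummary(calls, ann)
  chit <- s[s$functional_group == "chitinase", ]
  expect_equal(unlist(chit[, c("n", "n_AIEP_enriched", "n_XIEP_enriched",
                               "n_no_difference")], use.names = FALSE),
               c(4, 3, 0, 1))
  expect_equal(nrow(s), 9)           # all nine groups, empty ones included
  expect_equal(sum(s$n), nrow(calls))
  expect_error(groupRatioSummary(calls,
    data.frame(protein_id = paste0("c", 1:4), functional_group = "mystery")),
    "unknown functional group")
})

test_that("CAZyme entries of a processed table are counted through all columns", {
  df <- data.frame(protein_id = c("a", "b", "c", "d"),
                   is_cazyme = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(countCazymeEntries(df), 3)
  tf <- tempfile(fileext = ".tsv")
  writePeptideTable(data.frame(protein_id = c("a", "b"),
                               cazy_class = c("GH", "none")), tf)
  expect_equal(countCazymeEntries(tf), 1)
  expect_equal(countCazymeEntries(
    data.frame(protein_id = 1:3, family = c("GH10", "hypothetical", "CBM1"))), 2)
  expect_error(countCazymeEntries(data.frame(protein_id = "a")), "annotation column")
})
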