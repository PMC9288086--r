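test_that("differential statistic matches hand arithmetic and the Welch oracle", {
  d <- differentialStat(c(1, 1, 1), c(15, 16, 17), pseudocount = 1)
  expect_equal(d$log2fc, log2(17 / 2))  # mean 16 -> (16+1)/(1+1)
  same <- differentialStat(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$log2fc, 0)
  const <- differentialStat(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  expect_error(differentialStat(1, c(1, 2)), ">= 2")
  # p-values agree with an independently coded Welch test to 1e-9
  set.seed(33)
  for (i in 1:100) {
    a <- rlnorm(sample(3:6, 1), 2, 1)
    b <- rlnorm(sample(3:6, 1), 2.5, 1)
    d <- differentialStat(a, b)
    expect_equal(d$p_value, welchOracle(log2(b + 1), log2(a + 1)),
                 tolerance = 1e-9)
  }
})

test_that("threshold boundaries follow the inclusive-fold, strict-floor rules", {
  # build a two-gene experiment where replicate means hit the boundaries
  des <- generateDesign(3)
  ann <- data.frame(gene_id = c("fold4", "fold37", "lowexpr"),
                    length_bp = 1000, enzyme_class = "GH", family = "GH5",
                    functional_group = "other_GH")
  expr <- matrix(0, 3, nrow(des), dimnames = list(ann$gene_id, des$sample_id))
  base_wt <- des$sample_id[des$strain == "WT" & des$carbon == "baseline_glucose"]
  av24 <- des$sample_id[des$strain == "WT" & des$carbon == "avicel" & des$time_h == 24]
  # exact 4-fold on pseudocount means: baseline 1 -> induced (4*(1+1))-1 = 7
  expr["fold4", base_wt] <- c(0.9, 1.0, 1.1); expr["fold4", av24] <- c(6.8, 7.0, 7.2)
  expr["fold37", base_wt] <- c(0.9, 1.0, 1.1); expr["fold37", av24] <- c(6.5, 6.7, 6.9)
  expr["lowexpr", base_wt] <- c(0.05, 0.1, 0.15); expr["lowexpr", av24] <- c(1.4, 1.5, 1.6)
  counts <- matrix(1L, 3, nrow(des), dimnames = dimnames(expr))
  x <- cazymeExperiment(counts, ann, des)
  SummarizedExperiment::assay(x, "rpkm") <- expr
  calls <- callInduction(x, inductionThresholds())
  get <- function(g) calls[calls$gene_id == g & calls$strain == "WT" &
                           calls$carbon == "avicel", ]
  expect_equal(get("fold4")$log2fc, 2)      # boundary: log2FC exactly 2
  expect_true(get("fold4")$induced)          # inclusive >=
  expect_false(get("fold37")$induced)        # log2fc just below 2
  expect_false(get("lowexpr")$induced)       # high fold but RPKM floor strict
  strict <- callInduction(x, inductionThresholds(strict_fold = TRUE))
  expect_false(strict[strict$gene_id == "fold4" & strict$strain == "WT" &
                      strict$carbon == "avicel", "induced"])
})

test_that("relaxing any threshold never shrinks the induced set", {
  fx <- smallExperiment(seed = 13)
  caz <- fx$ann$gene_id[fx$ann$enzyme_class != "non-CAZyme"]
  base <- callInduction(fx$x, inductionThresholds(), genes = caz)
  relaxed <- list(inductionThresholds(min_abs_log2fc = 1),
                  inductionThresholds(max_p = 0.05),
                  inductionThresholds(min_expr = 0.5))
  for (thr in relaxed) {
    r <- callInduction(fx$x, thr, genes = caz)
    expect_true(all(r$induced[base$induced]))
  }
})

test_that("planted induction is recovered with few false positives", {
  fx <- smallExperiment(seed = 17, n_gh = 60,
                        groups = c(CS_CONTROLLED = 15, XYR1_SPECIFIC = 8))
  caz <- fx$ann$gene_id[fx$ann$enzyme_class != "non-CAZyme"]
  calls <- callInduction(fx$x, genes = caz)
  grp <- trueGroups(fx$arch)
  fc <- plantedLog2FC(fx$arch)
  wt <- calls[calls$strain == "WT", ]
  planted_pairs <- 0; called_pairs <- 0; fp <- 0; ni_pairs <- 0
  for (i in seq_len(nrow(wt))) {
    planted <- fc[wt$gene_id[i], "WT", wt$carbon[i], 1] >= 3
    if (planted) {
      planted_pairs <- planted_pairs + 1
      called_pairs <- called_pairs + wt$induced[i]
    }
    if (grp[wt$gene_id[i]] == "NON_INDUCIBLE") {
      ni_pairs <- ni_pairs + 1
      fp <- fp + wt$induced[i]
    }
  }
  expect_gte(called_pairs / planted_pairs, 0.95)
  expect_lte(fp / ni_pairs, 0.01)
})

test_that("per-class percentages match the rational-arithmetic rule", {
  # the printed-count pairs and half-away-from-zero rounding
  pairs <- list(c(106, 258, 41.1), c(14, 52, 26.9), c(11, 57, 19.3),
                c(1, 6, 16.7), c(5, 97, 5.2), c(0, 10, 0))
  for (p in pairs) expect_equal(classPercent(p[1], p[2], 1), p[3])
  expect_equal(classPercent(1, 8, 1), 12.5)
  expect_equal(roundHalfAway(0.125 * 100, 0), 13)  # half rounds away from zero
  expect_equal(roundHalfAway(-12.5, 0), -13)
  # rational oracle over many (n, N)
  set.seed(5)
  for (i in 1:50) {
    N <- sample(1:500, 1); n <- sample(0:N, 1)
    exact <- 100 * n / N
    expect_equal(classPercent(n, N, 1),
                 sign(exact) * floor(abs(exact) * 10 + 0.5) / 10)
  }
  expect_warning(out <- classPercent(0, 0), "zero totals")
  expect_equal(out, 0)
})

test_that("family summary counts WT polysaccharide induction only", {
  calls <- expand.grid(gene_id = c("g1", "g2", "g3", "g4"),
                       strain = c("WT", "xyr1_KO"),
                       carbon = c("no_carbon", "avicel", "xylan"),
                       stringsAsFactors = FALSE)
  calls$induced <- FALSE
  calls$induced[calls$gene_id == "g1" & calls$strain == "WT" & calls$carbon == "avicel"] <- TRUE
  calls$induced[calls$gene_id == "g2" & calls$strain == "WT" & calls$carbon == "no_carbon"] <- TRUE
  calls$induced[calls$gene_id == "g3" & calls$strain == "xyr1_KO" & calls$carbon == "xylan"] <- TRUE
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    enzyme_class = c("GH", "GH", "CE", "CE"))
  s <- familyInductionSummary(calls, ann)
  expect_equal(s$n_induced[s$enzyme_class == "GH"], 1)  # CS-only and KO-only do not count
  expect_equal(s$n_induced[s$enzyme_class == "CE"], 0)
  expect_equal(s$percent[s$enzyme_class == "GH"], 50)
})
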