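# Shared fixtures: a small planted experiment exercising every regulatory
# group, and an independently coded Welch t-test (the reference oracle).

smallExperiment <- function(seed = 1, n_gh = 40, n_bg = 20,
                            groups = c(CS_CONTROLLED = 10, XYR1_SPECIFIC = 5,
                                       OTHER_SPECIFIC = 2, XYR1_CS_CO = 2,
                                       OTHER_CS_CO = 1)) {
  ann <- generateAnnotation(c(GH = n_gh, CE = 5, `non-CAZyme` = n_bg), seed = seed)
  des <- generateDesign(3)
  arch <- plantArchitecture(ann, groups, seed = seed)
  x <- simulateCounts(arch, des, 2e7, seed = seed + 1000, annotation = ann)
  list(ann = ann, des = des, arch = arch, x = computeRPKM(x))
}

# independently coded rule table for the five-group decision procedure:
# a literal transcription of the narrative, structured as a lookup over the
# WT induction facts rather than the package's nested branching
oracleGroup <- function(wt_nc, wt_av, wt_xy, ko_any, poly_vs_cs,
                        ko_poly_vs_cs, ko_low) {
  wt_poly <- wt_av | wt_xy
  pattern <- paste0(as.integer(wt_poly), as.integer(wt_nc))
  switch(pattern,
    "00" = "NON_INDUCIBLE",
    "01" = "CS_CONTROLLED",  # cs_only flag case
    "10" = if (!ko_any && ko_low) "XYR1_SPECIFIC" else "OTHER_SPECIFIC",
    "11" = if (poly_vs_cs == "not_different") "CS_CONTROLLED"
           else if (ko_poly_vs_cs == "not_different") "XYR1_CS_CO"
           else "OTHER_CS_CO")
}

# Welch two-sample t-test written from the textbook formulas, independent of
# stats::t.test (which the package uses internally)
welchOracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1) / length(a)
  vb <- sum((b - mean(b))^2) / (length(b) - 1) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}
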