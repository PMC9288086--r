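# Synthetic-data generator: annotation, factorial design, planted regulatory
# architecture, and negative-binomial count simulation with known ground truth.

# family -> functional-group lookup used when sampling annotations
.FAMILY_POOL <- list(
  GH = c(GH1 = "other_GH", GH2 = "mannanase", GH3 = "cellulase",
         GH5 = "cellulase", GH6 = "cellulase", GH7 = "cellulase",
         GH10 = "xylanase", GH11 = "xylanase", GH12 = "cellulase",
         GH13 = "other_GH", GH16 = "other_GH", GH17 = "other_GH",
         GH18 = "chitinase", GH20 = "chitinase", GH26 = "mannanase",
         GH27 = "other_hemicellulase", GH30 = "xylanase",
         GH31 = "other_GH", GH32 = "other_GH", GH35 = "other_hemicellulase",
         GH36 = "other_hemicellulase", GH43 = "xylanase",
         GH45 = "cellulase", GH47 = "other_GH", GH51 = "other_hemicellulase",
         GH54 = "other_hemicellulase", GH55 = "other_GH",
         GH62 = "xylanase", GH71 = "other_GH", GH72 = "other_GH",
         GH74 = "other_hemicellulase", GH76 = "other_GH",
         GH78 = "other_GH", GH79 = "other_GH", GH92 = "other_GH"),
  CE = c(CE1 = "xylanase", CE3 = "xylanase", CE5 = "xylanase",
         CE8 = "other_hemicellulase", CE12 = "other_hemicellulase",
         CE15 = "other_hemicellulase", CE16 = "other_hemicellulase"),
  AA = c(AA1 = "other", AA2 = "other", AA3 = "other", AA7 = "other",
         AA9 = "cellulase", AA11 = "other"),
  PL = c(PL1 = "other", PL3 = "other", PL4 = "other"),
  GT = c(GT1 = "other", GT2 = "other", GT4 = "other", GT8 = "other",
         GT20 = "other", GT32 = "other", GT48 = "other"),
  `CBM-only` = c(CBM1 = "other", CBM13 = "unknown", CBM18 = "other",
                 CBM50 = "unknown"),
  `non-CAZyme` = c(none = "other", none2 = "unknown"))

#' Generate a synthetic gene annotation table
#'
#' Draws a per-gene annotation (length, CAZyme class, family, functional
#' group) with the requested number of genes per enzyme class. Families are
#' sampled from a fixed pool per class and mapped to functional groups
#' (cellulase, xylanase, chitinase, mannanase, other hemicellulase, other GH,
#' other, unknown); non-CAZyme genes always map to other/unknown.
#'
#' @param n_per_class named integer vector; names among GH, CE, AA, PL, GT,
#'   CBM-only, non-CAZyme. Defaults emulate a CAZyme complement of 476 genes
#'   plus 1500 background genes.
#' @param seed integer random seed.
#' @param length_range sampled gene length range in bp (default 600-6000).
#' @return data.frame with columns gene_id, length_bp, enzyme_class, family,
#'   functional_group.
#' @examples
#' ann <- generateAnnotation(c(GH = 10, `non-CAZyme` = 2), seed = 1)
#' table(ann$enzyme_class)
#' @export
generateAnnotation <- function(n_per_class = c(GH = 258, CE = 52, AA = 57,
                                               PL = 6, GT = 97, `CBM-only` = 6,
                                               `non-CAZyme` = 1500),
                               seed = 1, length_range = c(600, 6000)) {
  stopifnot(all(names(n_per_class) %in% .ENZYME_CLASSES))
  if (any(n_per_class < 0)) stop("class counts must be non-negative")
  n <- sum(n_per_class)
  if (n == 0) {
    return(data.frame(gene_id = character(), length_bp = integer(),
                      enzyme_class = character(), family = character(),
                      functional_group = character()))
  }
  set.seed(seed)
  cls <- rep(names(n_per_class), n_per_class)
  fam <- character(n)
  grp <- character(n)
  for (cl in unique(cls)) {
    pool <- .FAMILY_POOL[[cl]]
    idx <- which(cls == cl)
    pick <- sample(names(pool), length(idx), replace = TRUE)
    fam[idx] <- if (cl == "non-CAZyme") "none" else pick
    grp[idx] <- unname(pool[pick])
  }
  ord <- order(cls != "non-CAZyme", decreasing = TRUE)  # CAZymes first
  data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    length_bp = as.integer(round(stats::runif(n, length_range[1], length_range[2])))[ord],
    enzyme_class = cls[ord],
    family = fam[ord],
    functional_group = grp[ord],
    stringsAsFactors = FALSE)
}

#' Generate the factorial sample design
#'
#' Full factorial over strain (WT, xyr1_KO) x carbon (no_carbon, avicel,
#' xylan) x time (4, 24, 72 h) x replicates, plus per-strain glucose baseline
#' samples at 0 h.
#'
#' @param n_reps replicates per condition (>= 2; default 3).
#' @return data.frame with sample_id, strain, carbon, time_h, replicate.
#' @examples
#' nrow(generateDesign(3))  # 60
#' @export
generateDesign <- function(n_reps = 3) {
  if (n_reps < 2) stop("n_reps must be >= 2 (replicate tests are impossible otherwise)")
  base <- expand.grid(replicate = seq_len(n_reps), time_h = 0,
                      carbon = "baseline_glucose", strain = .STRAINS,
                      stringsAsFactors = FALSE)
  ind <- expand.grid(replicate = seq_len(n_reps), time_h = .TIMES_INDUCED,
                     carbon = .CARBONS_INDUCED, strain = .STRAINS,
                     stringsAsFactors = FALSE)
  d <- rbind(base, ind)[, c("strain", "carbon", "time_h", "replicate")]
  d$sample_id <- sprintf("%s_%s_%dh_r%d", d$strain, d$carbon, d$time_h, d$replicate)
  d[, c("sample_id", "strain", "carbon", "time_h", "replicate")]
}

# truncated lognormal on the log10 scale (resampling truncation)
.rlnormTrunc <- function(n, meanlog10, sdlog10, lower = 0, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- 10^stats::rnorm(length(todo), meanlog10, sdlog10)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Plant a regulatory architecture
#'
#' Assigns every CAZyme gene of an annotation to one of the six regulatory
#' groups and plants baseline expression levels, NB dispersions and log2
#' induction effects consistent with the group semantics: carbon-starvation
#' (CS) controlled genes are induced equally by starvation and both
#' polysaccharides in both strains; regulator-specific genes are induced by
#' polysaccharide only and silenced in the knockout (with a glucose baseline
#' below the expression floor); co-controlled genes are highly induced by the
#' polysaccharides and slightly by starvation, and in the knockout either
#' fall to their CS level (XYR1_CS_CO) or keep the high level (OTHER_CS_CO).
#'
#' Baseline levels are drawn per group: inducible genes have low,
#' catabolite-repressed glucose baselines; knockout-silenced genes sit in
#' U[1, 1.5] RPKM (below the 2-RPKM floor); co-controlled genes are
#' well-expressed when induced (baseline lognormal truncated to
#' [15, 150] RPKM); non-inducible CAZymes and background genes follow a
#' lognormal with log10 mean 1.5, sd 0.6. Two non-inducible CAZymes are set
#' to high constitutive baselines (167 and 676 RPKM) as housekeeping-like
#' fixtures. Background (non-CAZyme) baselines are rescaled so that the
#' expected library totals 1e6 RPKM-kb units, putting planted baselines on
#' the column-sum RPKM scale.
#'
#' @param annotation annotation data.frame from \code{\link{generateAnnotation}}.
#' @param group_sizes named integer vector of planted group sizes; unassigned
#'   CAZyme genes become NON_INDUCIBLE. Defaults 103/29/4/4/1.
#' @param effect_config list with elements \code{high} (log2FC range of high
#'   induction, default c(3, 5)), \code{slight} (range of slight CS induction
#'   for co-controlled genes, default c(2.45, 2.55)) and \code{co_gap}
#'   (planted separation between high and slight levels of co-controlled
#'   genes, default 2.5, capped so high <= max(high)).
#' @param seed integer random seed.
#' @param dispersion NB dispersion planted for every gene (default 0.05).
#' @return a \linkS4class{RegulatoryArchitecture}.
#' @examples
#' ann <- generateAnnotation(c(GH = 40, `non-CAZyme` = 10), seed = 1)
#' arch <- plantArchitecture(ann, c(CS_CONTROLLED = 10, XYR1_SPECIFIC = 5), seed = 1)
#' table(trueGroups(arch)[ann$gene_id[ann$enzyme_class != "non-CAZyme"]])
#' @export
plantArchitecture <- function(annotation,
                              group_sizes = c(CS_CONTROLLED = 103,
                                              XYR1_SPECIFIC = 29,
                                              OTHER_SPECIFIC = 4,
                                              XYR1_CS_CO = 4,
                                              OTHER_CS_CO = 1),
                              effect_config = list(),
                              seed = 1, dispersion = 0.05) {
  stopifnot(all(names(group_sizes) %in% setdiff(.REGULON_GROUPS, "NON_INDUCIBLE")))
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  cfg <- utils::modifyList(
    list(high = c(3, 5), slight = c(2.45, 2.55), co_gap = 2.5), effect_config)
  ann <- as.data.frame(annotation)
  caz <- ann$gene_id[ann$enzyme_class != "non-CAZyme"]
  if (sum(group_sizes) > length(caz))
    stop("group sizes oversubscribe the ", length(caz), " CAZyme genes")
  set.seed(seed)
  n <- nrow(ann)
  grp <- stats::setNames(rep("NON_INDUCIBLE", n), ann$gene_id)
  pool <- sample(caz)
  at <- 0
  for (g in names(group_sizes)) {
    k <- group_sizes[[g]]
    if (k > 0) grp[pool[at + seq_len(k)]] <- g
    at <- at + k
  }
  len_kb <- ann$length_bp / 1000

  base <- numeric(n)
  is_bg <- ann$enzyme_class == "non-CAZyme"
  for (g in .REGULON_GROUPS) {
    idx <- which(grp == g & !is_bg)
    if (!length(idx)) next
    base[idx] <- switch(g,
      NON_INDUCIBLE = .rlnormTrunc(length(idx), 1.5, 0.6),
      CS_CONTROLLED = ,
      OTHER_SPECIFIC = .rlnormTrunc(length(idx), 1.0, 0.4, lower = 3),
      XYR1_SPECIFIC = stats::runif(length(idx), 1.0, 1.5),
      XYR1_CS_CO = ,
      OTHER_CS_CO = .rlnormTrunc(length(idx), 1.4, 0.3, lower = 15, upper = 150))
  }
  base[is_bg] <- .rlnormTrunc(sum(is_bg), 1.5, 0.6)
  # housekeeping-like fixtures: two non-inducible CAZymes at high baseline
  hk <- which(grp == "NON_INDUCIBLE" & !is_bg)
  if (length(hk) >= 2) base[hk[1:2]] <- c(167, 676)
  # put planted levels on the column-sum RPKM scale: total = 1e6 RPKM-kb
  caz_total <- sum(base[!is_bg] * len_kb[!is_bg])
  bg_total <- sum(base[is_bg] * len_kb[is_bg])
  if (any(is_bg) && bg_total > 0 && caz_total < 1e6)
    base[is_bg] <- base[is_bg] * (1e6 - caz_total) / bg_total

  fc <- array(0, dim = c(n, 2, 3, 3),
              dimnames = list(ann$gene_id, .STRAINS, .CARBONS_INDUCED,
                              paste0(.TIMES_INDUCED, "h")))
  pickPoly <- function() switch(sample(3, 1), .POLY_CARBONS, "avicel", "xylan")
  for (i in seq_len(n)) {
    g <- grp[i]
    if (g == "NON_INDUCIBLE") next
    if (g == "CS_CONTROLLED") {
      hi <- stats::runif(1, cfg$high[1], cfg$high[2])
      fc[i, , , ] <- hi
    } else if (g == "XYR1_SPECIFIC") {
      hi <- stats::runif(1, cfg$high[1], cfg$high[2])
      fc[i, "WT", pickPoly(), ] <- hi
    } else if (g == "OTHER_SPECIFIC") {
      hi <- stats::runif(1, cfg$high[1], cfg$high[2])
      fc[i, , pickPoly(), ] <- hi
    } else {
      sl <- stats::runif(1, cfg$slight[1], cfg$slight[2])
      hi <- min(max(cfg$high), sl + cfg$co_gap)
      fc[i, "WT", .POLY_CARBONS, ] <- hi
      fc[i, "WT", "no_carbon", ] <- sl
      if (g == "XYR1_CS_CO") {
        fc[i, "xyr1_KO", , ] <- sl
      } else {  # OTHER_CS_CO: regulator-independent
        fc[i, "xyr1_KO", .POLY_CARBONS, ] <- hi
        fc[i, "xyr1_KO", "no_carbon", ] <- sl
      }
    }
  }
  new("RegulatoryArchitecture", gene_id = ann$gene_id,
      true_group = factor(unname(grp), levels = .REGULON_GROUPS),
      baseline_mean = base, dispersion = rep(dispersion, n),
      length_bp = as.integer(ann$length_bp), log2fc = fc)
}

# NB draw with mean/dispersion parameterization; dispersion 0 -> Poisson
.nbDraw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate read counts from a planted architecture
#'
#' Draws gene-by-sample counts with NB(mean, dispersion) noise, where the
#' mean for gene g in sample s is
#' \code{baseline_mean_g * 2^log2fc(g, strain_s, carbon_s, time_s) *
#' (length_bp_g / 1000) * (library_size / 1e6)}. Dispersion 0 falls back to
#' Poisson. The glucose baseline (0 h) has log2FC 0 by construction.
#'
#' @param architecture a \linkS4class{RegulatoryArchitecture}.
#' @param design design data.frame from \code{\link{generateDesign}}.
#' @param library_size_mean per-sample library size (default 2e7).
#' @param seed integer random seed.
#' @param annotation optional annotation data.frame carried into the result
#'   (rowData); defaults to a minimal one built from the architecture.
#' @return a \linkS4class{CazymeExperiment} with a counts assay; the planted
#'   group is in \code{rowData()$true_group}.
#' @export
simulateCounts <- function(architecture, design, library_size_mean = 2e7,
                           seed = 1, annotation = NULL) {
  stopifnot(is(architecture, "RegulatoryArchitecture"))
  des <- as.data.frame(design)
  set.seed(seed)
  n <- length(architecture@gene_id)
  m <- nrow(des)
  lfc <- matrix(0, n, m)
  for (j in seq_len(m)) {
    if (des$carbon[j] != "baseline_glucose")
      lfc[, j] <- architecture@log2fc[, des$strain[j], des$carbon[j],
                                      paste0(des$time_h[j], "h")]
  }
  mu <- architecture@baseline_mean * 2^lfc *
    (architecture@length_bp / 1000) * (library_size_mean / 1e6)
  counts <- matrix(0L, n, m, dimnames = list(architecture@gene_id, des$sample_id))
  for (i in seq_len(n))
    counts[i, ] <- as.integer(.nbDraw(m, mu[i, ], architecture@dispersion[i]))
  if (is.null(annotation)) {
    annotation <- data.frame(gene_id = architecture@gene_id,
                             length_bp = architecture@length_bp,
                             enzyme_class = "GH", family = "GH5",
                             functional_group = "other_GH",
                             stringsAsFactors = FALSE)
  }
  ann <- as.data.frame(annotation)
  ann$true_group <- as.character(architecture@true_group)[match(ann$gene_id, architecture@gene_id)]
  x <- cazymeExperiment(counts, ann, des,
                        library_size = pmax(colSums(counts), library_size_mean))
  metadata(x)$library_size_mean <- library_size_mean
  x
}
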