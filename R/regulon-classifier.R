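# Five-group regulatory classification, the absolutely-controlled regulon and
# the starvation-within-polysaccharide containment summary.

#' Compare induction levels of two conditions
#'
#' Welch test on log2(RPKM + pseudocount) replicate values at each
#' condition's argmax timepoint. The verdict is "higher" when the mean
#' ratio A/B (pseudocount-guarded only for a zero denominator) is at least
#' \code{level_ratio_min} and
#' the p-value is at most \code{level_p}; otherwise "not_different". The A
#' side may span several carbons (e.g. both polysaccharides, each at its own
#' argmax timepoint); their replicates are pooled.
#'
#' @param x a \linkS4class{CazymeExperiment} with an rpkm assay.
#' @param gene a single gene id.
#' @param strainA,carbonA,timeA condition A; \code{carbonA} and \code{timeA}
#'   may be parallel vectors.
#' @param strainB,carbonB,timeB condition B (single carbon/timepoint).
#' @param level_ratio_min minimum mean ratio for "higher" (default 2).
#' @param level_p maximum p-value for "higher" (default 0.01).
#' @param pseudocount pseudocount (default 1).
#' @return data.frame row: gene_id, ratio, p_value, verdict.
#' @export
compareLevels <- function(x, gene, strainA, carbonA, timeA,
                          strainB, carbonB, timeB,
                          level_ratio_min = 2, level_p = 0.01,
                          pseudocount = 1) {
  expr <- rpkm(x)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  des <- sampleDesign(x)
  pickReps <- function(strain, carbons, times) {
    unlist(lapply(seq_along(carbons), function(k) {
      cols <- des$sample_id[des$strain == strain & des$carbon == carbons[k] &
                            des$time_h == times[k]]
      expr[gene, cols]
    }))
  }
  a <- pickReps(strainA, carbonA, timeA)
  b <- pickReps(strainB, carbonB, timeB)
  if (length(a) < 2 || length(b) < 2)
    stop("both conditions need >= 2 replicates at their argmax timepoints")
  ratio <- if (mean(b) > 0) mean(a) / mean(b) else
    (mean(a) + pseudocount) / pseudocount
  p <- .welchP(log2(a + pseudocount), log2(b + pseudocount))
  data.frame(gene_id = gene, ratio = ratio, p_value = p,
             verdict = if (ratio >= level_ratio_min && p <= level_p)
               "higher" else "not_different",
             stringsAsFactors = FALSE)
}

#' Classify one gene into a regulatory group
#'
#' The normative decision procedure, evaluated in order:
#' \enumerate{
#'   \item WT not induced by any carbon: NON_INDUCIBLE.
#'   \item WT induced by a polysaccharide (avicel or xylan) AND by
#'     starvation: if the WT polysaccharide level is not different from the
#'     WT starvation level, CS_CONTROLLED; if it is higher, then XYR1_CS_CO
#'     when the knockout polysaccharide level has fallen to the WT
#'     starvation level (not different), OTHER_CS_CO otherwise.
#'   \item WT induced by polysaccharide only: XYR1_SPECIFIC when the gene is
#'     not induced in the knockout and its knockout expression maximum is
#'     below the floor; OTHER_SPECIFIC otherwise.
#'   \item WT induced by starvation only: CS_CONTROLLED with flag
#'     "cs_only" (a pattern absent from the motivating data).
#' }
#'
#' @param induced_wt,induced_ko named logical vectors with elements
#'   no_carbon, avicel, xylan.
#' @param poly_vs_cs verdict ("higher"/"not_different") of the WT
#'   polysaccharide-vs-starvation level comparison; may be NA when unused.
#' @param ko_poly_vs_cs verdict of the knockout-polysaccharide vs WT
#'   starvation comparison; may be NA when unused.
#' @param ko_expr_max maximum knockout replicate-mean RPKM over all
#'   conditions and timepoints.
#' @param expr_floor "almost no expression" floor (default 2 RPKM).
#' @return list with \code{group} and \code{flags} (character vector).
#' @export
classifyGene <- function(induced_wt, induced_ko, poly_vs_cs = NA,
                         ko_poly_vs_cs = NA, ko_expr_max = Inf,
                         expr_floor = 2) {
  need <- c("no_carbon", "avicel", "xylan")
  stopifnot(all(need %in% names(induced_wt)), all(need %in% names(induced_ko)))
  poly_wt <- induced_wt[["avicel"]] || induced_wt[["xylan"]]
  cs_wt <- induced_wt[["no_carbon"]]
  flags <- character()
  if (!poly_wt && !cs_wt) {
    group <- "NON_INDUCIBLE"
  } else if (poly_wt && cs_wt) {
    if (is.na(poly_vs_cs))
      stop("poly_vs_cs verdict required for a poly+CS induced gene")
    if (poly_vs_cs == "not_different") {
      group <- "CS_CONTROLLED"
    } else {
      if (is.na(ko_poly_vs_cs))
        stop("ko_poly_vs_cs verdict required when the poly level is higher")
      group <- if (ko_poly_vs_cs == "not_different") "XYR1_CS_CO" else "OTHER_CS_CO"
    }
  } else if (poly_wt) {
    ko_any <- any(induced_ko)
    group <- if (!ko_any && ko_expr_max < expr_floor) "XYR1_SPECIFIC" else "OTHER_SPECIFIC"
  } else {
    group <- "CS_CONTROLLED"
    flags <- "cs_only"
  }
  list(group = group, flags = flags)
}

# knockout replicate-mean RPKM maximum over every (carbon, time) cell
.koExprMax <- function(gm) {
  ko <- gm$info$strain == "xyr1_KO"
  if (!any(ko)) return(rep(Inf, nrow(gm$means)))
  apply(gm$means[, ko, drop = FALSE], 1, max)
}

#' Classify all CAZyme genes into regulatory groups
#'
#' Drives \code{\link{classifyGene}} over the induction calls, computing the
#' level contrasts with \code{\link{compareLevels}} where the decision needs
#' them. The polysaccharide side of a contrast pools the replicates of every
#' WT-induced polysaccharide condition at its argmax timepoint; the knockout
#' side uses the same polysaccharide carbons at the knockout's reported
#' timepoints.
#'
#' @param x a \linkS4class{CazymeExperiment} with an rpkm assay.
#' @param calls output of \code{\link{callInduction}} covering both strains
#'   and all three induced carbons.
#' @param expr_floor knockout expression floor (default 2 RPKM).
#' @param level_ratio_min,level_p,pseudocount passed to
#'   \code{\link{compareLevels}}.
#' @param genes gene ids to classify (default: all genes in \code{calls}).
#' @return data.frame with gene_id, group, absolutely_xyr1_controlled,
#'   ko_expr_max and flags. The absolute flag marks genes induced by a
#'   polysaccharide in the WT whose induction the knockout abolishes
#'   (knockout maximum below the floor) or reduces to the starvation level
#'   (group XYR1_CS_CO).
#' @export
classifyRegulons <- function(x, calls, expr_floor = 2, level_ratio_min = 2,
                             level_p = 0.01, pseudocount = 1, genes = NULL) {
  des <- sampleDesign(x)
  expr <- rpkm(x)
  if (is.null(genes)) genes <- unique(calls$gene_id)
  gm <- .groupMeans(expr, des)
  ko_max_all <- .koExprMax(gm)
  key <- function(g, st, ca) which(calls$gene_id == g & calls$strain == st &
                                   calls$carbon == ca)
  # index calls once for speed
  calls$.k <- interaction(calls$gene_id, calls$strain, calls$carbon, drop = FALSE)
  ktab <- split(seq_len(nrow(calls)), calls$.k)
  getCall <- function(g, st, ca) {
    i <- ktab[[paste(g, st, ca, sep = ".")]]
    if (is.null(i) || !length(i)) stop("missing induction call for ", g, " ", st, " ", ca)
    calls[i[1], ]
  }
  res <- lapply(genes, function(g) {
    iwt <- sapply(.CARBONS_INDUCED, function(ca) getCall(g, "WT", ca)$induced)
    iko <- sapply(.CARBONS_INDUCED, function(ca) getCall(g, "xyr1_KO", ca)$induced)
    ko_max <- ko_max_all[[g]]
    poly_vs_cs <- NA
    ko_poly_vs_cs <- NA
    contrasts <- NULL
    if ((iwt[["avicel"]] || iwt[["xylan"]]) && iwt[["no_carbon"]]) {
      polys <- .POLY_CARBONS[iwt[.POLY_CARBONS]]
      wt_times <- vapply(polys, function(ca) getCall(g, "WT", ca)$argmax_time_h, numeric(1))
      cs_time <- getCall(g, "WT", "no_carbon")$argmax_time_h
      cmpA <- compareLevels(x, g, "WT", polys, wt_times,
                            "WT", "no_carbon", cs_time,
                            level_ratio_min, level_p, pseudocount)
      poly_vs_cs <- cmpA$verdict
      if (poly_vs_cs == "higher") {
        ko_times <- vapply(polys, function(ca) getCall(g, "xyr1_KO", ca)$argmax_time_h,
                           numeric(1))
        cmpB <- compareLevels(x, g, "xyr1_KO", polys, ko_times,
                              "WT", "no_carbon", cs_time,
                              level_ratio_min, level_p, pseudocount)
        ko_poly_vs_cs <- cmpB$verdict
      }
    }
    cl <- classifyGene(iwt, iko, poly_vs_cs, ko_poly_vs_cs, ko_max, expr_floor)
    data.frame(gene_id = g, group = cl$group,
               absolutely_xyr1_controlled =
                 (iwt[["avicel"]] || iwt[["xylan"]]) &&
                 (ko_max < expr_floor || cl$group == "XYR1_CS_CO"),
               ko_expr_max = ko_max,
               flags = paste(cl$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Absolutely regulator-controlled gene set
#'
#' Genes induced by a polysaccharide in the wild type whose induction the
#' knockout either abolishes (knockout maximum replicate-mean RPKM below the
#' floor over every condition and timepoint) or collapses to the starvation
#' level (XYR1_CS_CO genes).
#'
#' @param assignments output of \code{\link{classifyRegulons}}.
#' @return list with \code{genes} (character) and \code{n}.
#' @export
absolutelyControlledSet <- function(assignments) {
  genes <- assignments$gene_id[assignments$absolutely_xyr1_controlled]
  list(genes = genes, n = length(genes))
}

#' Starvation-within-polysaccharide containment summary
#'
#' From wild-type induction calls: the set of starvation (no-carbon) induced
#' genes, the set of polysaccharide (avicel or xylan) induced genes, the
#' containment fraction 100 * |CS intersect poly| / |poly| (one decimal) and
#' whether the starvation set nests inside the polysaccharide set.
#'
#' @param calls output of \code{\link{callInduction}}.
#' @return list with n_cs_induced, n_poly_induced, containment_fraction,
#'   remainder_fraction, nested, and a zero_poly flag.
#' @export
containmentSummary <- function(calls) {
  wt <- calls[calls$strain == "WT", ]
  cs <- unique(wt$gene_id[wt$induced & wt$carbon == "no_carbon"])
  poly <- unique(wt$gene_id[wt$induced & wt$carbon %in% .POLY_CARBONS])
  if (length(poly) == 0) {
    return(list(n_cs_induced = length(cs), n_poly_induced = 0,
                containment_fraction = 0, remainder_fraction = 0,
                nested = length(cs) == 0, zero_poly = TRUE))
  }
  frac <- classPercent(length(intersect(cs, poly)), length(poly), 1)
  list(n_cs_induced = length(cs), n_poly_induced = length(poly),
       containment_fraction = frac,
       remainder_fraction = roundHalfAway(100 - frac, 1),
       nested = all(cs %in% poly), zero_poly = FALSE)
}
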