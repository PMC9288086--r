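# Significant-induction calling against the 0 h glucose baseline, and the
# per-class induction-rate summary.

#' Fold change and Welch p-value between two replicate groups
#'
#' log2FC is computed on pseudocount-shifted replicate means,
#' \code{log2((mean(induced) + pc) / (mean(baseline) + pc))}; the p-value is
#' a two-sided Welch t-test on log2(RPKM + pc) replicate values. When both
#' groups are constant, p is 1 for equal means and 0 otherwise.
#'
#' @param baseline_reps numeric vector of baseline RPKM (length >= 2).
#' @param induced_reps numeric vector of induced RPKM (length >= 2).
#' @param pseudocount positive pseudocount (default 1).
#' @return list with \code{log2fc} and \code{p_value}.
#' @examples
#' differentialStat(c(1, 1, 1), c(15, 16, 17))$log2fc  # log2(17/2)
#' @export
differentialStat <- function(baseline_reps, induced_reps, pseudocount = 1) {
  if (length(baseline_reps) < 2 || length(induced_reps) < 2)
    stop("each replicate group needs length >= 2")
  lfc <- log2((mean(induced_reps) + pseudocount) /
              (mean(baseline_reps) + pseudocount))
  p <- .welchP(log2(induced_reps + pseudocount),
               log2(baseline_reps + pseudocount))
  list(log2fc = lfc, p_value = p)
}

#' Call significant induction per gene, strain and carbon
#'
#' Each induced timepoint (4/24/72 h) is tested against the strain's 0 h
#' glucose baseline. A gene is induced under a (strain, carbon) when at
#' least one timepoint passes all three thresholds (log2FC, p-value, RPKM
#' floor on the induced replicate mean). The reported log2fc, p_value and
#' argmax_time_h come from the passing timepoint with the largest log2FC
#' (or, for non-induced genes, the timepoint with the largest log2FC);
#' max_mean_rpkm is the profile maximum over the three timepoints.
#'
#' @param x a \linkS4class{CazymeExperiment} with an rpkm assay.
#' @param thresholds an \linkS4class{InductionThresholds}.
#' @param genes optional gene ids to restrict the calling to (default: all).
#' @return data.frame with gene_id, strain, carbon, log2fc, p_value,
#'   max_mean_rpkm, argmax_time_h, induced.
#' @export
callInduction <- function(x, thresholds = inductionThresholds(), genes = NULL) {
  stopifnot(is(x, "CazymeExperiment"))
  validObject(thresholds)
  expr <- rpkm(x)
  des <- sampleDesign(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  pc <- thresholds@pseudocount
  cmp <- if (thresholds@strict_fold) `>` else `>=`
  out <- list()
  for (st in intersect(.STRAINS, unique(des$strain))) {
    bcols <- des$sample_id[des$strain == st & des$carbon == "baseline_glucose"]
    if (!length(bcols)) stop("missing baseline samples for strain ", st)
    base <- expr[, bcols, drop = FALSE]
    base_l2 <- log2(base + pc)
    base_mean <- rowMeans(base)
    for (ca in intersect(.CARBONS_INDUCED, unique(des$carbon))) {
      times <- sort(unique(des$time_h[des$strain == st & des$carbon == ca]))
      lfc <- p <- mu <- matrix(NA_real_, nrow(expr), length(times))
      for (k in seq_along(times)) {
        cols <- des$sample_id[des$strain == st & des$carbon == ca &
                              des$time_h == times[k]]
        ind <- expr[, cols, drop = FALSE]
        mu[, k] <- rowMeans(ind)
        lfc[, k] <- log2((mu[, k] + pc) / (base_mean + pc))
        ind_l2 <- log2(ind + pc)
        p[, k] <- vapply(seq_len(nrow(expr)),
                         function(i) .welchP(ind_l2[i, ], base_l2[i, ]),
                         numeric(1))
      }
      pass <- cmp(lfc, thresholds@min_abs_log2fc) &
        p <= thresholds@max_p & mu > thresholds@min_expr
      # report the passing timepoint with the largest log2FC, falling back
      # to the overall largest-log2FC timepoint for non-induced genes
      rank_lfc <- lfc
      rank_lfc[pass] <- rank_lfc[pass] + 1e6
      pick <- max.col(rank_lfc, ties.method = "first")
      i <- seq_len(nrow(expr))
      out[[paste(st, ca)]] <- data.frame(
        gene_id = rownames(expr), strain = st, carbon = ca,
        log2fc = lfc[cbind(i, pick)], p_value = p[cbind(i, pick)],
        max_mean_rpkm = apply(mu, 1, max),
        argmax_time_h = times[pick],
        induced = rowSums(pass) > 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class induction summary
#'
#' A gene counts as induced when it is called induced in the wild type under
#' avicel or xylan. Percentages are 100 * n_induced / n_total rounded half
#' away from zero.
#'
#' @param calls output of \code{\link{callInduction}}.
#' @param annotation annotation data.frame (gene_id, enzyme_class).
#' @param decimals decimal places for the percentage (default 1).
#' @return data.frame with enzyme_class, n_induced, n_total, percent and an
#'   empty_class flag for classes with no genes.
#' @export
familyInductionSummary <- function(calls, annotation, decimals = 1) {
  ann <- as.data.frame(annotation)
  wt <- calls[calls$strain == "WT" & calls$carbon %in% .POLY_CARBONS, ]
  induced_genes <- unique(wt$gene_id[wt$induced])
  classes <- intersect(.ENZYME_CLASSES, unique(ann$enzyme_class))
  ann_called <- ann[ann$gene_id %in% unique(calls$gene_id), ]
  res <- do.call(rbind, lapply(classes, function(cl) {
    ids <- ann_called$gene_id[ann_called$enzyme_class == cl]
    n <- length(ids)
    k <- sum(ids %in% induced_genes)
    data.frame(enzyme_class = cl, n_induced = k, n_total = n,
               percent = if (n == 0) 0 else classPercent(k, n, decimals),
               empty_class = n == 0, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
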