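# SWATH-style secretome comparison: peptide-to-protein abundance, median
# normalization, relative abundance with high-abundance flags, enrichment
# classification and functional-group summaries.

#' Protein abundance from peptide areas
#'
#' Sums peptide areas per protein and sample (the peptide areas themselves
#' are assumed to already be summed fragment-ion areas). Errors if a peptide
#' maps to more than one protein. Proteins without detected peptides in a
#' sample get abundance 0.
#'
#' @param peptides data.frame with peptide_id, protein_id, sample_id, area
#'   and (optionally) condition and replicate columns.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with an
#'   \code{abundance} assay (protein x sample) and condition/replicate in
#'   \code{colData} when available.
#' @export
proteinAbundance <- function(peptides) {
  pep <- as.data.frame(peptides)
  stopifnot(all(c("peptide_id", "protein_id", "sample_id", "area") %in% colnames(pep)))
  if (any(pep$area < 0)) stop("peptide areas must be >= 0")
  map <- unique(pep[, c("peptide_id", "protein_id")])
  if (anyDuplicated(map$peptide_id))
    stop("peptide(s) mapped to more than one protein: ",
         paste(utils::head(unique(map$peptide_id[duplicated(map$peptide_id)]), 3),
               collapse = ", "))
  prot <- sort(unique(pep$protein_id))
  smp <- unique(pep$sample_id)
  ab <- matrix(0, length(prot), length(smp), dimnames = list(prot, smp))
  agg <- stats::aggregate(area ~ protein_id + sample_id, data = pep, FUN = sum)
  ab[cbind(match(agg$protein_id, prot), match(agg$sample_id, smp))] <- agg$area
  cd <- unique(pep[, intersect(c("sample_id", "condition", "replicate"),
                               colnames(pep)), drop = FALSE])
  cd <- cd[match(smp, cd$sample_id), , drop = FALSE]
  SummarizedExperiment(assays = list(abundance = ab),
                       colData = DataFrame(cd[setdiff(colnames(cd), "sample_id")],
                                           row.names = smp))
}

#' Median normalization
#'
#' Scales each sample so that its median abundance over proteins detected in
#' at least one sample equals the grand median of the per-sample medians.
#' Zero entries stay zero; the normalization is invariant to a common
#' rescaling of the input.
#'
#' @param x SummarizedExperiment from \code{\link{proteinAbundance}} (or a
#'   plain matrix).
#' @param assay_name input assay (default "abundance").
#' @return the object with a \code{normalized} assay added (or the
#'   normalized matrix for matrix input).
#' @export
medianNormalize <- function(x, assay_name = "abundance") {
  ab <- if (is.matrix(x)) x else assay(x, assay_name)
  if (any(colSums(ab) == 0))
    stop("all-zero sample(s): ", paste(colnames(ab)[colSums(ab) == 0], collapse = ", "))
  keep <- rowSums(ab > 0) > 0
  med <- apply(ab[keep, , drop = FALSE], 2, stats::median)
  if (any(med == 0))
    stop("zero median abundance in sample(s): ",
         paste(colnames(ab)[med == 0], collapse = ", "))
  scale <- stats::median(med) / med
  norm <- sweep(ab, 2, scale, "*")
  if (is.matrix(x)) return(norm)
  assay(x, "normalized") <- norm
  x
}

#' Relative abundance and high-abundance flags
#'
#' Per-sample relative abundance is 100 * abundance / sample total (summing
#' to 100 per sample); per-condition relative abundance is the replicate
#' mean. A protein is flagged highly abundant in a condition when its
#' condition-mean relative abundance strictly exceeds
#' \code{high_cutoff_pct}.
#'
#' @param x SummarizedExperiment with a normalized (or abundance) assay and
#'   a condition column in colData.
#' @param high_cutoff_pct strict percentage cutoff (default 1).
#' @param assay_name assay to use; defaults to "normalized" when present.
#' @return list with \code{per_sample} (matrix of per-sample relative
#'   abundances) and \code{per_condition} (data.frame with condition-mean
#'   relative abundances and high flags).
#' @export
relativeAbundance <- function(x, high_cutoff_pct = 1,
                              assay_name = NULL) {
  if (is.null(assay_name))
    assay_name <- if ("normalized" %in% assayNames(x)) "normalized" else "abundance"
  ab <- assay(x, assay_name)
  tot <- colSums(ab)
  if (any(tot == 0)) stop("zero total abundance in sample(s): ",
                          paste(colnames(ab)[tot == 0], collapse = ", "))
  rel <- sweep(ab, 2, tot, "/") * 100
  cond <- colData(x)$condition
  if (is.null(cond)) stop("colData(x)$condition is required")
  per_cond <- vapply(unique(cond), function(cc)
    rowMeans(rel[, cond == cc, drop = FALSE]), numeric(nrow(rel)))
  df <- data.frame(protein_id = rownames(rel), per_cond,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in unique(cond)) df[[paste0("high_", cc)]] <- df[[cc]] > high_cutoff_pct
  list(per_sample = rel, per_condition = df)
}

#' AIEP/XIEP enrichment classification per protein
#'
#' The enrichment ratio is (mean AIEP + pseudo) / (mean XIEP + pseudo),
#' capped to [1/ratio_cap, ratio_cap]; significance is a two-sided Welch
#' test on log2(abundance + pseudo) replicate values. A protein is
#' AIEP_enriched when ratio >= enrich_fold and p <= enrich_p, XIEP_enriched
#' when ratio <= 1/enrich_fold and p <= enrich_p, no_difference otherwise.
#' The classification is antisymmetric under swapping the condition labels.
#'
#' @param x SummarizedExperiment with condition in colData and a normalized
#'   (or abundance) assay.
#' @param enrich_fold minimum fold for an enrichment call (default 1.9).
#' @param enrich_p maximum p-value (default 0.01).
#' @param pseudo pseudo-abundance; defaults to the smallest positive entry
#'   of the assay (per table).
#' @param ratio_cap cap on the reported ratio (default 1000).
#' @param assay_name assay to use; defaults to "normalized" when present.
#' @param conditions length-2 character: numerator and denominator
#'   condition (default AIEP, XIEP).
#' @return data.frame with protein_id, mean_ratio, p_value, class.
#' @export
enrichmentCall <- function(x, enrich_fold = 1.9, enrich_p = 0.01,
                           pseudo = NULL, ratio_cap = 1000,
                           assay_name = NULL,
                           conditions = c("AIEP", "XIEP")) {
  if (is.null(assay_name))
    assay_name <- if ("normalized" %in% assayNames(x)) "normalized" else "abundance"
  ab <- assay(x, assay_name)
  cond <- colData(x)$condition
  a_cols <- cond == conditions[1]
  b_cols <- cond == conditions[2]
  if (sum(a_cols) < 2 || sum(b_cols) < 2)
    stop("need >= 2 replicates per condition")
  if (is.null(pseudo)) {
    pos <- ab[ab > 0]
    pseudo <- if (length(pos)) min(pos) else 1
  }
  a <- ab[, a_cols, drop = FALSE]
  b <- ab[, b_cols, drop = FALSE]
  ratio <- (rowMeans(a) + pseudo) / (rowMeans(b) + pseudo)
  ratio <- pmin(pmax(ratio, 1 / ratio_cap), ratio_cap)
  p <- vapply(seq_len(nrow(ab)), function(i)
    .welchP(log2(a[i, ] + pseudo), log2(b[i, ] + pseudo)), numeric(1))
  cls <- rep("no_difference", nrow(ab))
  cls[ratio >= enrich_fold & p <= enrich_p] <- paste0(conditions[1], "_enriched")
  cls[ratio <= 1 / enrich_fold & p <= enrich_p] <- paste0(conditions[2], "_enriched")
  data.frame(protein_id = rownames(ab), mean_ratio = ratio, p_value = p,
             class = cls, stringsAsFactors = FALSE)
}

#' Functional-group enrichment summary
#'
#' Tabulates the enrichment calls over the nine functional groups
#' (cellulase, xylanase, chitinase, mannanase, other hemicellulase, other
#' GH, protease, other, unknown); empty groups are reported with n = 0.
#'
#' @param calls output of \code{\link{enrichmentCall}}.
#' @param annotation data.frame with protein_id and functional_group.
#' @return data.frame per group with n, n_AIEP_enriched, n_XIEP_enriched,
#'   n_no_difference and ratio quartiles.
#' @export
groupRatioSummary <- function(calls, annotation) {
  ann <- as.data.frame(annotation)
  bad <- setdiff(unique(ann$functional_group), .FUNCTIONAL_GROUPS)
  if (length(bad)) stop("unknown functional group label(s): ",
                        paste(bad, collapse = ", "))
  grp <- ann$functional_group[match(calls$protein_id, ann$protein_id)]
  if (anyNA(grp)) stop("proteins without group annotation: ",
                       paste(utils::head(calls$protein_id[is.na(grp)], 3), collapse = ", "))
  res <- do.call(rbind, lapply(.FUNCTIONAL_GROUPS, function(g) {
    sub <- calls[grp == g, , drop = FALSE]
    q <- if (nrow(sub)) stats::quantile(sub$mean_ratio, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
    data.frame(functional_group = g, n = nrow(sub),
               n_AIEP_enriched = sum(sub$class == "AIEP_enriched"),
               n_XIEP_enriched = sum(sub$class == "XIEP_enriched"),
               n_no_difference = sum(sub$class == "no_difference"),
               ratio_q25 = unname(q[1]), ratio_median = unname(q[2]),
               ratio_q75 = unname(q[3]), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Count CAZyme-annotated entries of a processed secretome table
#'
#' Reads a processed identification table (TSV with header) and counts the
#' proteins flagged as CAZymes, either through a logical/0-1
#' \code{is_cazyme} column or a non-empty \code{cazy_class}/\code{family}
#' annotation.
#'
#' @param table a data.frame or a path to a TSV file.
#' @return integer count of CAZyme entries (unique protein ids).
#' @export
countCazymeEntries <- function(table) {
  df <- if (is.character(table)) utils::read.delim(table, stringsAsFactors = FALSE) else as.data.frame(table)
  if ("is_cazyme" %in% colnames(df)) {
    caz <- df$is_cazyme %in% c(TRUE, "TRUE", "true", 1, "1", "yes")
  } else if ("cazy_class" %in% colnames(df)) {
    caz <- !is.na(df$cazy_class) & df$cazy_class != "" & df$cazy_class != "none"
  } else if ("family" %in% colnames(df)) {
    caz <- grepl("^(GH|CE|AA|PL|GT|CBM)", df$family)
  } else {
    stop("no CAZyme annotation column (is_cazyme, cazy_class or family)")
  }
  length(unique(df$protein_id[caz]))
}
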