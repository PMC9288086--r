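#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData colData
NULL

#' Induction-calling thresholds
#'
#' Holds the significance thresholds of the induction caller: a gene is
#' significantly induced at a timepoint when its fold change satisfies
#' log2FC >= \code{min_abs_log2fc}, the Welch p-value satisfies
#' p <= \code{max_p}, and the replicate-mean RPKM of the induced condition
#' exceeds \code{min_expr} (strictly). Fold changes are computed on
#' pseudocount-shifted replicate means.
#'
#' @slot min_abs_log2fc minimum log2 fold change (default 2, i.e. 4-fold).
#' @slot max_p maximum p-value (default 0.01).
#' @slot min_expr strict RPKM floor on the induced condition (default 2).
#' @slot pseudocount pseudocount added to RPKM means and replicates (default 1).
#' @slot strict_fold if TRUE the fold-change comparison is strict (>) rather
#'   than inclusive (>=); the inclusive form is the default.
#' @export
setClass("InductionThresholds",
  representation(min_abs_log2fc = "numeric", max_p = "numeric",
                 min_expr = "numeric", pseudocount = "numeric",
                 strict_fold = "logical"),
  prototype(min_abs_log2fc = 2, max_p = 0.01, min_expr = 2,
            pseudocount = 1, strict_fold = FALSE))

setValidity("InductionThresholds", function(object) {
  msg <- character()
  if (length(object@min_abs_log2fc) != 1 || object@min_abs_log2fc <= 0)
    msg <- c(msg, "min_abs_log2fc must be a single positive number")
  if (length(object@max_p) != 1 || object@max_p <= 0 || object@max_p > 1)
    msg <- c(msg, "max_p must lie in (0, 1]")
  if (length(object@min_expr) != 1 || object@min_expr <= 0)
    msg <- c(msg, "min_expr must be a single positive number")
  if (length(object@pseudocount) != 1 || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct induction thresholds
#'
#' @param min_abs_log2fc minimum log2 fold change (default 2).
#' @param max_p maximum Welch p-value (default 0.01).
#' @param min_expr strict RPKM floor on the induced condition (default 2).
#' @param pseudocount pseudocount for fold changes and log transforms.
#' @param strict_fold use a strict (>) fold comparison instead of >=.
#' @return an \linkS4class{InductionThresholds} object.
#' @examples
#' inductionThresholds()
#' @export
inductionThresholds <- function(min_abs_log2fc = 2, max_p = 0.01,
                                min_expr = 2, pseudocount = 1,
                                strict_fold = FALSE) {
  new("InductionThresholds", min_abs_log2fc = min_abs_log2fc, max_p = max_p,
      min_expr = min_expr, pseudocount = pseudocount,
      strict_fold = strict_fold)
}

setMethod("show", "InductionThresholds", function(object) {
  cat("InductionThresholds: log2FC", if (object@strict_fold) ">" else ">=",
      object@min_abs_log2fc, "; p <=", object@max_p,
      "; RPKM >", object@min_expr,
      "; pseudocount", object@pseudocount, "\n")
})

#' Planted regulatory architecture
#'
#' Ground truth of a synthetic experiment: per-gene regulatory group,
#' glucose-baseline expression level (on the RPKM scale), negative-binomial
#' dispersion, gene length, and the planted log2 induction over every
#' (strain, carbon, timepoint) cell of the design.
#'
#' @slot gene_id character gene identifiers.
#' @slot true_group factor over the six regulatory groups.
#' @slot baseline_mean positive numeric, expected baseline RPKM.
#' @slot dispersion non-negative NB dispersion (Var = mu + disp * mu^2).
#' @slot length_bp positive integer gene lengths.
#' @slot log2fc 4-d numeric array [gene, strain, carbon, time] of planted
#'   log2 fold changes over the baseline.
#' @export
setClass("RegulatoryArchitecture",
  representation(gene_id = "character", true_group = "factor",
                 baseline_mean = "numeric", dispersion = "numeric",
                 length_bp = "integer", log2fc = "array"))

setValidity("RegulatoryArchitecture", function(object) {
  msg <- character()
  n <- length(object@gene_id)
  if (anyDuplicated(object@gene_id)) msg <- c(msg, "gene ids must be unique")
  if (length(object@true_group) != n || !all(levels(object@true_group) %in% .REGULON_GROUPS))
    msg <- c(msg, "true_group must cover every gene with valid group labels")
  if (length(object@baseline_mean) != n || any(object@baseline_mean <= 0))
    msg <- c(msg, "baseline_mean must be positive for every gene")
  if (length(object@dispersion) != n || any(object@dispersion < 0))
    msg <- c(msg, "dispersion must be non-negative for every gene")
  if (length(object@length_bp) != n || any(object@length_bp < 1))
    msg <- c(msg, "length_bp must be >= 1 for every gene")
  d <- dim(object@log2fc)
  if (length(d) != 4 || d[1] != n || d[2] != 2 || d[3] != 3 || d[4] != 3) {
    msg <- c(msg, "log2fc must be a gene x 2 x 3 x 3 array")
  } else {
    fc <- object@log2fc
    grp <- as.character(object@true_group)
    ni <- grp == "NON_INDUCIBLE"
    if (any(fc[ni, , , ] != 0))
      msg <- c(msg, "NON_INDUCIBLE genes must have all planted log2FC = 0")
    xs <- grp == "XYR1_SPECIFIC"
    if (any(abs(fc[xs, "xyr1_KO", , ]) > 1e-8))
      msg <- c(msg, "XYR1_SPECIFIC genes must be silent in the knockout")
    xc <- grp == "XYR1_CS_CO"
    if (any(xc)) {
      cs <- fc[xc, "WT", "no_carbon", , drop = FALSE]
      for (ca in .CARBONS_INDUCED)
        if (any(abs(fc[xc, "xyr1_KO", ca, , drop = FALSE] - cs) > 1e-8))
          msg <- c(msg, "XYR1_CS_CO genes must fall to their CS level in the knockout")
    }
    cc <- grp == "CS_CONTROLLED"
    if (any(cc)) {
      ref <- fc[cc, , "no_carbon", , drop = FALSE]
      for (ca in .POLY_CARBONS)
        if (any(abs(fc[cc, , ca, , drop = FALSE] - ref) > 1e-8))
          msg <- c(msg, "CS_CONTROLLED genes must have equal induction for all carbons")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegulatoryArchitecture", function(object) {
  cat("RegulatoryArchitecture with", length(object@gene_id), "genes\n")
  print(table(object@true_group))
})

#' @describeIn RegulatoryArchitecture-class gene identifiers.
#' @param x a \code{RegulatoryArchitecture}.
#' @export
geneIds <- function(x) x@gene_id

#' @describeIn RegulatoryArchitecture-class planted group per gene (named).
#' @export
trueGroups <- function(x) stats::setNames(as.character(x@true_group), x@gene_id)

#' @describeIn RegulatoryArchitecture-class planted baseline RPKM per gene.
#' @export
baselineMeans <- function(x) stats::setNames(x@baseline_mean, x@gene_id)

#' @describeIn RegulatoryArchitecture-class planted log2FC array
#'   [gene, strain, carbon, time].
#' @export
plantedLog2FC <- function(x) x@log2fc

#' CAZyme induction experiment container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass for the
#' knockout-by-carbon induction design: a counts assay (genes x samples),
#' gene annotation in \code{rowData} (length_bp, enzyme_class, family,
#' functional_group), and the sample design in \code{colData} (strain,
#' carbon, time_h, replicate).
#'
#' @export
setClass("CazymeExperiment", contains = "SummarizedExperiment")

setValidity("CazymeExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  need_cd <- c("strain", "carbon", "time_h", "replicate")
  if (!all(need_cd %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  } else {
    if (!all(cd$strain %in% .STRAINS)) msg <- c(msg, "unknown strain labels")
    if (!all(cd$carbon %in% .CARBONS)) msg <- c(msg, "unknown carbon labels")
    base <- cd$carbon == "baseline_glucose"
    if (any(cd$time_h[base] != 0) || any(cd$time_h[!base] == 0))
      msg <- c(msg, "baseline_glucose samples and only those must be at 0 h")
  }
  rd <- rowData(object)
  need_rd <- c("length_bp", "enzyme_class", "family", "functional_group")
  if (!all(need_rd %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  } else if (any(rd$length_bp < 1)) {
    msg <- c(msg, "gene lengths must be >= 1")
  }
  if (!"counts" %in% assayNames(object)) {
    msg <- c(msg, "a 'counts' assay is required")
  } else if (any(assay(object, "counts") < 0)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CazymeExperiment
#'
#' @param counts integer matrix genes x samples; row names are gene ids,
#'   column names sample ids.
#' @param annotation data.frame with columns gene_id, length_bp,
#'   enzyme_class, family, functional_group.
#' @param design data.frame with columns sample_id, strain, carbon, time_h,
#'   replicate.
#' @param library_size optional per-sample nominal library sizes; defaults to
#'   the column sums of \code{counts}.
#' @return a \linkS4class{CazymeExperiment}.
#' @export
cazymeExperiment <- function(counts, annotation, design, library_size = NULL) {
  stopifnot(is.matrix(counts))
  ann <- as.data.frame(annotation)
  des <- as.data.frame(design)
  if (is.null(rownames(counts))) {
    if (nrow(ann) != nrow(counts))
      stop("annotation is missing genes present in counts")
    rownames(counts) <- ann$gene_id
  }
  if (is.null(colnames(counts))) {
    if (nrow(des) != ncol(counts))
      stop("design is missing samples present in counts")
    colnames(counts) <- des$sample_id
  }
  ann <- ann[match(rownames(counts), ann$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id)) stop("annotation is missing genes present in counts")
  des <- des[match(colnames(counts), des$sample_id), , drop = FALSE]
  if (anyNA(des$sample_id)) stop("design is missing samples present in counts")
  if (is.null(library_size)) library_size <- colSums(counts)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(ann[setdiff(colnames(ann), "gene_id")],
                        row.names = ann$gene_id),
    colData = DataFrame(des[setdiff(colnames(des), "sample_id")],
                        row.names = des$sample_id))
  metadata(se)$library_size <- library_size
  new("CazymeExperiment", se)
}

#' @describeIn CazymeExperiment-class gene annotation as a data.frame with a
#'   gene_id column.
#' @param x a \code{CazymeExperiment}.
#' @export
geneAnnotation <- function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(gene_id = rownames(x), rd, row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn CazymeExperiment-class sample design as a data.frame with a
#'   sample_id column.
#' @export
sampleDesign <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = colnames(x), cd, row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn CazymeExperiment-class the RPKM assay (computed by
#'   \code{\link{computeRPKM}}).
#' @export
rpkm <- function(x) {
  if (!"rpkm" %in% assayNames(x))
    stop("no 'rpkm' assay; run computeRPKM() first")
  assay(x, "rpkm")
}
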