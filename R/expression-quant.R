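# RPKM computation and the max-over-timepoints induction profile summary.

#' Compute RPKM
#'
#' RPKM(g, s) = count(g, s) * 1e9 / (length_bp(g) * library_size(s)), with
#' the library size taken as the within-matrix column sum, so the matrix is
#' self-contained. An entry is 0 exactly when its count is 0.
#'
#' @param counts integer matrix (genes x samples) or a
#'   \linkS4class{CazymeExperiment}.
#' @param annotation for the matrix method, an annotation data.frame with
#'   gene_id and length_bp covering every row of \code{counts}.
#' @param ... unused.
#' @return the matrix method returns the RPKM matrix; the
#'   \code{CazymeExperiment} method returns the object with an added
#'   \code{rpkm} assay.
#' @examples
#' m <- matrix(c(10, 990), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' ann <- data.frame(gene_id = c("a", "b"), length_bp = c(1000, 2000))
#' computeRPKM(m * 1000, ann)["a", ]  # 10 counts/kb at 1e6 reads -> 10 RPKM
#' @export
setGeneric("computeRPKM", function(counts, annotation, ...) standardGeneric("computeRPKM"))

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", signature(counts = "matrix"), function(counts, annotation, ...) {
  ann <- as.data.frame(annotation)
  len <- ann$length_bp[match(rownames(counts), ann$gene_id)]
  if (anyNA(len)) {
    miss <- rownames(counts)[is.na(len)]
    stop("no gene length for: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  counts * 1e9 / outer(len, lib)
})

#' @rdname computeRPKM
#' @export
setMethod("computeRPKM", signature(counts = "CazymeExperiment"),
  function(counts, annotation, ...) {
    x <- counts
    assay(x, "rpkm") <- computeRPKM(assay(x, "counts"), geneAnnotation(x))
    x
  })

# replicate-mean RPKM per (strain, carbon, time) cell; returns list of
# matrices and helpers shared by the profile summary and the caller
.groupMeans <- function(expr, design) {
  des <- as.data.frame(design)
  key <- interaction(des$strain, des$carbon, des$time_h, drop = TRUE)
  grp <- split(seq_len(nrow(des)), key)
  means <- vapply(grp, function(j) rowMeans(expr[, j, drop = FALSE]),
                  numeric(nrow(expr)))
  rownames(means) <- rownames(expr)
  info <- do.call(rbind, lapply(names(grp), function(k) des[grp[[k]][1],
                  c("strain", "carbon", "time_h")]))
  list(means = means, info = info, idx = grp)
}

#' Summarize per-gene induction profiles
#'
#' For every (gene, strain, carbon) combination, reports the replicate-mean
#' RPKM of the strain's glucose baseline (0 h) and the maximum replicate-mean
#' RPKM over the 4/24/72 h timepoints with the achieving timepoint; ties go
#' to the earliest timepoint.
#'
#' @param x a \linkS4class{CazymeExperiment} with an rpkm assay, or an RPKM
#'   matrix.
#' @param design required when \code{x} is a matrix: the design data.frame.
#' @return data.frame with gene_id, strain, carbon, baseline_mean_rpkm,
#'   max_mean_rpkm, argmax_time_h.
#' @export
summarizeProfiles <- function(x, design = NULL) {
  if (is(x, "CazymeExperiment")) {
    expr <- rpkm(x); design <- sampleDesign(x)
  } else {
    expr <- x
    if (is.null(design)) stop("design is required when x is a matrix")
  }
  des <- as.data.frame(design)
  gm <- .groupMeans(expr, des)
  out <- list()
  for (st in intersect(.STRAINS, unique(des$strain))) {
    bsel <- gm$info$strain == st & gm$info$carbon == "baseline_glucose"
    if (!any(bsel)) stop("missing baseline (0 h glucose) samples for strain ", st)
    baseline <- gm$means[, which(bsel)[1]]
    for (ca in intersect(.CARBONS_INDUCED, unique(des$carbon))) {
      cols <- which(gm$info$strain == st & gm$info$carbon == ca)
      cols <- cols[order(gm$info$time_h[cols])]
      if (!length(cols)) next
      sub <- gm$means[, cols, drop = FALSE]
      amax <- max.col(sub, ties.method = "first")
      out[[paste(st, ca)]] <- data.frame(
        gene_id = rownames(expr), strain = st, carbon = ca,
        baseline_mean_rpkm = unname(baseline),
        max_mean_rpkm = sub[cbind(seq_len(nrow(sub)), amax)],
        argmax_time_h = gm$info$time_h[cols][amax],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
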