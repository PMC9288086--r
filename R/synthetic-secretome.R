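# Synthetic SWATH-style secretome: planted protein truth and peptide-level
# abundance tables for the two induction conditions.

#' Default planted secretome truth
#'
#' Builds a protein truth table emulating the structure of the motivating
#' two-condition secretome: 163 proteins of which 90 are CAZymes, grouped
#' into the nine functional groups, with planted AIEP/XIEP enrichment
#' patterns (cellulases mostly AIEP-enriched 2.42-49.38-fold, the GH11-led
#' xylanases XIEP-enriched 1.97-70.92-fold, 3 of 4 chitinases AIEP-enriched
#' 2.42-5.88-fold, all 4 mannanases AIEP-enriched, and roughly two thirds of
#' the remaining groups AIEP-enriched). One exoglucanase is planted as the
#' dominant AIEP protein. Fold values are drawn log-uniformly within each
#' group's range.
#'
#' @param seed integer random seed.
#' @return data.frame with protein_id, functional_group, is_cazyme,
#'   n_peptides, AIEP_level, XIEP_level, planted_class (AIEP_enriched /
#'   XIEP_enriched / no_difference) and planted_fold (AIEP/XIEP).
#' @export
defaultSecretomeTruth <- function(seed = 1) {
  set.seed(seed)
  rlogu <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  mk <- function(group, caz, n, n_aiep, n_xiep, fold_a = c(2.2, 10),
                 fold_x = c(2.2, 10)) {
    cls <- c(rep("AIEP_enriched", n_aiep), rep("XIEP_enriched", n_xiep),
             rep("no_difference", n - n_aiep - n_xiep))
    fold <- rep(1, n)
    fold[cls == "AIEP_enriched"] <- rlogu(n_aiep, fold_a[1], fold_a[2])
    fold[cls == "XIEP_enriched"] <- 1 / rlogu(n_xiep, fold_x[1], fold_x[2])
    data.frame(functional_group = group, is_cazyme = caz,
               planted_class = cls, planted_fold = fold,
               stringsAsFactors = FALSE)
  }
  frac23 <- function(n) round(0.64 * n)
  tr <- rbind(
    mk("cellulase", TRUE, 11, 10, 1, fold_a = c(2.42, 49.38), fold_x = c(2, 5)),
    mk("xylanase", TRUE, 13, 2, 8, fold_a = c(2, 6), fold_x = c(1.97, 70.92)),
    mk("chitinase", TRUE, 4, 3, 0, fold_a = c(2.42, 5.88)),
    mk("mannanase", TRUE, 4, 4, 0, fold_a = c(2, 8)),
    mk("other_hemicellulase", TRUE, 6, frac23(6), 0),
    mk("other_GH", TRUE, 36, frac23(36), 0),
    mk("other", TRUE, 16, frac23(16), 0),      # CAZymes outside the named groups
    mk("protease", FALSE, 8, frac23(8), 0),
    mk("other", FALSE, 30, frac23(30), 0),
    mk("unknown", FALSE, 35, frac23(35), 0))
  n <- nrow(tr)
  tr$protein_id <- sprintf("prot_%03d", seq_len(n))
  tr$n_peptides <- sample(4:12, n, replace = TRUE)
  # Base abundances are banded so that the per-sample median falls on the
  # same no-difference proteins in both conditions: differential proteins
  # live in the abundant or scarce tails (as the dominant secreted enzymes
  # do), far enough out that depletion by the planted fold cannot move them
  # into the middle band. Enriched proteins keep their base level in the
  # enriched condition and are depleted in the other, which keeps the
  # planted truth consistent with median normalization.
  base <- numeric(n)
  nd <- tr$planted_class == "no_difference"
  base[nd] <- 10^stats::rnorm(sum(nd), 4, 0.25)
  k <- sum(!nd)
  tail_hi <- sample(c(TRUE, FALSE), k, replace = TRUE)
  base[!nd][tail_hi] <- 10^stats::rnorm(sum(tail_hi), 6.3, 0.25)
  base[!nd][!tail_hi] <- 10^stats::rnorm(sum(!tail_hi), 2.5, 0.3)
  aiep_up <- tr$planted_fold >= 1
  tr$AIEP_level <- ifelse(aiep_up, base, base * tr$planted_fold)
  tr$XIEP_level <- ifelse(aiep_up, base / tr$planted_fold, base)
  # a dominant exoglucanase-like protein on the AIEP side
  big <- which(tr$functional_group == "cellulase" & tr$planted_class == "AIEP_enriched")[1]
  tr$AIEP_level[big] <- tr$AIEP_level[big] * 40
  tr$XIEP_level[big] <- tr$AIEP_level[big] / tr$planted_fold[big]
  tr[, c("protein_id", "functional_group", "is_cazyme", "n_peptides",
         "AIEP_level", "XIEP_level", "planted_class", "planted_fold")]
}

#' Simulate a peptide-level abundance table
#'
#' For each protein, peptide areas are drawn lognormally around
#' level / n_peptides with coefficient of variation \code{noise_cv},
#' independently per replicate of each condition. A zero planted level gives
#' all-zero areas.
#'
#' @param truth data.frame with protein_id, n_peptides, AIEP_level,
#'   XIEP_level (e.g. \code{\link{defaultSecretomeTruth}}).
#' @param noise_cv lognormal coefficient of variation (default 0.2).
#' @param n_reps replicates per condition (default 3).
#' @param seed integer random seed.
#' @return data.frame with peptide_id, protein_id, sample_id, condition,
#'   replicate, area.
#' @export
simulateSecretome <- function(truth, noise_cv = 0.2, n_reps = 3, seed = 1) {
  stopifnot(all(c("protein_id", "n_peptides", "AIEP_level", "XIEP_level") %in%
                colnames(truth)))
  if (any(truth$AIEP_level < 0) || any(truth$XIEP_level < 0))
    stop("planted levels must be >= 0")
  if (any(truth$n_peptides < 1)) stop("n_peptides must be >= 1")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (cond in .SECRETOME_CONDITIONS) {
    lvl <- if (cond == "AIEP") truth$AIEP_level else truth$XIEP_level
    for (r in seq_len(n_reps)) {
      sid <- sprintf("%s_r%d", cond, r)
      for (i in seq_len(nrow(truth))) {
        np <- truth$n_peptides[i]
        m <- lvl[i] / np
        area <- if (m == 0) rep(0, np) else
          stats::rlnorm(np, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
        rows[[length(rows) + 1]] <- data.frame(
          peptide_id = sprintf("%s_pep%02d", truth$protein_id[i], seq_len(np)),
          protein_id = truth$protein_id[i], sample_id = sid,
          condition = cond, replicate = r, area = area,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
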