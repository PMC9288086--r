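# Shared factor levels for the experimental design and the classification.

.STRAINS <- c("WT", "xyr1_KO")
.CARBONS <- c("baseline_glucose", "no_carbon", "avicel", "xylan")
.CARBONS_INDUCED <- c("no_carbon", "avicel", "xylan")
.POLY_CARBONS <- c("avicel", "xylan")
.TIMES_INDUCED <- c(4, 24, 72)
.ENZYME_CLASSES <- c("GH", "CE", "AA", "PL", "GT", "CBM-only", "non-CAZyme")
.REGULON_GROUPS <- c("NON_INDUCIBLE", "CS_CONTROLLED", "XYR1_SPECIFIC",
                     "OTHER_SPECIFIC", "XYR1_CS_CO", "OTHER_CS_CO")
.FUNCTIONAL_GROUPS <- c("cellulase", "xylanase", "chitinase", "mannanase",
                        "other_hemicellulase", "other_GH", "protease",
                        "other", "unknown")
.SECRETOME_CONDITIONS <- c("AIEP", "XIEP")

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; percentage summaries here follow
#' the convention of rounding ties away from zero instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfAway(c(0.5, 1.5, -0.5), 0)
#' @export
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total
#'
#' Computes \code{100 * n / total} rounded half away from zero, the rule used
#' for all per-class induction percentages and containment fractions.
#'
#' @param n count (numeric, same length as \code{total} or length 1).
#' @param total denominator count.
#' @param decimals decimal places to keep (default 1).
#' @return numeric percentage; 0 when \code{total} is 0 (with a warning).
#' @examples
#' classPercent(106, 258)   # 41.1
#' classPercent(33, 476, 2) # 6.93
#' @export
classPercent <- function(n, total, decimals = 1) {
  stopifnot(is.numeric(n), is.numeric(total), all(n >= 0))
  out <- numeric(length(n))
  zero <- total == 0
  if (any(zero)) warning("zero totals; reporting 0 for those entries")
  out[!zero] <- roundHalfAway(100 * n[!zero] / total[!zero], decimals)
  out
}

# Welch two-sided t-test p-value on two replicate vectors, with the
# degenerate-case convention: if both groups are (numerically) constant,
# p = 1 when the means agree and 0 otherwise.
.welchP <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if ((va + vb) <= .Machine$double.eps * (mean(abs(c(a, b))) + 1)^2) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  out <- tryCatch(stats::t.test(a, b)$p.value,
                  error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  as.numeric(out)
}

# deterministic child seeds so one pipeline seed drives independent stages
.childSeed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
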