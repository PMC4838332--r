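## Exact and classical statistics over interaction outcomes.
##
## The exact 2x2 machinery (two-sided hypergeometric p, conditional-MLE
## odds ratio, exact conditional confidence bounds) is implemented here
## directly on the conditional (noncentral hypergeometric) likelihood;
## stats::fisher.test is used only as an independent cross-check in the
## test suite.

## Conditional distribution of the [1,1] cell given the margins at odds
## ratio psi, computed on the log scale for stability.
condSupport <- function(r1, r2, c1) {
  seq.int(max(0L, c1 - r2), min(r1, c1))
}

condProbs <- function(r1, r2, c1, psi) {
  k <- condSupport(r1, r2, c1)
  logw <- lchoose(r1, k) + lchoose(r2, c1 - k)
  logp <- logw + k * log(psi)
  logp <- logp - max(logp)
  p <- exp(logp)
  list(k = k, p = p / sum(p))
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Exact inference on a 2 x 2 table: the two-sided p-value sums the
#' hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one; the odds ratio is
#' the conditional maximum-likelihood estimate (root of the noncentral
#' hypergeometric score equation); the 95\% confidence interval inverts
#' the one-sided conditional tests at 2.5\% each side. Boundary tables
#' (a zero cell) yield 0 or \code{Inf} estimates/bounds.
#'
#' @param table a \linkS4class{ContingencyTable2x2} or a 2 x 2 matrix
#'   (rows = groups).
#' @return A \linkS4class{FisherResult}.
#' @examples
#' fisherExact(contingencyTable2x2(25, 25, 3, 22))  # OR 7.15
#' @export
fisherExact <- function(table) {
  m <- if (is(table, "ContingencyTable2x2")) table@counts else as.matrix(table)
  if (any(dim(m) != 2L) || any(m < 0)) stop("need a non-negative 2 x 2 table")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("degenerate margins: both rows and both columns must be non-empty")

  supp <- condSupport(r1, r2, c1)
  d0 <- dhyper(supp, c1, c2, r1)        # null probabilities over the support
  dobs <- dhyper(a, c1, c2, r1)
  p <- sum(d0[d0 <= dobs * (1 + 1e-7)])
  p <- min(1, p)

  condMean <- function(logpsi) {
    cp <- condProbs(r1, r2, c1, exp(logpsi))
    sum(cp$k * cp$p)
  }
  or <- if (a == max(supp)) Inf else if (a == min(supp)) 0 else
    exp(uniroot(function(lp) condMean(lp) - a, c(-40, 40), tol = 1e-10)$root)

  upperTail <- function(psi) {          # P(A >= a | psi), increasing in psi
    cp <- condProbs(r1, r2, c1, psi)
    sum(cp$p[cp$k >= a])
  }
  lowerTail <- function(psi) {          # P(A <= a | psi), decreasing in psi
    cp <- condProbs(r1, r2, c1, psi)
    sum(cp$p[cp$k <= a])
  }
  ciLo <- if (a == min(supp)) 0 else
    exp(uniroot(function(lp) upperTail(exp(lp)) - 0.025, c(-40, 40),
                tol = 1e-10)$root)
  ciHi <- if (a == max(supp)) Inf else
    exp(uniroot(function(lp) lowerTail(exp(lp)) - 0.025, c(-40, 40),
                tol = 1e-10)$root)

  new("FisherResult", pTwoSided = p, orCmle = or, ci95 = c(ciLo, ciHi),
      pAdjusted = NA_real_)
}

#' Relative risk of capture
#'
#' How many times more likely the second (unprotected, e.g. ablated)
#' group is to be captured than the first (protected, e.g. tymbaled)
#' group: the ratio of capture proportions, group 2 over group 1.
#' Summaries conventionally report it to one decimal ("x times less
#' likely to be captured" for the protected group).
#'
#' @param table a \linkS4class{ContingencyTable2x2} (rows: protected,
#'   unprotected; columns: non-capture, captured).
#' @return the risk ratio (unprotected over protected); \code{NA} with a
#'   warning when the protected group's capture risk is zero.
#' @examples
#' relativeRiskCapture(contingencyTable2x2(25, 25, 3, 22))  # 1.76
#' @export
relativeRiskCapture <- function(table) {
  stopifnot(is(table, "ContingencyTable2x2"))
  m <- table@counts
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  if (n1 == 0 || n2 == 0) stop("both group totals must be positive")
  risk1 <- m[1, "captured"] / n1
  risk2 <- m[2, "captured"] / n2
  if (risk1 == 0) {
    warning("capture risk of the reference (protected) group is zero; ",
            "relative risk undefined")
    return(NA_real_)
  }
  risk2 / risk1
}

#' Build a non-capture/captured contingency table from metadata
#'
#' Pools "capture, drop" and "consume" into a single captured column and
#' tabulates against non-capture for two groups. Apply
#' \code{\link{firstInteractionFilter}} beforehand.
#'
#' @param meta data.frame with columns \code{outcome} and the grouping
#'   column.
#' @param groups character(2): the two group labels to compare, in order.
#' @param groupCol name of the grouping column, default
#'   \code{"treatment"}.
#' @return A \linkS4class{ContingencyTable2x2}.
#' @export
buildContingency <- function(meta, groups, groupCol = "treatment") {
  stopifnot(is.data.frame(meta), length(groups) == 2L)
  if (!all(c(groupCol, "outcome") %in% names(meta)))
    stop("meta must have columns '", groupCol, "' and 'outcome'")
  g <- meta[[groupCol]]
  unknown <- setdiff(groups, unique(g))
  if (length(unknown) && nrow(meta) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  if (any(is.na(meta$outcome)))
    stop("every interaction must carry a scored outcome")
  cnt <- function(grp) {
    o <- meta$outcome[g == grp]
    c(nc = sum(o == "non_capture"),
      cap = sum(o %in% c("capture_drop", "consume")))
  }
  x1 <- cnt(groups[1]); x2 <- cnt(groups[2])
  contingencyTable2x2(x1["nc"], x1["cap"], x2["nc"], x2["cap"],
                      groups = groups)
}

#' One-sided exact binomial test of rejection (palatability)
#'
#' Rejections of captured moths are coded as successes; the null is
#' that the true rejection probability equals \code{p0} against the
#' one-sided alternative that it is greater. The field convention
#' uses the degenerate null p0 = 0 ("perfectly palatable"), under which
#' any x > 0 rejects trivially; the result is flagged and the
#' informative output is the exact one-sided 95\% lower confidence
#' bound (Clopper-Pearson construction, upper bound 1).
#'
#' @param x number of rejections (successes).
#' @param n number of captures (trials).
#' @param p0 null rejection probability in [0, 1).
#' @return An \linkS4class{ExactBinomialResult}.
#' @examples
#' exactBinomialRejection(14, 22)   # 64% rejected, lower bound 0.44
#' @export
exactBinomialRejection <- function(x, n, p0 = 0) {
  if (x < 0 || n < 0 || x > n) stop("need 0 <= x <= n")
  if (p0 < 0 || p0 >= 1) stop("p0 must lie in [0, 1)")
  x <- as.integer(x); n <- as.integer(n)
  p <- if (x == 0L) 1 else 1 - pbinom(x - 1L, n, p0)
  lower <- if (x == 0L) 0 else qbeta(0.05, x, n - x + 1L)
  new("ExactBinomialResult", x = x, n = n, proportion = x / n,
      pValue = p, ci95 = c(lower, 1), degenerateNull = (p0 == 0))
}

#' Welch's unequal-variance t-test
#'
#' @param a,b numeric samples (each of size >= 2 with positive variance).
#' @return list with \code{t}, \code{df}, \code{p}, \code{ci95} (mean
#'   difference a - b).
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  if (sd(a) == 0 && sd(b) == 0) stop("both samples are degenerate (zero variance)")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci95 = as.numeric(ht$conf.int))
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' @param a,b numeric samples.
#' @return list with \code{W} and \code{p}.
#' @export
mwwTest <- function(a, b) {
  ht <- suppressWarnings(wilcox.test(a, b))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b numeric samples.
#' @return list with \code{D} and \code{p}.
#' @export
ksTest <- function(a, b) {
  ht <- suppressWarnings(ks.test(a, b))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Levene's test after one-sided log-scale outlier removal
#'
#' Values are log10-transformed; values more than 1.5 IQR above the 75th
#' percentile of the transformed distribution (upper side only) are
#' removed; Levene's test for equality of variances is then run on the
#' transformed, trimmed data.
#'
#' @param values positive numeric vector.
#' @param groups grouping vector, same length.
#' @param center centering function for Levene's test,
#'   \code{"median"} (Brown-Forsythe, default) or \code{"mean"}.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{nRemoved}, and \code{kept} (logical vector).
#' @export
leveneAfterOutlierRemoval <- function(values, groups,
                                      center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(values) != length(groups)) stop("values and groups disagree")
  bad <- which(values <= 0 | !is.finite(values))
  if (length(bad))
    stop("non-positive value cannot be log10-transformed at record ", bad[1])
  lv <- log10(values)
  q <- quantile(lv, c(0.25, 0.75), names = FALSE)
  cut <- q[2] + 1.5 * (q[2] - q[1])
  kept <- lv <= cut
  g <- factor(groups[kept])
  lt <- car::leveneTest(lv[kept] ~ g,
                        center = if (center == "median") median else mean)
  list(statistic = lt[1, "F value"], df = lt[["Df"]], p = lt[1, "Pr(>F)"],
       nRemoved = sum(!kept), kept = kept)
}

#' Bonferroni correction
#'
#' Multiplies p-values by the family size m and caps at 1 (adjusted
#' p-values greater than 1 are reported as 1).
#'
#' @param p p-values in [0, 1].
#' @param m family size, at least \code{length(p)}.
#' @return adjusted p-values.
#' @examples
#' bonferroni(c(0.5, 0.01), m = 3)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of tests")
  pmin(1, m * p)
}

#' Keep only the first interaction of each moth
#'
#' Pseudoreplication control: retains the earliest interaction per moth
#' id (by timestamp, ties broken deterministically by interaction id).
#'
#' @param meta data.frame with columns \code{moth_id},
#'   \code{interaction_id} and \code{timestamp}.
#' @return the filtered data.frame (original row order preserved).
#' @export
firstInteractionFilter <- function(meta) {
  need <- c("moth_id", "interaction_id", "timestamp")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "))
  if (any(is.na(meta$moth_id)) || any(is.na(meta$interaction_id)))
    stop("missing moth or interaction ids")
  ord <- order(meta$moth_id, meta$timestamp, meta$interaction_id)
  first <- !duplicated(meta$moth_id[ord])
  keepIds <- meta$interaction_id[ord][first]
  meta[meta$interaction_id %in% keepIds, , drop = FALSE]
}

#' Species comparison of evasion frequency
#'
#' Turn-away interactions are excluded (rare in the field); treatments
#' are pooled within species (treatment does not affect whether evasion
#' is performed); a species x (dive, no evasion) table is tested with
#' Fisher's exact machinery.
#'
#' @param meta data.frame with columns \code{species} and
#'   \code{evasion}.
#' @param species character(2): the two species to compare, in order
#'   (first species in the numerator of the odds ratio).
#' @return list with \code{table} (2 x 2 matrix) and \code{fisher}
#'   (a \linkS4class{FisherResult}).
#' @export
evasionComparison <- function(meta,
                              species = c("P_roseicapitis", "C_martini")) {
  stopifnot(all(c("species", "evasion") %in% names(meta)))
  meta <- meta[!is.na(meta$evasion) & meta$evasion != "turn_away", ,
               drop = FALSE]
  cnt <- function(sp) {
    e <- meta$evasion[meta$species == sp]
    if (length(e) == 0)
      stop("no scored interactions for species ", sp)
    c(dive = sum(e == "dive"), no = sum(e == "no_evasion"))
  }
  x1 <- cnt(species[1]); x2 <- cnt(species[2])
  tab <- matrix(c(x1, x2), nrow = 2, byrow = TRUE,
                dimnames = list(species, c("dive", "no_evasion")))
  list(table = tab, fisher = fisherExact(tab))
}
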