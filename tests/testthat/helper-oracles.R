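## Independent brute-force oracles used across the suite. These are
## deliberately naive re-derivations from first principles; they never
## call the package code paths they check.

## Two-sided Fisher p by explicit enumeration of all tables with the
## observed margins: probability mass of tables no more probable than
## the observed one, with hypergeometric probabilities computed from
## factorials directly.
oracleFisherP <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1)
  p <- exp(logp)
  pobs <- p[ks == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

## Conditional-MLE odds ratio by direct maximization of the noncentral
## hypergeometric log-likelihood on a log-psi grid plus optimize().
oracleFisherOR <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  if (a == max(ks)) return(Inf)
  if (a == min(ks)) return(0)
  logw <- lchoose(r1, ks) + lchoose(r2, c1 - ks)
  nll <- function(lp) {
    z <- logw + ks * lp
    -(a * lp - (max(z) + log(sum(exp(z - max(z))))))
  }
  exp(optimize(nll, c(-30, 30), tol = 1e-10)$minimum)
}

## All-pairs critical-window jamming oracle: for every attack-phase call
## (first bout), test every click arrival against the +/- 2 ms window,
## given a distance function of time.
oracleJamming <- function(onsets, durations, clicks, distFun) {
  ipi <- 1000 * diff(onsets)
  att <- ipi < 50
  if (!any(att)) return(list(used = 0L, unaffected = 0L, fraction = NA_real_))
  first <- which(att)[1]
  stops <- which(!att & seq_along(ipi) > first)
  last <- if (length(stops)) stops[1] - 1L else length(ipi)
  idx <- (first:last) + 1L
  arrivals <- vapply(clicks, function(ct) ct + distFun(ct) / 343, numeric(1))
  flags <- vapply(idx, function(i) {
    mid <- onsets[i] + durations[i] / 2
    ret <- mid + 2 * distFun(mid) / 343
    any(arrivals >= ret - 0.002 & arrivals <= ret + 0.002)
  }, logical(1))
  list(used = length(idx), unaffected = sum(!flags),
       fraction = mean(!flags))
}

## Closest approach of two constant-velocity tracks: minimize
## |dp + dv t| analytically.
oracleClosestApproach <- function(p1, v1, p2, v2) {
  dp <- p2 - p1; dv <- v2 - v1
  tm <- if (sum(dv^2) < 1e-12) 0 else -sum(dp * dv) / sum(dv^2)
  list(t = tm, d = sqrt(sum((dp + dv * tm)^2)))
}

## Straight constant-velocity Trajectory3D helper.
lineTrajectory <- function(entity, p0, v, t) {
  pos <- outer(t, c(1, 1, 1)) * 0
  for (j in 1:3) pos[, j] <- p0[j] + v[j] * t
  Trajectory3D(entity, t, pos[, 1], pos[, 2], pos[, 3])
}

## EventStream from an IPI sequence in ms (first onset at t0).
streamFromIpis <- function(ipis_ms, t0 = 0, clicks = numeric(),
                           duration_s = 0.002) {
  EventStream(callOnsets = t0 + cumsum(c(0, ipis_ms)) / 1000,
              callDurations = duration_s, clickTimes = clicks)
}
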