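test_that("echo return and click arrival times follow 343 m/s acoustics", {
  expect_equal(echoReturnTime(1.0, 1.715), 1.010)
  expect_equal(echoReturnTime(0.5, 0), 0.5)
  expect_equal(echoReturnTime(0, 34.3), 0.2)
  expect_equal(clickArrivalTime(2.0, 0.343), 2.001)
  expect_equal(clickArrivalTime(0.5, 3.43), 0.510)
  expect_equal(clickArrivalTime(1.2, 0), 1.2)
  expect_error(echoReturnTime(1, -0.1))
  expect_error(clickArrivalTime(1, -0.1))
})

test_that("attack-call selection keeps the first below-50 ms bout", {
  s <- streamFromIpis(c(60, 40, 10, 70, 40))
  sel <- selectAttackCalls(s)
  expect_equal(sel$index, c(3L, 4L))           # calls ending the 40, 10 ms IPIs
  expect_equal(nrow(selectAttackCalls(streamFromIpis(c(60, 70, 90)))), 0L)
  # pooling adds the second bout's call
  expect_equal(selectAttackCalls(s, allBouts = TRUE)$index, c(3L, 4L, 6L))
  # call midpoints include half the call duration
  expect_equal(sel$midpoint_s, sel$onset_s + 0.001)
})

## Stationary bat and moth a fixed distance apart make window timing
## fully analytic.
stationaryPaths <- function(d, tmax = 3) {
  t <- seq(0, tmax, by = 1 / 60)
  list(bat = smoothTrajectory(lineTrajectory("bat", c(0, 0, 2), c(0, 0, 0), t), 0),
       moth = smoothTrajectory(lineTrajectory("moth", c(d, 0, 2), c(0, 0, 0), t), 0))
}

test_that("jamming assessment scores exact-window hits and silent moths", {
  d <- 2
  p <- stationaryPaths(d)
  s <- streamFromIpis(c(60, 40, 40, 40, 40), t0 = 1)   # 4 attack calls
  # a silent (ablated) moth leaves every echo unaffected
  r0 <- assessJamming(s, p$bat, p$moth)
  expect_equal(r0@nEchoesUsed, 4L)
  expect_equal(fractionUnaffected(r0), 1.0)

  # place one click so its arrival hits the 2nd window's centre exactly
  mids <- selectAttackCalls(s)$midpoint_s
  ret <- echoReturnTime(mids[2], d)
  hit <- ret - d / 343
  s1 <- EventStream(callOnsets = s@callOnsets, callDurations = s@callDurations,
                    clickTimes = hit)
  r1 <- assessJamming(s1, p$bat, p$moth)
  expect_equal(r1@nUnaffected, 3L)
  expect_equal(fractionUnaffected(r1), 0.75)
  expect_true(r1@windows$overlapped[2])

  # a click outside every window changes nothing
  s2 <- EventStream(callOnsets = s@callOnsets, callDurations = s@callDurations,
                    clickTimes = hit + 0.0025)
  expect_equal(fractionUnaffected(assessJamming(s2, p$bat, p$moth)), 1.0)
})

test_that("jamming matches the all-pairs brute-force oracle on random instances", {
  set.seed(11)
  d <- 1.5
  p <- stationaryPaths(d, tmax = 4)
  distFun <- function(t) d
  for (rep in 1:12) {
    nAttack <- sample(3:20, 1)
    ipis <- c(runif(2, 55, 100), runif(nAttack, 9, 45), runif(1, 60, 100),
              runif(sample(0:3, 1), 20, 45))
    onsets <- 1 + cumsum(c(0, ipis)) / 1000
    nClicks <- sample(0:25, 1)
    clicks <- sort(runif(nClicks, 1, max(onsets) + 0.05))
    s <- EventStream(callOnsets = onsets, callDurations = 0.002,
                     clickTimes = clicks)
    r <- assessJamming(s, p$bat, p$moth)
    o <- oracleJamming(onsets, rep(0.002, length(onsets)), clicks, distFun)
    expect_equal(r@nEchoesUsed, o$used)
    expect_equal(r@nUnaffected, o$unaffected)
  }
})

test_that("jamming is translation invariant and monotone in added clicks", {
  d <- 2
  t <- seq(0, 4, by = 1 / 60)
  mk <- function(shift) {
    list(bat = smoothTrajectory(
           lineTrajectory("bat", c(0, 0, 2), c(0, 0, 0), t + shift), 0),
         moth = smoothTrajectory(
           lineTrajectory("moth", c(d, 0, 2), c(0, 0, 0), t + shift), 0))
  }
  set.seed(5)
  ipis <- c(70, runif(8, 10, 45), 80)
  clicks <- sort(runif(10, 1, 1.5))
  s <- EventStream(callOnsets = 1 + cumsum(c(0, ipis)) / 1000,
                   callDurations = 0.002, clickTimes = clicks)
  p0 <- mk(0)
  r0 <- assessJamming(s, p0$bat, p0$moth)
  shift <- 7.25
  sS <- EventStream(callOnsets = s@callOnsets + shift,
                    callDurations = s@callDurations,
                    clickTimes = s@clickTimes + shift)
  pS <- mk(shift)
  rS <- assessJamming(sS, pS$bat, pS$moth)
  expect_equal(fractionUnaffected(r0), fractionUnaffected(rS))
  expect_equal(r0@windows$overlapped, rS@windows$overlapped)

  # adding clicks can only decrease the unaffected fraction
  fracs <- vapply(seq(0, 20, by = 5), function(k) {
    extra <- if (k > 0) sort(runif(k, 1, 1.6)) else numeric()
    s2 <- EventStream(callOnsets = s@callOnsets, callDurations = s@callDurations,
                      clickTimes = sort(c(clicks, extra)))
    fractionUnaffected(assessJamming(s2, p0$bat, p0$moth))
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("calls without 3-D coverage are excluded with a reason, not extrapolated", {
  d <- 2
  tshort <- seq(1.0, 1.12, by = 1 / 60)   # covers only part of the bout
  bat <- smoothTrajectory(lineTrajectory("bat", c(0, 0, 2), c(0, 0, 0), tshort), 0)
  moth <- smoothTrajectory(lineTrajectory("moth", c(d, 0, 2), c(0, 0, 0), tshort), 0)
  s <- streamFromIpis(c(60, 40, 40, 40, 40), t0 = 1)
  r <- assessJamming(s, bat, moth)
  expect_true(any(r@windows$excluded))
  expect_match(r@windows$reason[r@windows$excluded][1], "coverage")
  expect_equal(r@nEchoesUsed, sum(!r@windows$excluded))
  # zero usable echoes: flagged NA fraction, no error
  tnone <- seq(10, 11, by = 1 / 60)
  batN <- smoothTrajectory(lineTrajectory("bat", c(0, 0, 2), c(0, 0, 0), tnone), 0)
  mothN <- smoothTrajectory(lineTrajectory("moth", c(d, 0, 2), c(0, 0, 0), tnone), 0)
  rN <- assessJamming(s, batN, mothN)
  expect_equal(rN@nEchoesUsed, 0L)
  expect_true(is.na(fractionUnaffected(rN)))
})
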