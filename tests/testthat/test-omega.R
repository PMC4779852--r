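test_that("noise-free first-order decay recovers omega(A->A) = -k", {
  k <- 0.01
  sp <- decaySpline(k = k, z = 30L)
  om <- omegaSeries(sp, sp)
  g <- omegaGrid(om); span <- diff(range(g))
  interior <- g >= min(g) + 0.2 * span & g <= max(g) - 0.2 * span &
    !omegaMask(om)
  expect_true(any(interior))
  expect_lt(max(abs(omegaValues(om)[interior] - (-k))), 0.02 * k)
})

test_that("a constant source masks every grid point, with a warning", {
  t <- seq(0, 100, by = 10)
  spConst <- fitSmoothingSpline(t, rep(2, length(t)), lambda = 0,
                                metaboliteId = "C")
  spB <- fitSmoothingSpline(t, sin(t / 20), lambda = 0,
                            metaboliteId = "B")
  expect_warning(om <- omegaSeries(spConst, spB), "masked")
  expect_true(all(omegaMask(om)))
  expect_true(all(is.na(omegaValues(om))))
})

test_that("values equal the element-wise ratio of exported derivative tables", {
  set.seed(30)
  t <- sort(runif(12, 0, 100))
  spA <- fitSmoothingSpline(t, rnorm(12), lambda = 1, metaboliteId = "a")
  spB <- fitSmoothingSpline(t, rnorm(12), lambda = 0.1,
                            metaboliteId = "b")
  om <- omegaSeries(spA, spB)
  g <- omegaGrid(om)
  pA <- withr::local_tempfile(); pB <- withr::local_tempfile()
  writeFitTable(spA, pA, gridSize = length(g))
  writeFitTable(spB, pB, gridSize = length(g))
  fa <- read.delim(pA)$dS_dt
  dfb <- read.delim(pB)$d2S_dt2
  ok <- !omegaMask(om)
  ratio <- (dfb / fa)[ok]
  expect_lt(max(abs(omegaValues(om)[ok] - ratio)),
            1e-12 * max(abs(ratio)))
})

test_that("the mask covers exactly the near-zero denominator band", {
  set.seed(31)
  t <- seq(0, 100, length.out = 15)
  spA <- fitSmoothingSpline(t, sin(t / 15), lambda = 0,
                            metaboliteId = "a")
  om <- omegaSeries(spA, spA, epsilonRel = 0.05)
  fa <- evaluateSpline(spA, omegaGrid(om), order = 1L)
  eps <- 0.05 * max(abs(fa))
  expect_identical(omegaMask(om), abs(fa) <= eps)
  expect_equal(om@epsilon, eps)
  expect_true(all(is.finite(omegaValues(om)[!omegaMask(om)])))
})

test_that("absOmega takes absolute values, keeps the mask, and is idempotent", {
  om <- new("OmegaSeries", source = "a", target = "b",
            grid = c(0, 1, 2, 3), values = c(-2, 3, -0.5, NA),
            mask = c(FALSE, FALSE, FALSE, TRUE), epsilon = 0.1)
  ab <- absOmega(om)
  expect_equal(omegaValues(ab)[1:3], c(2, 3, 0.5))
  expect_identical(omegaMask(ab), omegaMask(om))
  expect_equal(omegaValues(absOmega(ab)), omegaValues(ab))
  allMasked <- new("OmegaSeries", source = "a", target = "b",
                   grid = 0:1, values = c(NA_real_, NA_real_),
                   mask = c(TRUE, TRUE), epsilon = 1)
  expect_true(all(omegaMask(absOmega(allMasked))))
})

test_that("strength classification follows the thresholds", {
  om <- new("OmegaSeries", source = "a", target = "b",
            grid = 1:4, values = c(0, 100, 0.5, NA),
            mask = c(FALSE, FALSE, FALSE, TRUE), epsilon = 0.1)
  lab <- classifyStrength(om, low = 0.1, high = 10)
  expect_identical(lab, c("weak", "strong", "intermediate",
                          NA_character_))
  expect_error(classifyStrength(om, low = 1, high = 1), "low < high")
  set.seed(32)
  vals <- rnorm(50); mask <- runif(50) < 0.2
  vals[mask] <- NA
  omr <- new("OmegaSeries", source = "a", target = "b",
             grid = seq_len(50), values = vals, mask = mask,
             epsilon = 0.1)
  med <- median(abs(vals), na.rm = TRUE)
  lab <- classifyStrength(omr, 0.1 * med, 10 * med)
  direct <- ifelse(mask, NA,
                   ifelse(abs(vals) >= 10 * med, "strong",
                          ifelse(abs(vals) <= 0.1 * med, "weak",
                                 "intermediate")))
  expect_identical(lab, direct)
})

test_that("peakTime returns the earliest argmax of |omega| among unmasked points", {
  daySec <- 86400
  grid <- (1:14) * daySec
  vals <- dnorm(1:14, mean = 8, sd = 2)
  om <- new("OmegaSeries", source = "Phe", target = "Flav",
            grid = grid, values = vals, mask = rep(FALSE, 14),
            epsilon = 0)
  expect_equal(peakTime(om), 8 * daySec)
  tie <- new("OmegaSeries", source = "a", target = "b", grid = 1:4,
             values = c(1, 5, -5, 2), mask = rep(FALSE, 4),
             epsilon = 0)
  expect_equal(peakTime(tie), 2)   # |5| at t=2 and t=3: earlier wins
  set.seed(33)
  v <- rnorm(40); m <- runif(40) < 0.3; v[m] <- NA
  omr <- new("OmegaSeries", source = "a", target = "b", grid = 1:40,
             values = v, mask = m, epsilon = 0)
  expect_equal(peakTime(omr), which.max(replace(abs(v), m, -Inf)))
  allm <- new("OmegaSeries", source = "a", target = "b", grid = 1:2,
              values = c(NA_real_, NA_real_), mask = c(TRUE, TRUE),
              epsilon = 0)
  expect_error(peakTime(allm), "masked")
})

test_that("omegaAllPairs computes exactly the Y = 1 cells", {
  net <- parseReactions("A -> B\nB -> C\nC -> D")
  Y <- interactionMatrix(net)
  sc <- benchmarkScenario("chain4")
  tr <- simulateTrajectories(sc$model, sc$times)
  fits <- lapply(rownames(tr), function(id)
    fitSmoothingSpline(sc$times, tr[id, ], lambda = 0,
                       metaboliteId = id))
  names(fits) <- rownames(tr)
  oms <- suppressWarnings(omegaAllPairs(fits, Y))
  e <- interactionEntries(Y)
  expect_length(oms, sum(e))
  for (s in oms)
    expect_identical(e[s@target, s@source], 1L)
  expect_setequal(names(oms),
                  c("A->A", "A->B", "B->B", "B->C", "C->C", "C->D"))
  # missing spline for a required metabolite is a named error
  expect_error(omegaAllPairs(fits[c("A", "B", "C")], Y), "D")
})

test_that("an all-zero interaction matrix yields no series", {
  Y <- new("InteractionMatrix",
           entries = matrix(0L, 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B"))))
  expect_length(omegaAllPairs(list(), Y), 0L)
})

test_that("omega is invariant to joint scaling and linear in the target", {
  k <- 0.015
  t <- seq(0, 3 * log(2) / k, length.out = 25)
  a <- exp(-k * t); b <- 2 + cos(t / 40)
  fit <- function(v, id) fitSmoothingSpline(t, v, lambda = 0,
                                            metaboliteId = id)
  base <- omegaSeries(fit(a, "a"), fit(b, "b"))
  joint <- omegaSeries(fit(7 * a, "a"), fit(7 * b, "b"))
  ok <- !omegaMask(base)
  expect_equal(omegaValues(joint)[ok], omegaValues(base)[ok],
               tolerance = 1e-9)
  targetOnly <- omegaSeries(fit(a, "a"), fit(7 * b, "b"))
  expect_equal(omegaValues(targetOnly)[ok], 7 * omegaValues(base)[ok],
               tolerance = 1e-9)
})

test_that("expressing time in hours scales omega by 3600", {
  k <- 0.01
  t <- seq(0, 3 * log(2) / k, length.out = 25)
  y <- exp(-k * t)
  spS <- fitSmoothingSpline(t, y, lambda = 0)
  spH <- fitSmoothingSpline(t / 3600, y, lambda = 0)
  omS <- omegaSeries(spS, spS)
  omH <- omegaSeries(spH, spH, grid = omegaGrid(omS) / 3600)
  ok <- !omegaMask(omS) & !omegaMask(omH)
  expect_equal(omegaValues(omH)[ok], 3600 * omegaValues(omS)[ok],
               tolerance = 1e-6)
})

test_that("noisy decay recovers -k within 15% via GCV smoothing", {
  k <- 0.01
  sc <- benchmarkScenario("decay")
  tr <- simulateTrajectories(sc$model, sc$times)
  ser <- suppressWarnings(makeReplicates(tr, sc$times, cv = 0.05, r = 5L,
                                         seed = 1, summarize = TRUE))
  A <- ser[["A"]]
  lam <- selectLambdaGCV(seriesTimes(A), seriesMeans(A),
                         seriesWeights(A))
  sp <- fitSmoothingSpline(seriesTimes(A), seriesMeans(A),
                           seriesWeights(A), lam, metaboliteId = "A")
  om <- omegaSeries(sp, sp)
  g <- omegaGrid(om); span <- diff(range(g))
  mid <- g >= min(g) + 0.2 * span & g <= max(g) - 0.2 * span &
    !omegaMask(om)
  est <- median(omegaValues(om)[mid])
  expect_lt(abs(est - (-k)), 0.15 * k)
})

test_that("omega tables export the documented long and summary formats", {
  sp <- decaySpline()
  om <- omegaSeries(sp, sp)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  tabs <- writeOmegaTables(list(om), p1, p2)
  expect_named(tabs$long, c("source", "target", "t_s", "omega_per_s",
                            "abs_omega_per_s", "masked", "label"))
  expect_named(tabs$summary, c("source", "target", "peak_time_s",
                               "peak_abs_omega_per_s"))
  back <- read.delim(p1)
  expect_equal(nrow(back), length(omegaGrid(om)))
  expect_equal(back$abs_omega_per_s[!back$masked],
               abs(back$omega_per_s[!back$masked]))
})
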