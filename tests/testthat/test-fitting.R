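test_that("BIC follows its definition", {
  expect_equal(bicScore(0, k = 0, n = 10), 0)
  expect_equal(bicScore(-100, k = 2, n = 216), 210.7506, tolerance = 1e-4)
  expect_equal(bicScore(-50, k = 4, n = 100) - bicScore(-50, 2, 100),
               2 * log(100))
  expect_error(bicScore(-10, 1, 0), "at least 1")
})

test_that("response log-likelihood matches the per-trial oracle sum", {
  trials <- rbind(
    makeBlock(block = 1, condition = "NU",
              responses = c("yes", "yes", "no", "no", "no", "no")),
    makeBlock(block = 2, condition = "UN",
              responses = c("no", "no", "no", "yes", "yes", "yes"),
              missed = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  p <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
  ll <- responseLogLik(trials, p)
  expect_equal(as.numeric(ll), oracleLogLik(trials, 0.55, 0.23, 0.3))
  expect_identical(attr(ll, "nObs"), 11L)

  # constant posterior under the frozen-prior variant
  allYes <- makeBlock(responses = rep("yes", 6))
  llc <- responseLogLik(allYes, modelParams(C = 0.5, lam = 1),
                        modelVariant("M3"))
  expect_equal(as.numeric(llc), 6 * log(0.5), tolerance = 1e-6)

  allMissed <- makeBlock(missed = rep(TRUE, 6))
  expect_error(responseLogLik(allMissed, p), "no scorable")
})

test_that("missed trials advance the trace without contributing", {
  resp <- c("yes", "yes", "no", "no", "no", "no")
  full <- makeBlock(responses = resp)
  holed <- makeBlock(responses = resp,
                     missed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  p <- modelParams(C = 0.55, lam = 0.4, sigma = 0.3)
  tr <- runBlock(blockDesign("NU"), p)
  pp <- posteriors(tr)
  expect_equal(as.numeric(responseLogLik(holed, p)),
               as.numeric(responseLogLik(full, p)) - log(1 - pp[3]))
})

test_that("grid search finds the maximizing grid point deterministically", {
  set.seed(21)
  sim <- simulateCohort(cohortSpec(nParticipants = 1, seed = 21))
  tp <- sim$trials
  g <- fitGrid(CStep = 0.05, lamStep = 0.05)
  fit <- gridFit(tp, "M1", grid = g)
  # exhaustive check against the slow per-point evaluation
  best <- -Inf
  for (C in g$C) for (lam in g$lam) {
    ll <- as.numeric(responseLogLik(
      tp, modelParams(C = C, lam = lam, sigma = 0.3)))
    if (ll > best) best <- ll
  }
  expect_equal(as.numeric(fit@loglik), best, tolerance = 1e-10)
  expect_true(params(fit)@C %in% g$C && params(fit)@lam %in% g$lam)
  expect_equal(bic(fit), bicScore(fit@loglik, 2, nObs(fit)))

  # a grid containing the generating point scores at least as high there
  truthLL <- as.numeric(responseLogLik(
    tp, modelParams(C = g$C[which.min(abs(g$C - sim$truth$C))],
                    lam = g$lam[which.min(abs(g$lam - sim$truth$lam))],
                    sigma = 0.3)))
  expect_gte(as.numeric(fit@loglik), truthLL)

  single <- list(C = 0.5, lam = 0.25)
  fs <- gridFit(tp, "M1", grid = single)
  expect_equal(params(fs)@C, 0.5)
  expect_equal(params(fs)@lam, 0.25)
  expect_error(gridFit(tp, "M1", grid = list(C = numeric(0), lam = 0.1)),
               "degenerate")
})

test_that("the likelihood is invariant to trial-row ordering", {
  sim <- simulateCohort(cohortSpec(nParticipants = 1, seed = 33))
  tp <- sim$trials
  shuffled <- tp[sample(nrow(tp)), ]
  p <- modelParams(C = 0.6, lam = 0.3, sigma = 0.3)
  expect_equal(as.numeric(responseLogLik(tp, p)),
               as.numeric(responseLogLik(shuffled, p)))
  expect_equal(bic(gridFit(tp, "M2")), bic(gridFit(shuffled, "M2")))
})

test_that("threshold is recovered from likelihood-only data at the design size", {
  sim <- simulateCohort(cohortSpec(nParticipants = 1, lamMean = 0,
                                   lamSd = 0, seed = 5))
  fit <- gridFit(sim$trials, "M2")
  expect_lt(abs(params(fit)@C - sim$truth$C), 0.05)
})

test_that("M4 fits condition-specific weights that beat a mismatched shared weight", {
  # build a participant whose NU and UN persistence genuinely differ
  pars <- modelParams(C = 0.5, lamNU = 0.05, lamUN = 0.6, sigma = 0.3)
  v4 <- modelVariant("M4")
  set.seed(9)
  blocks <- lapply(1:30, function(b) {
    cond <- if (b %% 2) "NU" else "UN"
    pp <- posteriors(runBlock(blockDesign(cond), pars, v4))
    makeBlock(block = b, condition = cond,
              responses = ifelse(runif(6) < pp, "yes", "no"))
  })
  tp <- do.call(rbind, blocks)
  f4 <- gridFit(tp, "M4", grid = fitGrid(0.02, 0.02))
  f1 <- gridFit(tp, "M1", grid = fitGrid(0.02, 0.02))
  expect_gte(as.numeric(f4@loglik), as.numeric(f1@loglik))
  expect_lt(params(f4)@lamNU, params(f4)@lamUN)
  expect_true(is.na(params(f4)@lam))
})

test_that("model comparison tabulates all variants on identical data", {
  sim <- simulateCohort(cohortSpec(nParticipants = 2, seed = 3))
  cmp <- compareModels(sim$trials, grid = fitGrid(0.05, 0.05))
  expect_identical(nrow(cmp$fits), 8L)
  expect_identical(length(unique(cmp$fits$nObs[cmp$fits$participant == 1])),
                   1L)
  expect_true(cmp$winner %in% c("M1", "M2", "M3", "M4"))
  expect_identical(sort(unique(cmp$fits$variant)),
                   c("M1", "M2", "M3", "M4"))
  # summed and pooled group BIC agree with their definitions
  f1 <- cmp$fits[cmp$fits$variant == "M1", ]
  expect_equal(cmp$group$sumBic[cmp$group$variant == "M1"], sum(f1$bic))
  expect_equal(cmp$group$pooledBic[cmp$group$variant == "M1"],
               bicScore(sum(f1$loglik), k = sum(f1$k), n = sum(f1$nObs)))
})
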