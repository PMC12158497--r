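test_that("scene likelihood matches its closed form and stated values", {
  p <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
  expect_equal(sceneLikelihood(0.55, p), 0.5)
  # threshold at the distribution mean gives one half for any spread
  for (s in c(0.05, 0.3, 1))
    expect_equal(sceneLikelihood(0.4, modelParams(C = 0.4, sigma = s)), 0.5)
  expect_equal(sceneLikelihood(1, modelParams(C = 0.55, sigma = 0.1)),
               0.9999966, tolerance = 1e-6)
  expect_equal(sceneLikelihood(0, p), 0.0334, tolerance = 1e-3)
  expect_error(sceneLikelihood(0.5, modelParams(C = 0.5, sigma = 0)),
               "sigma")
})

test_that("likelihood equals the right tail area beyond C (symmetry)", {
  grid <- expand.grid(a = seq(0, 1, length.out = 10),
                      C = seq(0.05, 0.95, length.out = 10),
                      s = seq(0.05, 1, length.out = 10))
  lhs <- sceneLikelihood(grid$a, grid$C, sigma = grid$s)
  rhs <- 1 - pnorm(grid$C, mean = grid$a, sd = grid$s)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  # strictly increasing in alpha, strictly decreasing in C
  expect_true(all(diff(sceneLikelihood(seq(0, 1, 0.1),
                                       modelParams(C = 0.5))) > 0))
  expect_true(all(diff(sapply(seq(0.1, 0.9, 0.1), function(C)
    sceneLikelihood(0.5, modelParams(C = C)))) < 0))
})

test_that("posterior update has the stated limits and value", {
  expect_equal(posteriorUpdate(0.31, 0.9, lam = 0), 0.9)
  expect_equal(posteriorUpdate(0.31, 0.9, lam = 1), 0.31)
  expect_equal(posteriorUpdate(0.5, 0.9, lam = 0.5),
               sqrt(0.9) / (sqrt(0.9) + sqrt(0.1)))
  expect_equal(posteriorUpdate(0.5, 0.9, lam = 0.5), 0.75)
  expect_error(posteriorUpdate(0.5, 0.9, lam = 1.2), "lam")
  # monotone non-decreasing in both prior and likelihood
  ps <- posteriorUpdate(seq(0.05, 0.95, 0.05), 0.7, 0.4)
  expect_true(all(diff(ps) >= 0))
  ps <- posteriorUpdate(0.3, seq(0.05, 0.95, 0.05), 0.4)
  expect_true(all(diff(ps) >= 0))
  # extreme inputs survive clipping
  expect_true(is.finite(posteriorUpdate(1, 0, 0.5)))
})

test_that("block traces chain posteriors into priors and match the oracle", {
  p <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
  tr <- runBlock(blockDesign("NU"), p)
  orc <- oracleTrace(seq(1, 0, by = -0.2), 0.55, 0.23, 0.3)
  expect_equal(likelihoods(tr), orc$likelihood)
  expect_equal(priors(tr), orc$prior)
  expect_equal(posteriors(tr), orc$posterior)
  expect_equal(priors(tr)[1], 0.5)
  expect_equal(priors(tr)[-1], posteriors(tr)[-6])

  # degenerate variants
  trM2 <- runBlock(blockDesign("UN"), p, modelVariant("M2"))
  expect_equal(posteriors(trM2), likelihoods(trM2))
  trM3 <- runBlock(blockDesign("UN"), p, modelVariant("M3"))
  expect_equal(posteriors(trM3), rep(0.5, 6), tolerance = 1e-7)

  # M4 routes the condition-specific weight
  p4 <- modelParams(C = 0.55, lamNU = 0.1, lamUN = 0.9, sigma = 0.3)
  trNU <- runBlock(blockDesign("NU"), p4, modelVariant("M4"))
  expect_equal(posteriors(trNU),
               oracleTrace(seq(1, 0, -0.2), 0.55, 0.1, 0.3)$posterior)
  trUN <- runBlock(blockDesign("UN"), p4, modelVariant("M4"))
  expect_equal(posteriors(trUN),
               oracleTrace(seq(0, 1, 0.2), 0.55, 0.9, 0.3)$posterior)

  expect_error(blockDesign("NU", alphas = numeric(0)), "descend")
  expect_error(runBlock(blockDesign("NU"), modelParams(C = 0.5),
                        modelVariant("M1")), "lambda")
})

test_that("a one-trial update through the block runner equals the bare update", {
  # BINARY designs accept arbitrary endpoint sequences; check the first
  # step of a trace against a single posteriorUpdate
  p <- modelParams(C = 0.55, lam = 0.4, sigma = 0.3)
  tr <- runBlock(blockDesign("BINARY", alphas = c(1, 0, 1, 0, 1, 0)), p)
  L1 <- clipProb(sceneLikelihood(1, p))
  expect_equal(posteriors(tr)[1], posteriorUpdate(0.5, L1, 0.4))
})

test_that("presentation order induces hysteresis at middle naturalness", {
  mids <- c(0.4, 0.6)
  for (lam in c(0.1, 0.3, 0.6, 0.9))
    for (C in c(0.25, 0.5, 0.75))
      for (s in c(0.1, 0.3, 0.8)) {
        p <- modelParams(C = C, lam = lam, sigma = s)
        nu <- runBlock(blockDesign("NU"), p)
        un <- runBlock(blockDesign("UN"), p)
        for (a in mids) {
          pNU <- posteriors(nu)[abs(alphas(nu) - a) < 1e-9]
          pUN <- posteriors(un)[abs(alphas(un) - a) < 1e-9]
          expect_gte(pNU, pUN)
        }
      }
  # no persistence, no hysteresis
  p0 <- modelParams(C = 0.5, lam = 0, sigma = 0.3)
  nu <- runBlock(blockDesign("NU"), p0)
  un <- runBlock(blockDesign("UN"), p0)
  expect_equal(posteriors(nu), rev(posteriors(un)))
})

test_that("transition probabilities are the stated products and sum to one", {
  expect_equal(transitionProbs(1, 1),
               c(yy = 1, yn = 0, ny = 0, nn = 0))
  expect_equal(transitionProbs(0.5, 0.75),
               c(yy = 0.375, yn = 0.125, ny = 0.375, nn = 0.125))
  set.seed(4)
  for (i in 1:50) {
    q <- runif(1); p <- runif(1)
    expect_lt(abs(sum(transitionProbs(q, p)) - 1), 1e-12)
  }
  expect_error(transitionProbs(1.2, 0.5), "must lie in")
})

test_that("parameter and trace containers enforce their invariants", {
  expect_error(modelParams(C = 0.5, lam = 1.5), "lam")
  expect_error(modelParams(C = Inf), "finite")
  expect_error(blockDesign("NU", alphas = seq(0, 1, 0.2)), "descend")
  expect_error(blockDesign("BINARY", alphas = c(0.4, rep(1, 5))),
               "BINARY")
  expect_error(new("PosteriorTrace", alpha = c(1, 0.8),
                   likelihood = c(0.9, 0.8), prior = c(0.5, 0.9),
                   posterior = c(0.8, 0.7), condition = "NU"),
               "prior of trial")
  v <- modelVariant("M4")
  expect_identical(v@k, 3L)
  expect_identical(modelVariant("M1")@k, 2L)
  expect_identical(modelVariant("M2")@k, 1L)
})
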