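test_that("certainty regressors are the logs of the trace probabilities", {
  p <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
  tr <- runBlock(blockDesign("NU"), p)
  expect_equal(likelihoodCertainty(tr), log(likelihoods(tr)))
  expect_equal(priorCertainty(tr), log(priors(tr)))
  expect_true(all(likelihoodCertainty(tr) <= 0))
  expect_true(all(priorCertainty(tr) <= 0))
  expect_equal(priorCertainty(tr)[1], log(0.5), tolerance = 1e-9)
  expect_equal(priorCertainty(tr)[-1], log(posteriors(tr)[-6]))
  # clipped unit probability gives (numerically) zero log
  expect_equal(log(clipProb(1)), 0, tolerance = 1e-8)
})

test_that("Bayesian surprise has both renderings with the stated values", {
  expect_equal(bayesianSurprise(0.9, 0.5), 0.3681, tolerance = 1e-4)
  expect_equal(bayesianSurprise(0.9, 0.5, formula = "as_printed"),
               0.6900, tolerance = 1e-4)
  # direct two-term oracle
  L <- 0.9; q <- 0.5
  expect_equal(bayesianSurprise(L, q),
               L * log(L / q) + (1 - L) * log((1 - L) / (1 - q)))
  for (v in c(0.1, 0.5, 0.9)) {
    expect_equal(bayesianSurprise(v, v), 0)
    expect_equal(bayesianSurprise(v, v, formula = "as_printed"), 0)
  }
  expect_error(bayesianSurprise(0.9, 0.5, formula = "nonsense"))
})

test_that("Bernoulli-KL surprise is non-negative and zero only at equality", {
  g <- seq(0.02, 0.98, by = 0.04)
  grid <- expand.grid(L = g, q = g)
  s <- bayesianSurprise(grid$L, grid$q)
  expect_true(all(s >= 0))
  expect_true(all(s[abs(grid$L - grid$q) > 1e-12] > 0))
  expect_true(all(abs(s[abs(grid$L - grid$q) < 1e-12]) < 1e-12))
})

test_that("serial orthogonalization matches the projection-matrix oracle", {
  set.seed(7)
  m <- cbind(surprise = rnorm(6), lik_cert = rnorm(6),
             prior_cert = rnorm(6))
  out <- serialOrthogonalize(m)
  likr <- oracleResid(m[, "lik_cert"], m[, "surprise", drop = FALSE])
  priorr <- oracleResid(m[, "prior_cert"],
                        cbind(likr, m[, "surprise"]))
  expect_equal(out[, "lik_cert"], likr,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(out[, "prior_cert"], priorr,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(out[, "surprise"], m[, "surprise"])

  # orthogonal, mean-centered columns pass through unchanged
  om <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1),
              cc = c(1, -1, -1, 1))
  expect_equal(serialOrthogonalize(om, scheme = list(a = "b", cc = "b")),
               om)
  # a column residualized against itself vanishes
  m2 <- cbind(a = rnorm(5), b = rnorm(5))
  m2[, "b"] <- m2[, "a"]
  z <- serialOrthogonalize(m2, scheme = list(b = "a"))
  expect_equal(z[, "b"], rep(0, 5), ignore_attr = TRUE,
               tolerance = 1e-10)
  # idempotence
  expect_equal(serialOrthogonalize(out), out, tolerance = 1e-9)
  # rank deficiency is reported
  bad <- cbind(a = rep(1, 5), b = rnorm(5))
  expect_error(serialOrthogonalize(bad, scheme = list(b = "a")),
               "rank-deficient")
})

test_that("regressor sets expose raw and orthogonalized modulators", {
  p <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
  traces <- list(runBlock(blockDesign("NU"), p),
                 runBlock(blockDesign("UN"), p))
  rs <- regressorSet(traces)
  expect_identical(nrow(rs), 12L)
  expect_equal(rs$duration, rep(4, 12))
  expect_true(all(rs$surprise >= 0))
  # orthogonalized prior certainty is orthogonal to the residualized
  # likelihood certainty, the raw surprise, and the constant vector
  v <- rs$prior_cert_orth
  expect_lt(abs(sum(v * rs$lik_cert_orth)) / sqrt(sum(v^2)), 1e-9)
  expect_lt(abs(sum(v * rs$surprise)) / sqrt(sum(v^2)), 1e-9)
  expect_lt(abs(sum(v)) / sqrt(sum(v^2)), 1e-9)

  # posterior-vs-prior operand pair is selectable
  rs2 <- regressorSet(traces, surpriseOperands = "posterior_prior")
  post <- unlist(lapply(traces, posteriors))
  pri <- unlist(lapply(traces, priors))
  expect_equal(rs2$surprise, bayesianSurprise(post, pri))
})

test_that("without persistence the prior regressor chains the likelihood one", {
  p <- modelParams(C = 0.55, lam = 0, sigma = 0.3)
  tr <- runBlock(blockDesign("NU"), p, modelVariant("M2"))
  rs <- regressorSet(tr, orthogonalize = FALSE)
  expect_equal(rs$prior_cert[-1], rs$lik_cert[-6], tolerance = 1e-9)
})

test_that("events tables are written per participant and session", {
  sim <- simulateCohort(cohortSpec(nParticipants = 2, seed = 8))
  cmp <- compareModels(sim$trials, variants = "M1",
                       grid = fitGrid(0.05, 0.05))
  dir <- tempfile("events")
  ev <- writeEventsTsv(sim$trials, cmp, dir = dir)
  files <- list.files(dir, pattern = "_events\\.tsv$")
  expect_identical(length(files), length(ev))
  expect_identical(length(ev), 12L)  # 2 participants x 6 sessions
  one <- read.delim(file.path(dir, files[1]))
  expect_true(all(c("onset", "duration", "trial_type", "lik_cert",
                    "prior_cert", "surprise", "lik_cert_orth",
                    "prior_cert_orth") %in% names(one)))
  expect_identical(nrow(one), 36L)  # 6 gradual blocks x 6 trials
  expect_true(all(diff(one$onset) > 0))
})
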