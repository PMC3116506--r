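# minimal covariate-table-like frame for direct model tests
mk_table <- function(n, seed = 1L, gen = function(x) plogis(-1 + 2 * x)) {
  set.seed(seed)
  x <- runif(n)
  z <- rnorm(n)
  p <- gen(x)
  data.frame(plate = "P1", error = rbinom(n, 1, p),
             error_type = "insertion", x = x, z = z,
             stringsAsFactors = FALSE)
}

test_that("single-covariate fit matches the closed-form log odds ratio", {
  # 2x2 table: x=0 -> 40/160 errors, x=1 -> 90/110
  d <- data.frame(
    plate = "P1",
    error = c(rep(1L, 40), rep(0L, 160), rep(1L, 90), rep(0L, 110)),
    error_type = "insertion",
    xbin = c(rep(0, 200), rep(1, 200)))
  d$error_type[d$error == 0L] <- "none"
  fit <- fit_logistic(d, "P1", "insertion", formula = error ~ xbin)
  lor <- log((90 / 110) / (40 / 160))
  expect_equal(fit$coefficients$estimate[2], lor, tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate[1], log(40 / 160),
               tolerance = 1e-8)
  expect_lte(fit$deviance, fit$null_deviance)
})

test_that("deviance explained is 0 for a null fit and grows with effect size", {
  d0 <- mk_table(4000, seed = 2L, gen = function(x) rep(0.3, length(x)))
  d0$error_type[d0$error == 0L] <- "none"
  f0 <- fit_logistic(d0, "P1", "insertion", formula = error ~ 1)
  expect_equal(deviance_explained(f0), 0)

  de <- vapply(c(0.5, 2, 4), function(b) {
    d <- mk_table(4000, seed = 3L, gen = function(x) plogis(-1 + b * x))
    d$error_type[d$error == 0L] <- "none"
    deviance_explained(fit_logistic(d, "P1", "insertion",
                                    formula = error ~ x))
  }, 0)
  expect_true(all(diff(de) > 0))
})

test_that("null covariates are rejected at the nominal type-I rate", {
  set.seed(4)
  pvals <- replicate(120, {
    d <- mk_table(400, seed = sample.int(1e6, 1),
                  gen = function(x) rep(0.4, length(x)))
    d$error_type[d$error == 0L] <- "none"
    f <- fit_logistic(d, "P1", "insertion", formula = error ~ x)
    f$coefficients$p[2]
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("deviance decomposition: identity, nesting, and degenerate cases", {
  set.seed(5)
  n <- 4000
  d <- data.frame(plate = "P1", error_type = "insertion",
                  A = rnorm(n), B = rnorm(n), konst = 1)
  d$Adup <- d$A
  d$error <- rbinom(n, 1, plogis(0.8 * d$A + 0.8 * d$B))
  d$error_type[d$error == 0L] <- "none"

  dec <- decompose_deviance(d, "P1", "insertion", "A", vars = c("A", "B"))
  expect_equal(dec$part_xi + dec$part_rest + dec$shared, 1, tolerance = 1e-12)
  expect_gte(dec$part_xi, 0)
  expect_gte(dec$part_rest, 0)
  # with the complete-model-deviance denominators, orthogonality shows up
  # as additivity of the deviance reductions, not as shared ~ 0 (the
  # shared term also carries the baseline unexplained deviance)
  null_dev <- fit_logistic(d, "P1", "insertion",
                           formula = error ~ 1)$deviance
  additivity <- ((dec$dev_sub - dec$dev_comp) + (dec$dev_solo - dec$dev_comp) -
                   (null_dev - dec$dev_comp)) / dec$dev_comp
  expect_lt(abs(additivity), 0.02)

  # constant column: no unique contribution
  dk <- decompose_deviance(d, "P1", "insertion", "konst",
                           vars = c("A", "B", "konst"))
  expect_equal(dk$part_xi, 0, tolerance = 1e-8)

  # exact duplicate among the rest: unique part vanishes, shared absorbs it
  dd <- decompose_deviance(d, "P1", "insertion", "A",
                           vars = c("A", "Adup", "B"))
  expect_equal(dd$part_xi, 0, tolerance = 1e-8)
  expect_gt(dd$shared, dec$shared)
})

test_that("rows of other error types are excluded from a per-type fit", {
  d <- mk_table(500, seed = 6L)
  d$error_type[d$error == 0L] <- "none"
  d$error_type[which(d$error == 1L)[1:5]] <- "deletion"
  fit <- fit_logistic(d, "P1", "insertion", formula = error ~ x)
  expect_identical(fit$n, nrow(d) - 5L)
})

test_that("permutation correlation tests behave on edge cases", {
  set.seed(7)
  n <- 120
  tab <- data.frame(
    Position = runif(n),
    Seq.type = factor(sample(paste0("ref", 1:3), n, TRUE)),
    Homopolymer = factor(sample(c(0, 1, 3), n, TRUE), levels = c(0, 1, 3, 4, 5, 6)),
    Dist.region = runif(n), Dist.plate = runif(n),
    Seq.length = sample(300:500, n, TRUE),
    Region = factor(sample(1:5, n, TRUE)))
  tab$Dist.plate <- tab$Dist.region # perfectly correlated pair
  res <- correlation_tests(tab, n_perm = 199, seed = 8L)
  expect_identical(nrow(res), 21L)
  pair <- res[res$var1 == "Dist.region" & res$var2 == "Dist.plate", ]
  expect_equal(pair$r, 1)
  expect_equal(pair$p, 1 / 200)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(abs(res$r) <= 1))

  tab$Seq.length <- 400L
  w <- testthat::capture_warnings(
    res2 <- correlation_tests(tab, n_perm = 199, seed = 8L))
  expect_true(all(grepl("zero variance", w)))
  expect_identical(length(w), 6L) # one per skipped Seq.length pair
  expect_identical(nrow(res2), 15L)
})

test_that("independent variables are rarely flagged after BH", {
  set.seed(9)
  n_sig <- replicate(8, {
    n <- 150
    tab <- data.frame(
      Position = runif(n), Seq.type = factor(sample(1:3, n, TRUE)),
      Homopolymer = factor(sample(c(0, 1, 3), n, TRUE), levels = c(0, 1, 3, 4, 5, 6)),
      Dist.region = runif(n), Dist.plate = runif(n),
      Seq.length = rnorm(n), Region = factor(sample(1:5, n, TRUE)))
    sum(correlation_tests(tab, n_perm = 199, seed = sample.int(1e6, 1))$significant)
  })
  expect_lte(sum(n_sig > 0), 2)
})

test_that("BH adjustment matches the hand step-up rule", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
  set.seed(10)
  for (i in 1:10) {
    q <- runif(sample(3:25, 1))
    expect_equal(p.adjust(q, method = "BH"), oracle_bh(q))
  }
})

test_that("plate homogeneity reproduces the hand-computed chi-square", {
  m <- cbind(errors = c(10, 20, 30), non_errors = c(990, 980, 970))
  got <- plate_homogeneity(m)
  expect_equal(got$chi2, oracle_chisq(m), tolerance = 1e-12)
  expect_identical(got$df, 2L)
  expect_equal(got$p, pchisq(oracle_chisq(m), 2, lower.tail = FALSE))

  even <- cbind(errors = c(50, 50, 50), non_errors = c(950, 950, 950))
  expect_lt(plate_homogeneity(even)$chi2, 1e-10)
  expect_error(plate_homogeneity(cbind(errors = c(0, 0), non_errors = c(1, 1))),
               "zero marginal|invalid")
})
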