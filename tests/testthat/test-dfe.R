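test_that("neutral expected SFS equals theta*L/i and quadrature agrees near 0", {
  for (n in c(4, 10, 20, 50)) {
    e <- expected_sfs_discrete(0, 1e-4, 1e6, n)
    expect_equal(e, 100 / seq_len(n - 1), tolerance = 1e-8)
    # quadrature path (gamma != 0) must approach the closed form too
    eq <- expected_sfs_discrete(-1e-6, 1e-4, 1e6, n)
    expect_equal(eq, 100 / seq_len(n - 1), tolerance = 1e-5)
  }
})

test_that("selected expected SFS matches an adaptive-quadrature oracle", {
  for (g in c(-5, -0.5, 2, -50)) {
    e <- expected_sfs_discrete(g, 1, 1, 4)
    expect_equal(e, oracle_expected_sfs(g, 1, 1, 4), tolerance = 1e-8)
  }
  e10 <- expected_sfs_discrete(-5, 2e-4, 1e5, 10)
  expect_equal(e10, oracle_expected_sfs(-5, 2e-4, 1e5, 10), tolerance = 1e-8)
})

test_that("strong purifying selection skews the spectrum toward singletons", {
  e_weak <- expected_sfs_discrete(-1, 1e-4, 1e6, 10)
  e_strong <- expected_sfs_discrete(-100, 1e-4, 1e6, 10)
  expect_gt(e_strong[1] / sum(e_strong), e_weak[1] / sum(e_weak))
  # extreme gamma still finite and positive (log-space evaluation)
  e_ext <- expected_sfs_discrete(-3000, 1e-4, 1e6, 20)
  expect_true(all(is.finite(e_ext)) && all(e_ext > 0))
})

test_that("gamma-DFE mixture: point-mass limit, monotone shape, K-convergence", {
  # large shape with scale = m/shape converges to the discrete model at -m
  m <- 2
  e_pt <- expected_sfs_gamma(shape = 1e4, scale = m / 1e4, theta = 1e-4,
                             L = 1e6, n = 10)
  e_d <- expected_sfs_discrete(-m, 1e-4, 1e6, 10)
  expect_equal(e_pt, e_d, tolerance = 0.01)

  # published deletion MLEs: finite, positive, monotone decreasing
  eg <- expected_sfs_gamma(0.106, 715, 0.000293, 1e6, 20)
  expect_true(all(is.finite(eg)) && all(eg > 0))
  expect_true(all(diff(eg) < 0))

  # discretization self-convergence: K vs 2K within 0.5% per class
  eK <- expected_sfs_gamma(0.5, 20, 1e-4, 1e6, 20, K = 100L)
  e2K <- expected_sfs_gamma(0.5, 20, 1e-4, 1e6, 20, K = 200L)
  expect_true(all(abs(e2K / eK - 1) < 0.005))
})

test_that("error folding is linear and matches the SFS-level mixing map", {
  e <- orientation_errors(0.07, 0.03)
  ei <- 100 / (1:9); ed <- 140 / (1:9)
  f1 <- fold_in_errors(ei, ed, e)
  # single source of truth with apply_misorientation
  pair <- apply_misorientation(sfs_pair(sfs(ei, 10), sfs(ed, 10)), e)
  expect_equal(f1$ins, pair$ins$counts)
  expect_equal(f1$del, pair$del$counts)
  # identity and linearity
  f0 <- fold_in_errors(ei, ed, orientation_errors(0, 0))
  expect_equal(f0$ins, ei)
  f3 <- fold_in_errors(3 * ei, 3 * ed, e)
  expect_equal(f3$ins, 3 * f1$ins)
  expect_equal(f3$del, 3 * f1$del)
})

test_that("log-likelihood peaks at the generating expectation", {
  tr <- synth_sfs_truth(focal = list(ins = list(gammas = -2, thetas = 1.5e-4),
                                     del = list(gammas = -3, thetas = 2.5e-4)),
                        eps = orientation_errors(0.05, 0.02), seed = 9)
  spec <- dfe_model_spec("discrete", classes = 1)
  pars <- list(theta_neutral = tr$theta_neutral,
               theta_focal = list(ins = 1.5e-4, del = 2.5e-4),
               gammas = list(ins = -2, del = -3), eps = tr$eps, r = NULL)
  e <- indeldfe:::expected_observed(pars, spec, simulate_sfs_dataset(tr))
  # dataset equal to the rounded expectation: perturbing one count lowers lnL
  n <- tr$n
  mk <- function(ni, nd, fi, fd) dfe_data(
    sfs_pair(sfs(ni, n, tr$L_neutral), sfs(nd, n, tr$L_neutral)),
    sfs_pair(sfs(fi, n, tr$L_focal), sfs(fd, n, tr$L_focal)))
  base <- mk(round(e$neutral$ins), round(e$neutral$del),
             round(e$focal$ins), round(e$focal$del))
  ll0 <- log_likelihood(base, pars, spec)
  bumped <- round(e$focal$ins); bumped[3] <- bumped[3] + 25
  ll1 <- log_likelihood(mk(round(e$neutral$ins), round(e$neutral$del),
                           bumped, round(e$focal$del)), pars, spec)
  expect_lt(ll1, ll0)
})

test_that("fitting is deterministic given a seed and satisfies the AIC identity", {
  tr <- synth_sfs_truth(focal = list(ins = list(gammas = -2, thetas = 1.5e-4),
                                     del = list(gammas = -3, thetas = 2.5e-4)),
                        eps = orientation_errors(0.08, 0.03), seed = 7)
  d <- simulate_sfs_dataset(tr)
  spec <- dfe_model_spec("discrete", classes = 1)
  f1 <- fit_model(d, spec, n_starts = 2, seed = 11)
  f2 <- fit_model(d, spec, n_starts = 2, seed = 11)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$aic, 2 * f1$n_params - 2 * f1$loglik)

  # recovery on one seeded replicate at L = 1e6
  np <- natural_params(f1)
  expect_lt(abs(np[["eps_ins"]] - 0.08), 0.02)
  expect_lt(abs(np[["th_n_ins"]] / 1.2e-4 - 1), 0.25)
  expect_lt(abs(np[["gamma_ins_1"]] - (-2)), 1.5)
})

test_that("model comparison: nesting, AIC ranking, single-fit delta", {
  tr <- synth_sfs_truth(focal = list(ins = list(gammas = -2, thetas = 1.39e-4),
                                     del = list(gammas = -3, thetas = 2.14e-4)),
                        theta_neutral = c(ins = 1.39e-4, del = 2.14e-4),
                        eps = orientation_errors(0.03, 0.03), seed = 21)
  d <- simulate_sfs_dataset(tr)
  f_eq <- fit_model(d, dfe_model_spec("discrete", 1, "equal"),
                    n_starts = 2, seed = 1)
  f_var <- fit_model(d, dfe_model_spec("discrete", 1, "variable"),
                     n_starts = 2, seed = 1)
  # the variable-rate model nests the equal-rate model
  expect_gte(f_var$loglik, f_eq$loglik - 1e-3)
  cmp <- compare_models(list(f_eq, f_var))
  expect_equal(cmp$delta_aic[cmp$best], 0)
  expect_equal(nrow(cmp), 2)
  one <- compare_models(list(f_eq))
  expect_equal(one$delta_aic, 0)
  expect_error(compare_models(list()), "no fits")
})

test_that("gamma_mass: published banding, normalization, small-shape series oracle", {
  expect_equal(round(gamma_mass(0.106, 715, 0, 1), 2), 0.52)
  expect_equal(gamma_mass(0.106, 715, 0, Inf), 1)
  expect_equal(gamma_mass(2, 3, 0, Inf), 1)

  # small-shape series oracle: P(X <= x) = x^k/(k Gamma(k) s^k) * sum_j (-x/s)^j / (j! (k+j))
  series_cdf <- function(x, k, s) {
    j <- 0:60
    x^k / (gamma(k) * s^k) * sum((-x / s)^j / (factorial(j) * (j + k)))
  }
  got <- gamma_mass(0.0345, 1553, 0, 1)
  expect_equal(got, series_cdf(1, 0.0345, 1553), tolerance = 1e-6)
  # partition sums to 1
  cuts <- c(0, 1, 10, 100, Inf)
  parts <- vapply(1:4, function(j) gamma_mass(0.0345, 1553, cuts[j], cuts[j + 1]),
                  numeric(1))
  expect_equal(sum(parts), 1)
})

test_that("relative fixation rate: neutral limit, strong-selection limits", {
  expect_equal(relative_fixation_rate(0), 1)
  expect_equal(relative_fixation_rate(-801), 0)
  expect_equal(relative_fixation_rate(-1.14), 0.5360245, tolerance = 1e-6)
  # series check at small |gamma|: f ~ 1 + g/2 + g^2/12
  g <- 1e-3
  expect_equal(relative_fixation_rate(g), 1 + g / 2 + g^2 / 12,
               tolerance = 1e-9)
  expect_equal(relative_fixation_rate(500), 500, tolerance = 1e-10)
})

test_that("alpha from class weights and divergence", {
  # worked arithmetic: 96/4 split between gamma -801 and -1.14
  fit <- structure(list(
    spec = dfe_model_spec("discrete", 2, "equal"),
    mle = list(theta_focal = list(ins = c(0.04, 0.96), del = c(0.04, 0.96)),
               gammas = list(ins = c(-1.14, -801), del = c(-1.14, -801)))),
    class = "dfe_fit")
  a <- alpha_estimate(fit, d_neutral = 0.01, d_selected_obs = 0.001)
  d_pred <- 0.01 * 0.04 * relative_fixation_rate(-1.14)
  expect_equal(a$d_pred[a$type == "ins"], d_pred)
  expect_equal(a$alpha[a$type == "ins"], 1 - d_pred / 0.001)
  expect_equal(round(a$alpha[a$type == "ins"], 2), 0.79)

  # neutral single class with equal divergence: alpha = 0
  fit0 <- structure(list(
    spec = dfe_model_spec("discrete", 1, "equal"),
    mle = list(theta_focal = list(ins = 1e-4, del = 1e-4),
               gammas = list(ins = 0, del = 0))), class = "dfe_fit")
  a0 <- alpha_estimate(fit0, 0.01, 0.01)
  expect_equal(a0$alpha, c(0, 0))
  # d_obs equal to d_pred: alpha = 0 whatever the DFE
  a1 <- alpha_estimate(fit, 0.01, d_pred)
  expect_equal(a1$alpha[a1$type == "ins"], 0)
  expect_error(alpha_estimate(fit, 0.01, 0), "undefined")
  fit_var <- fit; fit_var$spec <- dfe_model_spec("discrete", 2, "variable")
  expect_error(alpha_estimate(fit_var, 0.01, 0.001), "equal")
})

test_that("demography multipliers scale expected classes and are recovered in the likelihood", {
  r <- c(1, rep(1.5, 8))
  e <- expected_sfs_discrete(0, 1e-4, 1e6, 10, r = r)
  expect_equal(e, 100 / (1:9) * r)
  # a distorted dataset is better explained with the generating r than without
  tr <- synth_sfs_truth(n = 10,
                        focal = list(ins = list(gammas = -1, thetas = 1.5e-4),
                                     del = list(gammas = -1, thetas = 2.5e-4)),
                        eps = orientation_errors(0, 0),
                        r = c(1, seq(1.6, 0.4, length.out = 7), 0.3), seed = 31)
  d <- simulate_sfs_dataset(tr)
  spec <- dfe_model_spec("discrete", classes = 1)
  pars <- list(theta_neutral = tr$theta_neutral,
               theta_focal = list(ins = 1.5e-4, del = 2.5e-4),
               gammas = list(ins = -1, del = -1), eps = tr$eps)
  ll_r <- log_likelihood(d, c(pars, list(r = tr$r)), spec)
  ll_flat <- log_likelihood(d, c(pars, list(r = NULL)), spec)
  expect_gt(ll_r, ll_flat)
})
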