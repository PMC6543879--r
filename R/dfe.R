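#' @importFrom stats optim pgamma qgamma plogis qlogis runif setNames
NULL

# Cache of Gauss-Legendre bases keyed by (n, nodes). M[i, k] gives, for
# frequency class i, the quadrature weight C(n,i) w_k x_k^{i-1} (1-x_k)^{n-i-1}
# so that E[phi_i] / (theta L r_i) = (M %*% ratio)(i) where ratio is the
# selection-dependent part of the sojourn density evaluated at the nodes.
.dfe_cache <- new.env(parent = emptyenv())

gl_basis <- function(n, nodes = 128L) {
  key <- paste0("n", n, "_q", nodes)
  if (!is.null(.dfe_cache[[key]])) return(.dfe_cache[[key]])
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  x <- gl$x
  w <- gl$w
  i <- seq_len(n - 1L)
  # log-space assembly: x^(i-1) underflows for large i at small x otherwise
  logM <- outer(i, seq_along(x), function(ii, kk) {
    lchoose(n, ii) + log(w[kk]) + (ii - 1) * log(x[kk]) +
      (n - ii - 1) * log1p(-x[kk])
  })
  b <- list(x = x, w = w, M = exp(logM))
  .dfe_cache[[key]] <- b
  b
}

# Selection part of the unscaled sojourn density, relative to the neutral
# 1/(x(1-x)) factor already absorbed into the basis:
#   ratio(x; g) = (1 - exp(-g (1-x))) / (1 - exp(-g)),  ratio(x; 0) = 1 - x.
# For g < 0 evaluated exactly in log space (stable for arbitrarily strong
# purifying selection); for g > 0 via expm1.
sojourn_ratio <- function(x, gamma) {
  if (abs(gamma) < 1e-8) return(1 - x)
  if (gamma < 0) {
    u <- -gamma
    exp(-u * x + log1p(-exp(-u * (1 - x))) - log1p(-exp(-u)))
  } else {
    expm1(-gamma * (1 - x)) / expm1(-gamma)
  }
}

# matrix of ratios: nodes x length(gammas), block-vectorized by sign
sojourn_ratio_mat <- function(x, gammas) {
  R <- matrix(0, length(x), length(gammas))
  zero <- abs(gammas) < 1e-8
  neg <- gammas < 0 & !zero
  pos <- gammas > 0 & !zero
  if (any(zero)) R[, zero] <- 1 - x
  if (any(neg)) {
    u <- -gammas[neg]
    A <- -outer(x, u) + log1p(-exp(-outer(1 - x, u)))
    R[, neg] <- exp(sweep(A, 2, log1p(-exp(-u)), "-"))
  }
  if (any(pos)) {
    g <- gammas[pos]
    B <- expm1(-outer(1 - x, g))
    R[, pos] <- sweep(B, 2, expm1(-g), "/")
  }
  R
}

#' Expected unfolded SFS under a single selection coefficient
#'
#' Poisson-random-field expectation for the number of segregating sites at
#' derived count \eqn{i} in a sample of \eqn{n} chromosomes, for sites with
#' scaled selection coefficient \eqn{\gamma = 4N_e s}, per-site scaled
#' mutation rate \eqn{\theta = 4N_e\mu} and \eqn{L} callable sites:
#' \deqn{E[\phi_i] = r_i\, \theta L \binom{n}{i} \int_0^1
#'   \frac{1 - e^{-\gamma(1-x)}}{(1 - e^{-\gamma})\,x(1-x)}
#'   x^i (1-x)^{n-i} \, dx.}
#' At \eqn{\gamma = 0} (and \eqn{r \equiv 1}) this reduces to
#' \eqn{\theta L / i}. The integral is evaluated by fixed Gauss-Legendre
#' quadrature after recasting the integrand with \eqn{x^{i-1}}, which
#' removes the \eqn{1/x} singularity; the selection factor is evaluated in
#' log space so arbitrarily strong purifying selection is handled without
#' overflow.
#'
#' @param gamma scaled selection coefficient (negative = deleterious).
#' @param theta per-site scaled mutation rate, `> 0`.
#' @param L callable sites, `>= 1`.
#' @param n haploid sample size.
#' @param r optional demography multipliers `r_i` (length `n - 1`,
#'   `r[1] = 1`); default all 1.
#' @param nodes number of quadrature nodes.
#' @return Numeric vector of expected counts for `i = 1..n-1`.
#' @export
expected_sfs_discrete <- function(gamma, theta, L, n, r = NULL, nodes = 128L) {
  stopifnot(theta > 0, L >= 1, n >= 2)
  if (gamma == 0) { # exact neutral reduction, skips the quadrature
    e <- 1 / seq_len(n - 1L)
    if (!is.null(r)) e <- e * r
    return(theta * L * e)
  }
  b <- gl_basis(n, nodes)
  e <- as.numeric(b$M %*% sojourn_ratio(b$x, gamma))
  if (!is.null(r)) e <- e * r
  theta * L * e
}

# equal-probability-mass discretization of Gamma(shape, scale): K bin
# representatives, each the mass-weighted mean |gamma| within its bin
gamma_bin_means <- function(shape, scale, K) {
  edges <- qgamma(seq(0, 1, length.out = K + 1), shape = shape, scale = scale)
  edges[K + 1] <- Inf
  # E[X; a<X<b] for Gamma(k, s) is k s (F_{k+1}(b) - F_{k+1}(a))
  upper <- pgamma(edges[-1], shape = shape + 1, scale = scale)
  lower <- pgamma(edges[-(K + 1)], shape = shape + 1, scale = scale)
  shape * scale * (upper - lower) * K
}

#' Expected unfolded SFS under a gamma DFE
#'
#' Mixture of [expected_sfs_discrete()] over a gamma distribution of
#' deleterious selection-coefficient magnitudes (\eqn{\gamma = -|\gamma|},
#' \eqn{|\gamma| \sim} Gamma(`shape`, `scale`)). The continuous DFE is
#' discretized into `K` equal-probability-mass bins, each represented by
#' its mass-weighted mean magnitude.
#'
#' @param shape,scale gamma DFE parameters, both `> 0`; the mean
#'   \eqn{|\gamma|} is `shape * scale`.
#' @param theta,L,n,r,nodes as in [expected_sfs_discrete()].
#' @param K number of discretization bins.
#' @return Numeric vector of expected counts for `i = 1..n-1`.
#' @export
expected_sfs_gamma <- function(shape, scale, theta, L, n, r = NULL,
                               K = 100L, nodes = 128L) {
  stopifnot(shape > 0, scale > 0, theta > 0, L >= 1)
  b <- gl_basis(n, nodes)
  g <- gamma_bin_means(shape, scale, K)
  # mixture mean commutes with the quadrature: average the node-wise
  # selection factors over bins first, then apply the basis once
  e <- as.numeric(b$M %*% rowMeans(sojourn_ratio_mat(b$x, -g)))
  if (any(!is.finite(e))) stop("non-finite gamma-DFE mixture expectation")
  if (!is.null(r)) e <- e * r
  theta * L * e
}

#' Fold polarization error into expected spectra
#'
#' Applies the forward misorientation mixing (the same linear map as
#' [apply_misorientation()]) to a pair of expected insertion/deletion
#' spectra, giving the expectations on the observed scale.
#'
#' @param e_ins,e_del expected count vectors (length `n - 1`).
#' @param errors [orientation_errors()].
#' @return List with elements `ins` and `del`.
#' @export
fold_in_errors <- function(e_ins, e_del, errors) {
  stopifnot(length(e_ins) == length(e_del),
            inherits(errors, "orientation_errors"))
  mix_spectra(e_ins, e_del, errors)
}

#' Model family specification for DFE fitting
#'
#' @param family `"discrete"` (a fixed number of selection classes, each
#'   with its own \eqn{\gamma} and mutation-rate share) or `"gamma"`
#'   (deleterious gamma-distributed \eqn{|\gamma|}).
#' @param classes number of site classes (discrete family only).
#' @param mutation_mode `"variable"` lets the focal per-type mutation rate
#'   differ from the neutral reference; `"equal"` constrains the summed
#'   focal \eqn{\theta} per type to equal the neutral \eqn{\theta} of that
#'   type (required for estimating the adaptive proportion \eqn{\alpha}).
#' @param demography if `TRUE`, per-frequency multipliers \eqn{r_i}
#'   (`r_1 = 1`), shared across regions and variant types, are estimated
#'   jointly to absorb demographic distortion of the SFS.
#' @param K gamma-DFE discretization bins.
#' @param nodes quadrature nodes.
#' @param gamma_bounds box bounds for discrete-class selection
#'   coefficients. The default permits a positively selected class; use
#'   `c(-5000, 0)` for a deleterious-only model (a positive class and
#'   polarization error both generate high-frequency variants and are
#'   weakly separable, so deleterious-support fits are often the sounder
#'   choice).
#' @return An object of class `"dfe_model_spec"`.
#' @export
dfe_model_spec <- function(family = c("discrete", "gamma"), classes = 1L,
                           mutation_mode = c("variable", "equal"),
                           demography = FALSE, K = 100L, nodes = 128L,
                           gamma_bounds = c(-5000, 100)) {
  family <- match.arg(family)
  mutation_mode <- match.arg(mutation_mode)
  classes <- as.integer(classes)
  stopifnot(classes >= 1L, length(gamma_bounds) == 2L,
            gamma_bounds[1] < gamma_bounds[2])
  structure(list(family = family, classes = classes,
                 mutation_mode = mutation_mode, demography = demography,
                 K = as.integer(K), nodes = as.integer(nodes),
                 gamma_bounds = gamma_bounds),
            class = "dfe_model_spec")
}

#' Neutral-reference plus focal-region dataset
#'
#' @param neutral,focal observed [sfs_pair()]s for the neutral reference
#'   (e.g. ancestral repeats) and the focal region; must share `n`.
#' @return An object of class `"dfe_data"`.
#' @export
dfe_data <- function(neutral, focal) {
  stopifnot(inherits(neutral, "sfs_pair"), inherits(focal, "sfs_pair"))
  if (neutral$ins$n != focal$ins$n)
    stop("neutral and focal spectra must share the sample size n")
  structure(list(neutral = neutral, focal = focal, n = neutral$ins$n),
            class = "dfe_data")
}

## ---- parameter packing ----------------------------------------------------
## transformed scale: log(theta), gamma raw, eps = 0.5 * plogis(z),
## log(shape), log(scale), log(r_i) for i >= 2. Weights for the equal
## mutation-rate discrete model use stick-breaking logits.

par_skeleton <- function(spec, n) {
  nm <- c("lth_n_ins", "lth_n_del")
  if (spec$family == "discrete") {
    c_ <- spec$classes
    if (spec$mutation_mode == "variable") {
      nm <- c(nm, paste0("lth_f_ins_", 1:c_), paste0("lth_f_del_", 1:c_))
    } else if (c_ > 1L) {
      nm <- c(nm, paste0("wlogit_ins_", 1:(c_ - 1L)),
              paste0("wlogit_del_", 1:(c_ - 1L)))
    }
    nm <- c(nm, paste0("gamma_ins_", 1:c_), paste0("gamma_del_", 1:c_))
  } else {
    if (spec$mutation_mode == "variable")
      nm <- c(nm, "lth_f_ins", "lth_f_del")
    nm <- c(nm, "lshape_ins", "lshape_del", "lscale_ins", "lscale_del")
  }
  nm <- c(nm, "zeps_ins", "zeps_del")
  if (spec$demography) nm <- c(nm, paste0("lr_", 2:(n - 1L)))
  nm
}

par_bounds <- function(nm, spec) {
  lower <- vapply(nm, function(s) {
    if (startsWith(s, "lth_")) log(1e-10)
    else if (startsWith(s, "gamma_")) spec$gamma_bounds[1]
    else if (startsWith(s, "lshape_")) log(1e-3)
    else if (startsWith(s, "lscale_")) log(1e-3)
    else if (startsWith(s, "zeps_")) -18
    else if (startsWith(s, "lr_")) log(0.01)
    else -25
  }, numeric(1))
  upper <- vapply(nm, function(s) {
    if (startsWith(s, "lth_")) log(1)
    else if (startsWith(s, "gamma_")) spec$gamma_bounds[2]
    else if (startsWith(s, "lshape_")) log(100)
    else if (startsWith(s, "lscale_")) log(1e6)
    else if (startsWith(s, "zeps_")) 18
    else if (startsWith(s, "lr_")) log(100)
    else 25
  }, numeric(1))
  list(lower = lower, upper = upper)
}

stick_weights <- function(logits) {
  # c-1 logits -> c positive weights summing to 1
  w <- numeric(length(logits) + 1L)
  remaining <- 1
  for (j in seq_along(logits)) {
    p <- plogis(logits[j])
    w[j] <- remaining * p
    remaining <- remaining * (1 - p)
  }
  w[length(w)] <- remaining
  w
}

unpack_params <- function(par, spec, n) {
  g <- function(key) unname(par[startsWith(names(par), key)])
  out <- list(theta_neutral = c(ins = exp(par[["lth_n_ins"]]),
                                del = exp(par[["lth_n_del"]])),
              eps = orientation_errors(0.5 * plogis(par[["zeps_ins"]]),
                                       0.5 * plogis(par[["zeps_del"]])))
  if (spec$family == "discrete") {
    out$gammas <- list(ins = g("gamma_ins_"), del = g("gamma_del_"))
    if (spec$mutation_mode == "variable") {
      out$theta_focal <- list(ins = exp(g("lth_f_ins_")),
                              del = exp(g("lth_f_del_")))
    } else {
      w_ins <- if (spec$classes > 1L) stick_weights(g("wlogit_ins_")) else 1
      w_del <- if (spec$classes > 1L) stick_weights(g("wlogit_del_")) else 1
      out$theta_focal <- list(ins = out$theta_neutral[["ins"]] * w_ins,
                              del = out$theta_neutral[["del"]] * w_del)
    }
  } else {
    out$shape <- c(ins = exp(par[["lshape_ins"]]),
                   del = exp(par[["lshape_del"]]))
    out$scale <- c(ins = exp(par[["lscale_ins"]]),
                   del = exp(par[["lscale_del"]]))
    out$theta_focal <- if (spec$mutation_mode == "variable") {
      c(ins = exp(par[["lth_f_ins"]]), del = exp(par[["lth_f_del"]]))
    } else out$theta_neutral
  }
  if (spec$demography) out$r <- c(1, exp(g("lr_"))) else out$r <- NULL
  out
}

expected_observed <- function(p, spec, data) {
  n <- data$n
  nodes <- spec$nodes
  en_ins <- expected_sfs_discrete(0, p$theta_neutral[["ins"]],
                                  data$neutral$ins$callable_sites, n,
                                  p$r, nodes)
  en_del <- expected_sfs_discrete(0, p$theta_neutral[["del"]],
                                  data$neutral$del$callable_sites, n,
                                  p$r, nodes)
  focal_one <- function(type) {
    L <- data$focal[[type]]$callable_sites
    if (spec$family == "discrete") {
      th <- p$theta_focal[[type]]
      gs <- p$gammas[[type]]
      e <- numeric(n - 1L)
      for (j in seq_along(gs))
        e <- e + expected_sfs_discrete(gs[j], th[j], L, n, p$r, nodes)
      e
    } else {
      expected_sfs_gamma(p$shape[[type]], p$scale[[type]],
                         p$theta_focal[[type]], L, n, p$r, spec$K, nodes)
    }
  }
  ef_ins <- focal_one("ins")
  ef_del <- focal_one("del")
  list(neutral = fold_in_errors(en_ins, en_del, p$eps),
       focal = fold_in_errors(ef_ins, ef_del, p$eps))
}

poisson_ll <- function(obs, expd) {
  expd <- pmax(expd, 1e-12) # floor keeps the likelihood finite
  sum(obs * log(expd) - expd - lgamma(obs + 1))
}

#' Poisson-random-field log-likelihood
#'
#' Sum over region (neutral, focal) x variant type x frequency class of the
#' Poisson log-probability of the observed count given the model's expected
#' count on the observed (error-folded) scale. Expected counts are floored
#' at `1e-12` before logs so the likelihood stays finite.
#'
#' @param data a [dfe_data()].
#' @param params natural-scale parameter list as stored in a fit's `mle`
#'   (fields `theta_neutral`, `theta_focal`, `gammas` or `shape`/`scale`,
#'   `eps`, optional `r`).
#' @param spec the [dfe_model_spec()].
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(data, params, spec) {
  e <- expected_observed(params, spec, data)
  poisson_ll(data$neutral$ins$counts, e$neutral$ins) +
    poisson_ll(data$neutral$del$counts, e$neutral$del) +
    poisson_ll(data$focal$ins$counts, e$focal$ins) +
    poisson_ll(data$focal$del$counts, e$focal$del)
}

negloglik_vec <- function(parvec, nm, spec, data) {
  names(parvec) <- nm
  p <- tryCatch(unpack_params(parvec, spec, data$n), error = function(e) NULL)
  if (is.null(p)) return(1e10)
  ll <- tryCatch(log_likelihood(data, p, spec), error = function(e) NA_real_)
  if (!is.finite(ll)) return(1e10)
  -ll
}

make_starts <- function(spec, data, n_starts, seed) {
  n <- data$n
  a1 <- sum(1 / seq_len(n - 1L))
  nm <- par_skeleton(spec, n)
  wt <- function(x) max(sum(x$counts) / (a1 * x$callable_sites), 1e-9)
  th_n_ins <- wt(data$neutral$ins); th_n_del <- wt(data$neutral$del)
  th_f_ins <- wt(data$focal$ins);   th_f_del <- wt(data$focal$del)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(seq_len(n_starts), function(s) {
    jit <- function(x, f = 0.3) x * exp(runif(length(x), -f, f) * (s > 1))
    v <- vapply(nm, function(name) {
      if (name == "lth_n_ins") log(jit(th_n_ins))
      else if (name == "lth_n_del") log(jit(th_n_del))
      else if (startsWith(name, "lth_f_ins")) {
        log(jit(th_f_ins / spec$classes))
      } else if (startsWith(name, "lth_f_del")) {
        log(jit(th_f_del / spec$classes))
      } else if (name %in% c("lth_f_ins", "lth_f_del")) {
        log(jit(if (name == "lth_f_ins") th_f_ins else th_f_del))
      } else if (startsWith(name, "wlogit_")) {
        # weak classes start as a small share of sites
        if (s == 1) qlogis(0.1) else runif(1, -4, 1)
      } else if (startsWith(name, "gamma_")) {
        j <- as.integer(sub(".*_", "", name))
        base <- -10^(2 * (j - 1)) # classes spread over selection decades
        if (s == 1) base else -10^runif(1, -1, 3.2)
      } else if (startsWith(name, "lshape_")) {
        if (s == 1) log(0.3) else log(10^runif(1, -1.5, 0.7))
      } else if (startsWith(name, "lscale_")) {
        if (s == 1) log(100) else log(10^runif(1, 0, 4))
      } else if (startsWith(name, "zeps_")) {
        qlogis(min(0.01 * jit(1), 0.49) / 0.5)
      } else if (startsWith(name, "lr_")) {
        if (s == 1) 0 else runif(1, -0.2, 0.2)
      } else 0
    }, numeric(1))
    # order each type's class coefficients weakest-first: stabilizes class
    # labels and keeps jittered starts exploring ordered DFEs
    for (ty in c("ins", "del")) {
      gi <- which(startsWith(nm, paste0("gamma_", ty)))
      if (length(gi) > 1L) v[gi] <- -sort(abs(v[gi]))
    }
    v
  })
}

#' Fit a DFE model by multi-start bounded maximum likelihood
#'
#' Maximizes the Poisson-random-field likelihood over the model's natural
#' parameters using bounded quasi-Newton (`L-BFGS-B`) local optimization
#' from `n_starts` seeded starting points (first start: moment-based
#' initial values, mutation rates at Watterson estimates, polarization
#' error at 0.01; later starts jittered). The best converged start is
#' returned; refitting with the same seed reproduces the fit exactly.
#'
#' @param data a [dfe_data()].
#' @param spec a [dfe_model_spec()].
#' @param n_starts number of optimizer starts.
#' @param seed integer seed for start generation.
#' @param control passed to [stats::optim()] (`maxit`, `factr` defaults
#'   raised for likelihood surfaces that are flat in strong-selection
#'   directions).
#' @return An object of class `"dfe_fit"`: `mle` (natural-scale parameter
#'   list), `par` (transformed vector), `loglik`, `n_params`, `aic`
#'   (`2 k - 2 lnL`), `converged`, `n_starts`, `seed`, `spec`, and a
#'   per-start table `starts`.
#' @export
fit_model <- function(data, spec, n_starts = 10L, seed = 1L,
                      control = list()) {
  stopifnot(inherits(data, "dfe_data"), inherits(spec, "dfe_model_spec"))
  nm <- par_skeleton(spec, data$n)
  bb <- par_bounds(nm, spec)
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e8), control)
  starts <- make_starts(spec, data, n_starts, seed)
  runs <- lapply(starts, function(p0) {
    p0 <- pmin(pmax(p0, bb$lower), bb$upper)
    tryCatch(
      optim(p0, negloglik_vec, nm = nm, spec = spec, data = data,
            method = "L-BFGS-B", lower = bb$lower, upper = bb$upper,
            control = ctrl),
      error = function(e) list(value = Inf, convergence = 99L, par = p0))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) r$convergence == 0L, logical(1))
  if (all(!is.finite(vals)))
    stop("no optimizer start produced a finite likelihood; diagnostics: ",
         paste(vals, collapse = ", "))
  best <- which.min(vals)
  par <- runs[[best]]$par
  names(par) <- nm
  loglik <- -vals[best]
  k <- length(par)
  structure(list(
    mle = unpack_params(par, spec, data$n),
    par = par, loglik = loglik, n_params = k,
    aic = 2 * k - 2 * loglik,
    converged = conv[best], n_starts = as.integer(n_starts),
    seed = as.integer(seed), spec = spec,
    starts = data.frame(start = seq_along(vals), nll = vals,
                        converged = conv)),
    class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit (%s, %s mutation rate%s): lnL = %.3f, AIC = %.3f, k = %d%s\n",
              x$spec$family, x$spec$mutation_mode,
              if (x$spec$demography) ", demography" else "",
              x$loglik, x$aic, x$n_params,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Standard errors for a DFE fit
#'
#' Observed-information standard errors: numerical Hessian of the negative
#' log-likelihood at the MLE on the transformed (unconstrained-ish) scale,
#' inverted and delta-method mapped to the natural scale (`theta`, `eps`,
#' `shape`, `scale` are log/logistic transformed; `gamma` is untransformed).
#'
#' @param fit a `"dfe_fit"`.
#' @param data the [dfe_data()] it was fitted to.
#' @return Named vector of natural-scale standard errors. Entries are NA
#'   where the information matrix is not invertible in that direction or
#'   where the MLE sits on a box bound (no interior curvature exists
#'   there, so a Wald error is undefined).
#' @export
fit_se <- function(fit, data) {
  nm <- names(fit$par)
  V <- fit_vcov(fit, data)
  se_t <- suppressWarnings(sqrt(diag(V)))
  # delta method: d(natural)/d(transformed), diagonal
  nat <- natural_params(fit)
  deriv <- vapply(seq_along(nm), function(j) {
    s <- nm[j]
    if (startsWith(s, "lth_") || startsWith(s, "lshape_") ||
        startsWith(s, "lscale_") || startsWith(s, "lr_")) exp(fit$par[[j]])
    else if (startsWith(s, "zeps_")) {
      p <- plogis(fit$par[[j]]); 0.5 * p * (1 - p)
    } else 1
  }, numeric(1))
  setNames(se_t * abs(deriv), names(nat))
}

# Observed-information covariance on the transformed scale. Parameters
# pinned at a box bound have no interior curvature; they are treated as
# fixed (their rows/columns are NA) so the free block stays invertible.
fit_vcov <- function(fit, data) {
  nm <- names(fit$par)
  v <- as.numeric(fit$par)
  bb <- par_bounds(nm, fit$spec)
  free <- v > bb$lower + 1e-6 & v < bb$upper - 1e-6
  V <- matrix(NA_real_, length(v), length(v),
              dimnames = list(nm, nm))
  if (any(free)) {
    Hf <- pracma::hessian(function(p) {
      w <- v; w[free] <- p
      negloglik_vec(w, nm, fit$spec, data)
    }, v[free])
    Hf <- (Hf + t(Hf)) / 2
    # near-flat (or numerically saddle) directions make the raw inverse
    # indefinite; floor the eigenvalue magnitudes so flat directions map
    # to large, not nonsensical, variances
    ev <- eigen(Hf, symmetric = TRUE)
    lam <- pmax(abs(ev$values), max(abs(ev$values)) * 1e-9)
    V[free, free] <- ev$vectors %*% (t(ev$vectors) / lam)
  }
  V
}

#' Delta-method standard error of a smooth functional of the MLE
#'
#' Wald standard error for `fun(par)` where `par` is the fit's transformed
#' parameter vector: gradient of the functional times the inverse observed
#' information. Useful for identifiable combinations (e.g. the
#' effectively-neutral mutation-rate mass `theta * P(|gamma| <= 1)`) when
#' individual parameters sit on a likelihood ridge.
#'
#' @param fit a `"dfe_fit"`.
#' @param data the [dfe_data()] it was fitted to.
#' @param fun function taking a named transformed parameter vector and
#'   returning a scalar, or a named list of such functions (one shared
#'   information matrix).
#' @return For a single function, a list with `value` and `se`; for a list
#'   of functions, a data.frame with columns `fun`, `value`, `se`.
#' @export
fit_se_fun <- function(fit, data, fun) {
  nm <- names(fit$par)
  v <- as.numeric(fit$par)
  V <- fit_vcov(fit, data)
  free <- !is.na(diag(V))
  one <- function(f) {
    g <- pracma::grad(function(p) { names(p) <- nm; f(p) }, v)
    pv <- v; names(pv) <- nm
    # gradient mass on a bound-pinned parameter: SE undefined
    if (any(abs(g[!free]) > 1e-8))
      return(list(value = f(pv), se = NA_real_))
    gv <- as.numeric(t(g[free]) %*% V[free, free, drop = FALSE] %*% g[free])
    list(value = f(pv), se = sqrt(max(gv, 0)))
  }
  if (is.function(fun)) return(one(fun))
  res <- lapply(fun, one)
  data.frame(fun = names(res),
             value = vapply(res, `[[`, numeric(1), "value"),
             se = vapply(res, `[[`, numeric(1), "se"),
             row.names = NULL)
}

#' Natural-scale parameter vector of a fit
#'
#' Flattens a fit's transformed parameter vector to the natural scale
#' (theta, gamma, shape, scale, eps, r), keeping the transformed names with
#' their prefixes stripped.
#'
#' @param fit a `"dfe_fit"`.
#' @return Named numeric vector.
#' @export
natural_params <- function(fit) {
  nm <- names(fit$par)
  val <- vapply(seq_along(nm), function(j) {
    s <- nm[j]
    v <- fit$par[[j]]
    if (startsWith(s, "lth_") || startsWith(s, "lshape_") ||
        startsWith(s, "lscale_") || startsWith(s, "lr_")) exp(v)
    else if (startsWith(s, "zeps_")) 0.5 * plogis(v)
    else v
  }, numeric(1))
  out_nm <- sub("^l(th|shape|scale|r)", "\\1", nm)
  out_nm <- sub("^zeps", "eps", out_nm)
  setNames(val, out_nm)
}

#' Compare fitted models by AIC
#'
#' @param fits list of `"dfe_fit"` objects on the same data.
#' @return data.frame sorted by AIC with `delta_aic` relative to the best
#'   (minimum-AIC) fit, which carries `best = TRUE`.
#' @export
compare_models <- function(fits) {
  if (length(fits) == 0L) stop("no fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "dfe_fit")))
  tab <- data.frame(
    model = vapply(fits, function(f)
      paste0(f$spec$family,
             if (f$spec$family == "discrete") paste0("_c", f$spec$classes) else "",
             "_", f$spec$mutation_mode), character(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$best <- tab$delta_aic == 0
  tab[order(tab$aic), ]
}

#' Probability mass of a gamma DFE between two magnitudes
#'
#' `P(lo < |gamma| <= hi)` when `|gamma| ~ Gamma(shape, scale)`. Used to
#' band a continuous DFE into effectively-neutral (`|gamma| <= 1`) and
#' selected (`|gamma| > 1`) fractions.
#'
#' @param shape,scale gamma parameters.
#' @param lo,hi band limits, `0 <= lo < hi` (`hi` may be `Inf`).
#' @return Probability.
#' @export
gamma_mass <- function(shape, scale, lo, hi) {
  stopifnot(lo >= 0, hi > lo)
  pgamma(hi, shape = shape, scale = scale) -
    pgamma(lo, shape = shape, scale = scale)
}

#' Relative fixation rate under selection
#'
#' Ratio of the fixation probability of a semidominant mutation with scaled
#' coefficient \eqn{\gamma} to the neutral fixation probability:
#' \deqn{f(\gamma) = \frac{\gamma}{1 - e^{-\gamma}},} with \eqn{f(0) = 1}
#' by continuity. Strong purifying selection gives \eqn{f \to 0}; strong
#' positive selection gives \eqn{f \approx \gamma}.
#'
#' @param gamma scaled selection coefficient (vectorized).
#' @return Relative fixation rate(s).
#' @export
relative_fixation_rate <- function(gamma) {
  out <- ifelse(abs(gamma) < 1e-8,
                1 + gamma / 2,
                gamma / (-expm1(-gamma)))
  # gamma << 0: -expm1(-gamma) overflows to -Inf, ratio correctly -> 0
  out[gamma < -745 & !is.finite(-expm1(-gamma))] <- 0
  unname(out)
}

#' Proportion of substitutions fixed by positive selection
#'
#' From an equal-mutation-rate discrete-class fit, predicts the per-site
#' divergence attributable to neutral and deleterious fixations,
#' \deqn{d_{pred} = d_{neutral} \sum_j w_j f(\gamma_j), \qquad
#'       w_j = \theta_j / \textstyle\sum_j \theta_j,}
#' and estimates \eqn{\alpha = 1 - d_{pred} / d_{obs}} per variant type.
#' The equal mutation-rate constraint is required: the neutral divergence
#' only calibrates the focal fixation rate when both share \eqn{\theta}.
#'
#' @param fit a `"dfe_fit"` of a discrete-family, `mutation_mode = "equal"`
#'   model.
#' @param d_neutral neutral divergence per site (scalar or per-type named
#'   vector `c(ins=, del=)`).
#' @param d_selected_obs observed focal divergence per site, per type.
#' @return data.frame with one row per type: `alpha`, `d_obs`, `d_pred`.
#' @export
alpha_estimate <- function(fit, d_neutral, d_selected_obs) {
  stopifnot(inherits(fit, "dfe_fit"))
  if (fit$spec$mutation_mode != "equal")
    stop("alpha requires an equal mutation-rate fit")
  if (fit$spec$family != "discrete")
    stop("alpha is computed from discrete-class fits")
  types <- c("ins", "del")
  dn <- if (length(d_neutral) == 1L) setNames(rep(d_neutral, 2), types) else d_neutral
  dobs <- if (length(d_selected_obs) == 1L)
    setNames(rep(d_selected_obs, 2), types) else d_selected_obs
  rows <- lapply(types, function(ty) {
    th <- fit$mle$theta_focal[[ty]]
    w <- th / sum(th)
    if (dobs[[ty]] == 0) stop("observed focal divergence is zero: alpha undefined")
    d_pred <- dn[[ty]] * sum(w * relative_fixation_rate(fit$mle$gammas[[ty]]))
    data.frame(type = ty, alpha = 1 - d_pred / dobs[[ty]],
               d_obs = dobs[[ty]], d_pred = d_pred)
  })
  do.call(rbind, rows)
}
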