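#' Retained draw count of a Gibbs run
#'
#' \eqn{\lfloor (n_{iter} - n_{burnin}) / thin \rfloor}; e.g. 400000
#' iterations, 200000 burn-in, thin 40 retains exactly 5000 draws.
#'
#' @param nIter,nBurnin,thin Sampler settings.
#' @return Integer count of retained draws per chain.
#' @export
retainedDraws <- function(nIter, nBurnin, thin) {
  if (nBurnin >= nIter) stop("nBurnin must be below nIter")
  as.integer(floor((nIter - nBurnin) / thin))
}

#' Split Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain into
#' halves: with \eqn{m} split sequences of length \eqn{n}, within-variance
#' \eqn{W} (mean of the per-sequence variances) and between-variance
#' \eqn{B = n \cdot \mathrm{Var}(\bar\theta_j)},
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}.}
#' Chains with zero total variance return 1 by convention (the ratio is
#' undefined for constant chains).
#'
#' @param chains List of (or matrix with columns as) at least two numeric
#'   chains of equal length \eqn{\ge 10}.
#' @return \eqn{\hat R}, a scalar \eqn{\ge 1} up to numerical tolerance.
#' @export
gelmanRubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2)
    stop("gelmanRubin needs at least 2 chains")
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1) stop("chains must have equal length")
  if (len < 10) stop("chains must have length >= 10")
  half <- floor(len / 2)
  splits <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(half)], ch[half + seq_len(half)])), recursive = FALSE)
  mns <- vapply(splits, mean, numeric(1))
  vars <- vapply(splits, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# scaled inverse chi-square prior with df nu whose mode equals `mode`
.sichiScale <- function(mode, nu) mode * (nu + 2) / nu

# eigendecomposition of the (jittered) relationship matrix, shared by all
# chains and by the ML arm; block-diagonal inputs (family blocks) are
# decomposed block by block
.eigenA <- function(A, jitter = 1e-8) {
  blocks <- if (inherits(A, "famaggRelBlocks")) {
    n <- length(attr(A, "ids"))
    off <- 0L
    out <- lapply(A, function(B) {
      m <- nrow(B)
      b <- list(A = B, idx = off + seq_len(m))
      off <<- off + m
      b
    })
    out
  } else {
    if (is(A, "KinshipMatrix")) A <- relationshipMatrix(A, jitter = jitter)
    list(list(A = as.matrix(A), idx = seq_len(nrow(A))))
  }
  d <- numeric(sum(vapply(blocks, function(b) length(b$idx), integer(1))))
  eb <- lapply(blocks, function(b) {
    ev <- eigen(b$A, symmetric = TRUE)
    dv <- ev$values
    if (min(dv) < -1e-6 * max(dv, 1))
      stop("relationship matrix is not positive semidefinite after jitter")
    dv[dv < 0] <- 0
    d[b$idx] <<- dv
    list(U = ev$vectors, idx = b$idx)
  })
  # with many blocks, rotations go through one sparse block-diagonal U
  Usp <- if (length(eb) > 1) {
    Matrix::sparseMatrix(
      i = unlist(lapply(eb, function(b) rep(b$idx, length(b$idx)))),
      j = unlist(lapply(eb, function(b) rep(b$idx, each = length(b$idx)))),
      x = unlist(lapply(eb, function(b) as.numeric(b$U))),
      dims = c(length(d), length(d)))
  } else NULL
  list(blocks = eb, d = d, Usp = Usp)
}

# t(U) %*% M with U block diagonal; rows of the result follow block order
.rotT <- function(eg, M) {
  M <- as.matrix(M)
  out <- if (!is.null(eg$Usp)) {
    as.matrix(Matrix::crossprod(eg$Usp, M))
  } else {
    o <- matrix(0, nrow(M), ncol(M))
    for (b in eg$blocks)
      o[b$idx, ] <- crossprod(b$U, M[b$idx, , drop = FALSE])
    o
  }
  colnames(out) <- colnames(M)
  out
}

# U %*% v back to the original row order
.rot <- function(eg, v) {
  if (!is.null(eg$Usp)) return(as.numeric(eg$Usp %*% v))
  out <- numeric(length(v))
  for (b in eg$blocks) out[b$idx] <- b$U %*% v[b$idx]
  out
}

.asDesign <- function(X, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("beta", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# one Gibbs chain in the eigenbasis of A; for the probit link `y` is binary
# and the latent liability is resampled each sweep with sigma_e2 fixed at 1
.gibbsChain <- function(y, X, eg, nIter, nBurnin, thin, seed,
                        priorDf, S0g, S0e, probit = FALSE) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  d <- eg$d
  Xstar <- .rotT(eg, X)
  XtXinv <- chol2inv(chol(crossprod(Xstar)))
  cholXtXinv <- chol(XtXinv)
  pos <- d > 1e-10
  dp <- d[pos]
  if (probit) {
    l <- ifelse(y > 0, 0.7, -0.7)
    ystar <- drop(.rotT(eg, l))
  } else ystar <- drop(.rotT(eg, y))
  beta <- drop(XtXinv %*% crossprod(Xstar, ystar))
  a <- numeric(n)
  v0 <- stats::var(if (probit) drop(l) else y)
  sigma_g2 <- v0 / 2
  sigma_e2 <- if (probit) 1 else v0 / 2
  nKeep <- retainedDraws(nIter, nBurnin, thin)
  draws <- matrix(NA_real_, nKeep, 3 + p,
                  dimnames = list(NULL, c("sigma_g2", "sigma_e2", "h2",
                                          colnames(X))))
  k <- 0L
  for (it in seq_len(nIter)) {
    if (probit) {
      # data augmentation: truncated-normal liabilities around eta
      eta <- drop(X %*% beta) + .rot(eg, a)
      pLo <- stats::pnorm(-eta)
      u <- stats::runif(n)
      q <- ifelse(y > 0, pLo + u * (1 - pLo), u * pLo)
      q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
      l <- eta + stats::qnorm(q)
      ystar <- drop(.rotT(eg, l))
    }
    # fixed effects
    rb <- ystar - a
    bhat <- drop(XtXinv %*% crossprod(Xstar, rb))
    beta <- bhat + sqrt(sigma_e2) * drop(crossprod(cholXtXinv,
                                                   stats::rnorm(p)))
    # genetic effects, independent in the eigenbasis
    r <- drop(ystar - Xstar %*% beta)
    prec <- 1 / sigma_e2 + 1 / (sigma_g2 * dp)
    mu_a <- (r[pos] / sigma_e2) / prec
    a[pos] <- mu_a + stats::rnorm(sum(pos)) / sqrt(prec)
    # variance components: scaled inverse chi-square full conditionals
    ssg <- sum(a[pos]^2 / dp)
    sigma_g2 <- (priorDf * S0g + ssg) /
      stats::rchisq(1, priorDf + sum(pos))
    if (!probit) {
      e <- r - a
      sigma_e2 <- (priorDf * S0e + sum(e^2)) /
        stats::rchisq(1, priorDf + n)
    }
    if (it > nBurnin && (it - nBurnin) %% thin == 0) {
      k <- k + 1L
      draws[k, ] <- c(sigma_g2, sigma_e2,
                      sigma_g2 / (sigma_g2 + sigma_e2), beta)
    }
  }
  draws
}

.mcmcFit <- function(y, X, A, nIter, nBurnin, thin, nChains, seed,
                     priorDf, rhatThreshold, probit, jitter) {
  X <- .asDesign(X, length(y))
  eg <- .eigenA(A, jitter = jitter)
  v0 <- stats::var(as.numeric(y))
  S0g <- .sichiScale(if (probit) 0.5 else v0 / 2, priorDf)
  S0e <- .sichiScale(v0 / 2, priorDf)
  seeds <- as.integer((seed + 99991 * (seq_len(nChains) - 1)) %% .Machine$integer.max)
  chains <- lapply(seeds, function(s)
    .gibbsChain(y, X, eg, nIter, nBurnin, thin, s,
                priorDf, S0g, S0e, probit = probit))
  nKeep <- nrow(chains[[1]])
  draws <- do.call(rbind, lapply(seq_along(chains), function(ci)
    data.frame(chain = ci, iter = seq_len(nKeep), chains[[ci]],
               check.names = FALSE)))
  rh <- if (nChains >= 2) {
    vapply(c("h2", "sigma_g2", "sigma_e2"), function(par)
      gelmanRubin(lapply(chains, function(ch) ch[, par])), numeric(1))
  } else stats::setNames(rep(NA_real_, 3), c("h2", "sigma_g2", "sigma_e2"))
  if (probit) rh["sigma_e2"] <- NA_real_   # fixed at 1, constant by design
  h2 <- draws$h2
  summ <- list(h2_mean = mean(h2), h2_sd = stats::sd(h2),
               h2_ci95 = unname(stats::quantile(h2, c(0.025, 0.975))),
               sigma_g2_mean = mean(draws$sigma_g2),
               sigma_e2_mean = mean(draws$sigma_e2))
  warnFlag <- any(rh > rhatThreshold, na.rm = TRUE)
  new("HeritabilityFit", draws = draws, summary = summ, rhat = rh,
      nRetained = as.integer(nKeep),
      settings = list(n_iter = nIter, n_burnin = nBurnin, thin = thin,
                      n_chains = nChains, seed = seed, prior_df = priorDf,
                      link = if (probit) "probit" else "gaussian",
                      rhat_threshold = rhatThreshold, chain_seeds = seeds),
      ml = list(), convergenceWarning = warnFlag)
}

#' Gaussian kinship-covariance heritability model, Gibbs MCMC
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, A\sigma_g^2)} (A the
#' additive relationship matrix) and \eqn{e \sim N(0, I\sigma_e^2)} by Gibbs
#' sampling. The model is rotated once into the eigenbasis of \eqn{A = U D
#' U^T}, where the genetic effects have independent full conditionals; the
#' variance components get scaled inverse chi-square updates. Priors are
#' scaled inverse chi-square with \code{priorDf} degrees of freedom, scale
#' set so the prior mode splits the phenotypic variance 50:50. Heritability
#' draws are \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}; with at
#' least two chains the split Gelman-Rubin statistic is computed for
#' \eqn{h^2} and both variances, and the fit carries a convergence warning
#' flag (not an error) when any exceeds \code{rhatThreshold}.
#'
#' @param y Numeric response (a prepared trait), complete cases only.
#' @param X Fixed-effects design matrix (default intercept only; collinear
#'   columns are dropped). Supply age and sex columns for the standard
#'   analysis.
#' @param A Additive relationship matrix (\eqn{2\phi}) or a
#'   [KinshipMatrix-class], ordered like \code{y}.
#' @param nIter,nBurnin,thin,nChains Sampler settings. Defaults are
#'   desk-scale; \code{preset = "full"} selects 400000/200000/40.
#' @param seed Integer seed; chain \eqn{c} uses \code{seed + 99991 (c-1)}.
#' @param priorDf Prior degrees of freedom for both variance components
#'   (default 5).
#' @param rhatThreshold Convergence flag threshold (default 1.03).
#' @param preset \code{"default"} or \code{"full"} (the long-run settings).
#' @param jitter Diagonal ridge added to \code{A} (default 1e-8).
#' @return A [HeritabilityFit-class].
#' @seealso [fitProbitMCMC()], [fitGaussianML()], [gelmanRubin()]
#' @export
fitGaussianMCMC <- function(y, X = NULL, A, nIter = 20000, nBurnin = 10000,
                            thin = 10, nChains = 2, seed = 1, priorDf = 5,
                            rhatThreshold = 1.03,
                            preset = c("default", "full"), jitter = 1e-8) {
  preset <- match.arg(preset)
  if (preset == "full") { nIter <- 400000; nBurnin <- 200000; thin <- 40 }
  if (anyNA(y)) stop("y must be complete; drop missing rows first")
  .mcmcFit(as.numeric(y), X, A, nIter, nBurnin, thin, nChains, seed,
           priorDf, rhatThreshold, probit = FALSE, jitter = jitter)
}

#' Probit-liability heritability model, Gibbs MCMC
#'
#' Binary outcomes are modelled as a thresholded latent Gaussian liability:
#' \eqn{P(y_i = 1) = \Phi(\eta_i)} with \eqn{\eta = X\beta + g},
#' \eqn{g \sim N(0, A\sigma_g^2)}. Each Gibbs sweep augments the data with
#' truncated-normal liabilities around \eqn{\eta} and then applies the
#' Gaussian machinery with the residual variance fixed at 1. Heritability is
#' reported on the liability scale, \eqn{h^2 = \sigma_g^2/(\sigma_g^2 + 1)}.
#'
#' @inheritParams fitGaussianMCMC
#' @param y Binary vector (0/1) with both classes present.
#' @return A [HeritabilityFit-class].
#' @export
fitProbitMCMC <- function(y, X = NULL, A, nIter = 20000, nBurnin = 10000,
                          thin = 10, nChains = 2, seed = 1, priorDf = 5,
                          rhatThreshold = 1.03,
                          preset = c("default", "full"), jitter = 1e-8) {
  preset <- match.arg(preset)
  if (preset == "full") { nIter <- 400000; nBurnin <- 200000; thin <- 40 }
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("y must be a complete 0/1 vector")
  if (all(y == 0) || all(y == 1))
    stop("degenerate_response: all responses identical")
  .mcmcFit(y, X, A, nIter, nBurnin, thin, nChains, seed, priorDf,
           rhatThreshold, probit = TRUE, jitter = jitter)
}

#' Gaussian heritability by profiled maximum likelihood
#'
#' The classical arm: with \eqn{V = \sigma_p^2\,(\rho A + (1-\rho) I)} and
#' \eqn{\rho = \sigma_g^2/(\sigma_g^2+\sigma_e^2)}, the likelihood is
#' profiled over \eqn{\rho} in the eigenbasis of \eqn{A} (\eqn{\beta} by
#' GLS and \eqn{\sigma_p^2} in closed form at each \eqn{\rho}; a single 1-D
#' optimization). Includes a likelihood-ratio test of \eqn{H_0:
#' \sigma_g^2 = 0} against the 50:50 boundary mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}.
#'
#' @inheritParams fitGaussianMCMC
#' @return List: \code{sigma_g2}, \code{sigma_e2}, \code{h2} (\eqn{=\hat\rho}),
#'   \code{beta}, \code{loglik}, \code{loglik_null}, \code{lrt},
#'   \code{p_value}, \code{boundary} (estimate pinned at 0 or 1) and
#'   \code{flat_likelihood} (\eqn{\rho} unidentifiable, e.g. \code{A}
#'   proportional to the identity).
#' @export
fitGaussianML <- function(y, X = NULL, A, jitter = 1e-8) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete; drop missing rows first")
  n <- length(y)
  X <- .asDesign(X, n)
  eg <- .eigenA(A, jitter = jitter)
  ystar <- drop(.rotT(eg, y))
  Xstar <- .rotT(eg, X)
  d <- eg$d
  profile <- function(rho) {
    w <- rho * d + (1 - rho)
    sw <- sqrt(w)
    fit <- stats::lm.fit(Xstar / sw, ystar / sw)
    rss <- sum(fit$residuals^2)
    sigma_p2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma_p2) + sum(log(w)) + n)
    list(ll = ll, sigma_p2 = sigma_p2, beta = fit$coefficients)
  }
  grid <- seq(0, 0.999, length.out = 21)
  gl <- vapply(grid, function(r) profile(r)$ll, numeric(1))
  flat <- diff(range(gl)) < 1e-8
  opt <- stats::optimize(function(r) profile(r)$ll, interval = c(0, 0.999),
                         maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, grid[which.max(gl)], 0)
  lls <- vapply(cand, function(r) profile(r)$ll, numeric(1))
  rho <- cand[which.max(lls)]
  at <- profile(rho)
  null <- profile(0)
  lrt <- max(0, 2 * (at$ll - null$ll))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                lower.tail = FALSE)
  boundary <- rho < 1e-6 || rho > 0.999 - 1e-6
  list(sigma_g2 = rho * at$sigma_p2,
       sigma_e2 = (1 - rho) * at$sigma_p2,
       h2 = if (flat) NA_real_ else rho,
       beta = at$beta, loglik = at$ll, loglik_null = null$ll,
       lrt = lrt, p_value = p, boundary = boundary,
       flat_likelihood = flat)
}

#' Fit a heritability model for one prepared trait
#'
#' Convenience wrapper: builds the design matrix (intercept, age,
#' sex = male indicator) from a prepared [PhenotypeTable-class], aligns the
#' relationship matrix to the phenotyped individuals (dropping rows with
#' missing covariates listwise, with a message), and dispatches to the MCMC
#' and/or ML arms.
#'
#' @param x A prepared [PhenotypeTable-class].
#' @param kin A [KinshipMatrix-class] covering the phenotyped individuals.
#' @param trait Trait column name. For the probit link the trait is
#'   dichotomized at \code{threshold}.
#' @param link \code{"gaussian"} or \code{"probit"}.
#' @param arm \code{"mcmc"}, \code{"ml"} or \code{"both"}.
#' @param threshold Liability threshold for the probit link (default 0, the
#'   prepared-trait median region).
#' @param ... Passed to [fitGaussianMCMC()] / [fitProbitMCMC()].
#' @return A [HeritabilityFit-class]; when \code{arm} includes \code{"ml"},
#'   the classical estimates are in [mlEstimate()].
#' @export
fitHeritability <- function(x, kin, trait,
                            link = c("gaussian", "probit"),
                            arm = c("both", "mcmc", "ml"),
                            threshold = 0, ...) {
  link <- match.arg(link); arm <- match.arg(arm)
  stopifnot(is(x, "PhenotypeTable"))
  if (!(is(kin, "KinshipMatrix") || inherits(kin, "famaggRelBlocks")))
    stop("kin must be a KinshipMatrix or relationshipBlocks() output")
  if (prepState(x) != "prepared")
    stop("fitHeritability expects a prepared table")
  d <- phenoData(x)
  ok <- !is.na(d[[trait]]) & !is.na(d$age) & !is.na(d$sex)
  if (any(!ok))
    message(sum(!ok), " rows dropped for missing trait/covariates")
  d <- d[ok, , drop = FALSE]
  kinIds <- if (is(kin, "KinshipMatrix")) individualIds(kin)
            else attr(kin, "ids")
  ids <- intersect(kinIds, d$individual_id)
  A <- if (is(kin, "KinshipMatrix")) {
    relationshipMatrix(kin)[ids, ids]
  } else {
    blocks <- lapply(unclass(kin), function(B) {
      keep <- rownames(B) %in% ids
      if (any(keep)) B[keep, keep, drop = FALSE] else NULL
    })
    blocks <- Filter(Negate(is.null), blocks)
    ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
    structure(blocks, ids = ids, class = "famaggRelBlocks")
  }
  d <- d[match(ids, d$individual_id), , drop = FALSE]
  X <- cbind(intercept = 1, age = d$age,
             sex_male = as.numeric(d$sex == "male"))
  y <- d[[trait]]
  if (link == "probit") y <- as.numeric(y > threshold)
  fit <- if (arm %in% c("mcmc", "both")) {
    if (link == "probit") fitProbitMCMC(y, X, A, ...)
    else fitGaussianMCMC(y, X, A, ...)
  } else {
    new("HeritabilityFit", draws = data.frame(), summary = list(),
        rhat = stats::setNames(rep(NA_real_, 3),
                               c("h2", "sigma_g2", "sigma_e2")),
        nRetained = 0L, settings = list(link = link), ml = list(),
        convergenceWarning = FALSE)
  }
  if (arm %in% c("ml", "both")) {
    if (link == "probit")
      stop("the classical likelihood arm supports the gaussian link only")
    fit@ml <- fitGaussianML(y, X, A)
  }
  fit
}

#' @describeIn posteriorDraws Retained draws accessor.
#' @export
setMethod("posteriorDraws", "HeritabilityFit", function(x) x@draws)

#' @describeIn h2Mean Posterior mean of \eqn{h^2}.
#' @export
setMethod("h2Mean", "HeritabilityFit", function(x) x@summary$h2_mean)

#' @describeIn h2CI Central 95\% credible interval of \eqn{h^2}.
#' @export
setMethod("h2CI", "HeritabilityFit", function(x) x@summary$h2_ci95)

#' @describeIn rhat Split Gelman-Rubin statistics.
#' @export
setMethod("rhat", "HeritabilityFit", function(x) x@rhat)

#' @describeIn mlEstimate Classical-arm estimates.
#' @export
setMethod("mlEstimate", "HeritabilityFit", function(x) x@ml)

#' Summarize a heritability fit as a one-row table
#'
#' Lays out the posterior mean heritability (as a percentage) and its
#' posterior standard deviation, the 95\% credible bounds, the monitored
#' \eqn{\hat R} and retained-draw count. The "SD" column is the posterior
#' standard deviation of the \eqn{h^2} draws on the proportion scale (it can
#' equally be read as a standard-error-like spread; both readings refer to
#' the same number).
#'
#' @param fit A [HeritabilityFit-class].
#' @param trait Optional trait label.
#' @return One-row \code{data.frame}.
#' @export
heritabilityTable <- function(fit, trait = NA_character_) {
  s <- fit@summary
  ml <- fit@ml
  data.frame(trait = trait,
             h2_percent = 100 * s$h2_mean,
             h2_sd = s$h2_sd,
             ci_low = s$h2_ci95[1], ci_high = s$h2_ci95[2],
             rhat_h2 = unname(fit@rhat["h2"]),
             n_retained = fit@nRetained,
             ml_h2 = if (length(ml)) ml$h2 else NA_real_,
             ml_p = if (length(ml)) ml$p_value else NA_real_,
             stringsAsFactors = FALSE)
}

setMethod("show", "HeritabilityFit", function(object) {
  s <- object@summary
  cat("HeritabilityFit (", object@settings$link, " link)\n", sep = "")
  if (length(s)) {
    cat(sprintf("  h2 = %.2f%% (posterior SD %.4f), 95%% CI [%.3f, %.3f]\n",
                100 * s$h2_mean, s$h2_sd, s$h2_ci95[1], s$h2_ci95[2]))
    cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f, retained draws = %d\n",
                s$sigma_g2_mean, s$sigma_e2_mean, object@nRetained))
    if (!is.na(object@rhat["h2"]))
      cat(sprintf("  split Rhat(h2) = %.4f%s\n", object@rhat["h2"],
                  if (object@convergenceWarning) "  [convergence warning]"
                  else ""))
  }
  if (length(object@ml))
    cat(sprintf("  ML arm: h2 = %.3f, LRT p = %.3g%s\n",
                object@ml$h2, object@ml$p_value,
                if (isTRUE(object@ml$flat_likelihood))
                  " [flat likelihood]" else ""))
  invisible(NULL)
})
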