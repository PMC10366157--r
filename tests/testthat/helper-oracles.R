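# independent oracles, written directly from first principles; they share no
# code with the package implementation

# ---- gene-dropping kinship estimate --------------------------------------
# drops unique founder alleles through the pedigree `reps` times; phi_ij is
# the probability a random allele from i and one from j are identical by
# descent, estimated as the mean over drops of the 4-combination indicator
oracleGeneDrop <- function(ped, reps = 1e5, seed = 42) {
  set.seed(seed)
  p <- pedTable(ped)
  p <- p[order(p$generation, p$iid), ]
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$iid)
  al1 <- matrix(0L, reps, n)   # paternal allele
  al2 <- matrix(0L, reps, n)   # maternal allele
  nextAllele <- 0L
  for (i in seq_len(n)) {
    fa <- p$pat[i]; mo <- p$mat[i]
    if (is.na(fa)) {
      al1[, i] <- nextAllele + 1L; nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      al1[, i] <- ifelse(pick, al1[, idx[fa]], al2[, idx[fa]])
    }
    if (is.na(mo)) {
      al2[, i] <- nextAllele + 1L; nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      al2[, i] <- ifelse(pick, al1[, idx[mo]], al2[, idx[mo]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(p$iid, p$iid))
  se <- matrix(0, n, n, dimnames = list(p$iid, p$iid))
  for (i in seq_len(n)) for (j in i:n) {
    ind <- ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
            (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
    phi[i, j] <- phi[j, i] <- mean(ind)
    se[i, j] <- se[j, i] <- stats::sd(ind) / sqrt(reps)
  }
  list(phi = phi, se = se)
}

# ---- brute-force relative-pair classification ----------------------------
# enumerates every ancestor path of each individual and labels each pair
# from the path structure
oracleClassify <- function(ped) {
  p <- pedTable(ped)
  pat <- stats::setNames(p$pat, p$iid)
  mat <- stats::setNames(p$mat, p$iid)
  sex <- stats::setNames(p$sex, p$iid)
  # all ancestor paths as vectors id -> ... -> ancestor
  pathsOf <- function(i) {
    out <- list()
    recurse <- function(path) {
      tail <- path[length(path)]
      for (pr in c(pat[tail], mat[tail])) {
        if (is.na(pr)) next
        np <- c(path, pr)
        out[[length(out) + 1L]] <<- np
        recurse(np)
      }
    }
    recurse(i)
    out
  }
  allPaths <- lapply(stats::setNames(p$iid, p$iid), pathsOf)
  ancAtDepth <- function(i, k) {
    ps <- allPaths[[i]]
    unique(unlist(lapply(ps, function(pp)
      if (length(pp) == k + 1L) pp[k + 1L] else NULL)))
  }
  parentsOf <- function(i) ancAtDepth(i, 1L)
  isFullSib <- function(i, j) {
    pi <- parentsOf(i); pj <- parentsOf(j)
    length(pi) == 2 && length(pj) == 2 && setequal(pi, pj)
  }
  childrenKey <- paste(p$pat, p$mat)
  classify <- function(i, j) {
    pi <- parentsOf(i); pj <- parentsOf(j)
    if (i %in% pj || j %in% pi) {
      par <- if (i %in% pj) i else j
      kid <- if (i %in% pj) j else i
      if (sex[par] == "unknown" || sex[kid] == "unknown") return(NULL)
      return(paste0(if (sex[par] == "male") "father-" else "mother-",
                    if (sex[kid] == "male") "son" else "daughter"))
    }
    if (isFullSib(i, j)) {
      ss <- sort(c(sex[i], sex[j]))
      if ("unknown" %in% ss) return(NULL)
      return(if (all(ss == "female")) "sister-sister"
             else if (all(ss == "male")) "brother-brother"
             else "brother-sister")
    }
    if (length(intersect(pi, pj)) == 1L) return("half-sibling")
    if (any(childrenKey %in% c(paste(i, j), paste(j, i))))
      return("spouse")
    if (i %in% ancAtDepth(j, 2L) || j %in% ancAtDepth(i, 2L))
      return("grandparent")
    if (any(vapply(pj, function(q) isFullSib(i, q), logical(1))) ||
        any(vapply(pi, function(q) isFullSib(j, q), logical(1))))
      return("avuncular")
    for (a in pi) for (b in pj)
      if (a != b && isFullSib(a, b)) return("cousin")
    NULL
  }
  counts <- stats::setNames(integer(length(pairClasses())), pairClasses())
  for (fam in unique(p$fid)) {
    ids <- p$iid[p$fid == fam]
    if (length(ids) < 2) next
    for (u in seq_len(length(ids) - 1L)) for (v in (u + 1L):length(ids)) {
      cl <- classify(ids[u], ids[v])
      if (!is.null(cl)) counts[cl] <- counts[cl] + 1L
    }
  }
  counts
}

# ---- brute-force familial correlation estimators -------------------------
oracleInterclass <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

oracleDoubleEntry <- function(a, b) {
  x <- c(a, b); y <- c(b, a)
  m <- mean(c(a, b))
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - m) * (y[i] - m)
    den <- den + (x[i] - m)^2
  }
  num / den
}

# ---- split Gelman-Rubin, plain formula -----------------------------------
oracleSplitRhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    h <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[1:h]), list(ch[(h + 1):(2 * h)]))
  }
  nn <- length(halves[[1]])
  means <- sapply(halves, mean)
  W <- mean(sapply(halves, var))
  B <- nn * var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# ---- dense multivariate-normal log-likelihood for the ML grid oracle -----
oracleLoglikGrid <- function(y, X, A, rhos) {
  n <- length(y)
  vapply(rhos, function(rho) {
    V0 <- rho * A + (1 - rho) * diag(n)
    # profile beta (GLS) and total variance
    Vi <- solve(V0)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    sigma_p2 <- drop(t(r) %*% Vi %*% r) / n
    ld <- determinant(V0, logarithm = TRUE)$modulus
    -0.5 * (n * log(2 * pi) + n * log(sigma_p2) + ld + n)
  }, numeric(1))
}

# ---- exact posterior mean of h2 by 2-D numerical integration -------------
# beta integrated analytically under its flat prior; scaled-inv-chisq(nu, S0)
# priors on both variances with prior mode v0/2 (matching the fitter)
oracleExactPosteriorH2 <- function(y, X, A, nu, gridN = 100,
                                   upper = 3 * var(y)) {
  n <- length(y)
  ev <- eigen(A, symmetric = TRUE)
  dd <- ev$values
  ys <- crossprod(ev$vectors, y)
  Xs <- crossprod(ev$vectors, X)
  v0 <- var(y)
  S0 <- v0 / 2 * (nu + 2) / nu
  margll <- function(sg, se) {
    w <- sg * dd + se
    fit <- lm.fit(Xs / sqrt(w), ys / sqrt(w))
    -0.5 * (sum(log(w)) +
              determinant(crossprod(Xs / sqrt(w)), log = TRUE)$modulus +
              sum(fit$residuals^2))
  }
  logprior <- function(s2) -(nu / 2 + 1) * log(s2) - nu * S0 / (2 * s2)
  gs <- seq(upper / gridN / 4, upper, length.out = gridN)
  es <- seq(upper / gridN / 4, upper, length.out = gridN)
  lg <- outer(gs, es, Vectorize(function(a, b)
    margll(a, b) + logprior(a) + logprior(b)))
  w <- exp(lg - max(lg)); w <- w / sum(w)
  sum(w * outer(gs, es, function(a, b) a / (a + b)))
}

# ---- Box-Cox profile-likelihood grid -------------------------------------
oracleBoxCoxGrid <- function(x, grid = seq(-2, 2, by = 0.005)) {
  n <- length(x)
  ll <- vapply(grid, function(lam) {
    y <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
    -n / 2 * log(sum((y - mean(y))^2) / n) + (lam - 1) * sum(log(x))
  }, numeric(1))
  grid[which.max(ll)]
}
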