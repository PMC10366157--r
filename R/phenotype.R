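#' Construct a PhenotypeTable
#'
#' @param data \code{data.frame} with columns \code{individual_id},
#'   \code{age} (years), \code{sex} and \code{energy} (kcal/day), plus trait
#'   columns.
#' @param traits Character vector naming the trait columns; defaults to every
#'   numeric column other than the covariates.
#' @param state Preparation state, default \code{"raw"} (servings/day).
#' @return A [PhenotypeTable-class].
#' @export
phenotypeTable <- function(data, traits = NULL, state = "raw") {
  data$individual_id <- as.character(data$individual_id)
  if (is.null(traits)) {
    cand <- setdiff(names(data), c("individual_id", "age", "sex", "energy"))
    traits <- cand[vapply(data[cand], is.numeric, logical(1))]
  }
  new("PhenotypeTable", data = data, traits = traits, state = state,
      exclusions = data.frame(individual_id = character(),
                              reason = character(), stringsAsFactors = FALSE))
}

#' Read a phenotype CSV
#'
#' Expects a header with \code{individual_id}, \code{age}, \code{sex},
#' \code{energy} and one column per food variable (servings/day).
#'
#' @param path CSV path.
#' @param traits Optional explicit trait column names.
#' @return A raw-state [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path, traits = NULL) {
  phenotypeTable(utils::read.csv(path, stringsAsFactors = FALSE),
                 traits = traits)
}

#' Exclude energy misreporters
#'
#' Removes rows whose reported daily energy intake is implausible: strictly
#' below \code{lo} or strictly above \code{hi} kcal/day (boundary values are
#' retained); rows with missing or non-positive energy are removed with
#' reason \code{"invalid_energy"}. Defaults reproduce the conventional
#' 800-4200 kcal/day plausibility window.
#'
#' @param x A raw-state [PhenotypeTable-class].
#' @param lo,hi Window bounds in kcal/day (defaults 800 and 4200).
#' @return The filtered table; removed rows are appended to
#'   [exclusionReport()].
#' @examples
#' pt <- phenotypeTable(data.frame(individual_id = 1:5, age = 40,
#'                                 sex = "female",
#'                                 energy = c(750, 800, 2000, 4200, 4201),
#'                                 fruit = 1))
#' phenoData(filterEnergy(pt))$energy   # 800 2000 4200
#' @export
filterEnergy <- function(x, lo = 800, hi = 4200) {
  stopifnot(is(x, "PhenotypeTable"))
  if (prepState(x) != "raw")
    stop("filterEnergy expects a raw-state table, got state=", prepState(x))
  if (!(lo < hi)) stop("lo must be below hi")
  d <- x@data
  e <- d$energy
  reason <- rep(NA_character_, nrow(d))
  reason[is.na(e) | e <= 0] <- "invalid_energy"
  reason[is.na(reason) & e < lo] <- "under_report"
  reason[is.na(reason) & e > hi] <- "over_report"
  drop <- !is.na(reason)
  excl <- rbind(x@exclusions,
                data.frame(individual_id = d$individual_id[drop],
                           reason = reason[drop], stringsAsFactors = FALSE))
  initialize(x, data = d[!drop, , drop = FALSE], exclusions = excl)
}

#' Exclude rows by a boolean criterion column
#'
#' Generic cohort-style exclusion (pregnancy, disease history, ...): removes
#' rows where the named logical column is \code{TRUE}.
#'
#' @param x A [PhenotypeTable-class].
#' @param column Name of a logical column in the table.
#' @param reason Reason recorded in the exclusion report (default the column
#'   name).
#' @return The filtered table.
#' @export
filterCriterion <- function(x, column, reason = column) {
  stopifnot(is(x, "PhenotypeTable"))
  d <- x@data
  if (!column %in% names(d)) stop("no such column: ", column)
  drop <- !is.na(d[[column]]) & as.logical(d[[column]])
  excl <- rbind(x@exclusions,
                data.frame(individual_id = d$individual_id[drop],
                           reason = reason, stringsAsFactors = FALSE))
  initialize(x, data = d[!drop, , drop = FALSE], exclusions = excl)
}

#' Energy-adjust trait columns
#'
#' Converts every trait from servings/day to servings per 1000 kcal:
#' \eqn{x \mapsto x / (\mathrm{energy}/1000)}.
#'
#' @param x A raw-state [PhenotypeTable-class] with positive energy for every
#'   row (run [filterEnergy()] first).
#' @return The table in \code{"energy_adjusted"} state.
#' @export
energyAdjust <- function(x) {
  stopifnot(is(x, "PhenotypeTable"))
  if (prepState(x) != "raw")
    stop("energyAdjust expects a raw-state table, got state=", prepState(x))
  d <- x@data
  if (any(is.na(d$energy) | d$energy <= 0))
    stop("non-positive or missing energy present; run filterEnergy() first")
  for (tr in x@traits) d[[tr]] <- d[[tr]] / (d$energy / 1000)
  initialize(x, data = d, state = "energy_adjusted")
}

#' Aggregate items into food groups
#'
#' Adds one column per group, the row-wise sum of its member item columns.
#' Groups may overlap (e.g. total meat containing red meat). Existing columns
#' are untouched; the new columns join the trait set.
#'
#' @param x A [PhenotypeTable-class].
#' @param groups Named list mapping group name to a character vector of item
#'   column names. An empty member list yields a column of zeros.
#' @return The table with the group columns appended.
#' @export
aggregateGroups <- function(x, groups) {
  stopifnot(is(x, "PhenotypeTable"), is.list(groups))
  d <- x@data
  for (g in names(groups)) {
    items <- groups[[g]]
    unknown <- setdiff(items, names(d))
    if (length(unknown))
      stop("food group '", g, "' references unknown items: ",
           paste(unknown, collapse = ", "))
    d[[g]] <- if (length(items))
      rowSums(as.matrix(d[, items, drop = FALSE])) else rep(0, nrow(d))
  }
  initialize(x, data = d, traits = union(x@traits, names(groups)))
}

#' Rank-based inverse-normal transform
#'
#' Blom scores: \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))} with average ranks for
#' ties, rescaled to exactly zero mean and unit variance.
#'
#' @param x Numeric vector without missing values.
#' @return Transformed vector.
#' @export
inverseNormal <- function(x) {
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  as.numeric(scale(z))
}

#' Profile-likelihood Box-Cox exponent
#'
#' Maximizes the Box-Cox profile log-likelihood
#' \eqn{\ell(\lambda) = -\tfrac n2 \log \hat\sigma^2_\lambda +
#' (\lambda - 1) \sum \log x_i} over \eqn{\lambda \in} \code{interval}.
#'
#' @param x Positive numeric vector.
#' @param interval Search interval for \eqn{\lambda} (default \code{c(-2, 2)}).
#' @return List with \code{lambda} and the transformed values \code{y}
#'   (\eqn{(x^\lambda - 1)/\lambda}, or \eqn{\log x} at \eqn{\lambda = 0}).
#' @export
boxCox <- function(x, interval = c(-2, 2)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  n <- length(x)
  slog <- sum(log(x))
  ll <- function(lam) {
    y <- if (abs(lam) < 1e-6) log(x) else (x^lam - 1) / lam
    -n / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * slog
  }
  opt <- stats::optimize(ll, interval = interval, maximum = TRUE,
                         tol = 1e-6)
  lam <- opt$maximum
  y <- if (abs(lam) < 1e-6) log(x) else (x^lam - 1) / lam
  list(lambda = lam, y = y)
}

#' Age-adjust and normalize traits
#'
#' The final preparation step: each trait is (1) age-adjusted by simple
#' linear regression on age (pooled across sexes by default; sex enters the
#' heritability model as a fixed effect), keeping the residuals, and (2)
#' normalized, either by the rank-based inverse-normal transform (default)
#' or by Box-Cox (profile-ML \eqn{\lambda} on residuals shifted to be
#' strictly positive) followed by z-scoring.
#'
#' @param x An energy-adjusted [PhenotypeTable-class].
#' @param traits Traits to prepare (default: all).
#' @param method \code{"inverse_normal"} or \code{"boxcox_then_zscore"}.
#' @param bySex Adjust for age within each sex separately (default
#'   \code{FALSE}, pooled).
#' @return The table in \code{"prepared"} state; prepared traits have mean 0
#'   and variance 1.
#' @export
prepareTraits <- function(x, traits = NULL,
                          method = c("inverse_normal", "boxcox_then_zscore"),
                          bySex = FALSE) {
  stopifnot(is(x, "PhenotypeTable"))
  method <- match.arg(method)
  if (prepState(x) != "energy_adjusted")
    stop("prepareTraits expects an energy_adjusted table, got state=",
         prepState(x))
  if (is.null(traits)) traits <- x@traits
  d <- x@data
  n <- nrow(d)
  if (n < 3) stop("need at least 3 phenotyped individuals")
  for (tr in traits) {
    v <- d[[tr]]
    if (anyNA(v) || anyNA(d$age))
      stop("missing values in trait or age for '", tr,
           "'; drop incomplete rows first")
    res <- if (bySex) {
      r <- numeric(n)
      for (s in unique(d$sex)) {
        i <- d$sex == s
        r[i] <- stats::resid(stats::lm(v[i] ~ d$age[i]))
      }
      r
    } else stats::resid(stats::lm(v ~ d$age))
    if (stats::var(res) < 1e-12 * max(1, mean(v)^2))
      stop("degenerate_trait: '", tr,
           "' has no residual variance after age adjustment")
    d[[tr]] <- switch(method,
      inverse_normal = inverseNormal(res),
      boxcox_then_zscore = {
        shifted <- res - min(res) + 1e-3 * stats::sd(res)
        as.numeric(scale(boxCox(shifted)$y))
      })
  }
  initialize(x, data = d, state = "prepared")
}

#' @describeIn phenoData Underlying data accessor.
#' @export
setMethod("phenoData", "PhenotypeTable", function(x) x@data)

#' @describeIn traitNames Trait column names.
#' @export
setMethod("traitNames", "PhenotypeTable", function(x) x@traits)

#' @describeIn prepState Preparation state accessor.
#' @export
setMethod("prepState", "PhenotypeTable", function(x) x@state)

#' @describeIn exclusionReport Rows removed by filters, with reasons.
#' @export
setMethod("exclusionReport", "PhenotypeTable", function(x) x@exclusions)

#' @describeIn nIndividuals Retained row count.
#' @export
setMethod("nIndividuals", "PhenotypeTable", function(x) nrow(x@data))

#' @describeIn individualIds Retained individual ids.
#' @export
setMethod("individualIds", "PhenotypeTable",
          function(x) x@data$individual_id)

#' @describeIn familyIds Family ids, when a \code{fid} column is present.
#' @export
setMethod("familyIds", "PhenotypeTable", function(x) {
  if ("fid" %in% names(x@data)) unique(x@data$fid) else character()
})

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", nrow(object@data), "individuals,",
      length(object@traits), "traits, state =", object@state, "\n")
  if (nrow(object@exclusions))
    cat("  excluded:", nrow(object@exclusions), "rows (",
        paste(sprintf("%s: %d", names(table(object@exclusions$reason)),
                      table(object@exclusions$reason)), collapse = ", "),
        ")\n")
  invisible(NULL)
})
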