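#' @import methods
NULL

#' Pedigree of related individuals
#'
#' An S4 container for a validated multi-family pedigree. Individuals carry a
#' family identifier, optional father/mother links, a sex code and a
#' generation index (founders are generation 0). Parent links must form a
#' directed acyclic graph, every referenced parent must be present, fathers
#' must be male and mothers female.
#'
#' @slot ped A \code{data.frame} with columns \code{fid}, \code{iid},
#'   \code{pat}, \code{mat} (\code{NA} when the parent is unknown),
#'   \code{sex} (\code{"male"}, \code{"female"} or \code{"unknown"}) and
#'   \code{generation} (integer, founders 0).
#'
#' @seealso [readPedigree()], [classifyPairs()], [kinshipMatrix()]
#' @export
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  need <- c("fid", "iid", "pat", "mat", "sex", "generation")
  if (!all(need %in% names(p)))
    return(paste("missing pedigree columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(p$iid))
    msgs <- c(msgs, paste("duplicate individual ids:",
                          paste(unique(p$iid[duplicated(p$iid)]), collapse = ", ")))
  if (!all(p$sex %in% c("male", "female", "unknown")))
    msgs <- c(msgs, "sex must be male, female or unknown")
  refs <- c(p$pat, p$mat)
  refs <- refs[!is.na(refs)]
  if (!all(refs %in% p$iid))
    msgs <- c(msgs, paste("referenced parents absent from pedigree:",
                          paste(unique(setdiff(refs, p$iid)), collapse = ", ")))
  sex <- stats::setNames(p$sex, p$iid)
  badF <- !is.na(p$pat) & sex[p$pat] == "female"
  badM <- !is.na(p$mat) & sex[p$mat] == "male"
  if (any(badF, na.rm = TRUE))
    msgs <- c(msgs, paste("father is recorded as female for rows:",
                          paste(p$iid[which(badF)], collapse = ", ")))
  if (any(badM, na.rm = TRUE))
    msgs <- c(msgs, paste("mother is recorded as male for rows:",
                          paste(p$iid[which(badM)], collapse = ", ")))
  if (length(msgs)) return(paste(msgs, collapse = "; "))
  TRUE
})

#' Kinship matrix of a pedigree
#'
#' Symmetric matrix of pairwise kinship coefficients \eqn{\phi_{ij}} (the
#' probability that one allele drawn at random from each individual is
#' identical by descent). The diagonal is \eqn{0.5 (1 + f_i)} with \eqn{f_i}
#' the inbreeding coefficient. The additive (numerator) relationship matrix is
#' \eqn{A = 2\phi}; see [relationshipMatrix()].
#'
#' @slot phi Symmetric numeric matrix with individual ids as dimnames.
#'
#' @seealso [kinshipMatrix()], [relationshipMatrix()], [writeKinship()]
#' @export
setClass("KinshipMatrix", representation(phi = "matrix"))

setValidity("KinshipMatrix", function(object) {
  phi <- object@phi
  if (is.null(rownames(phi)) || is.null(colnames(phi)))
    return("phi must carry individual ids as dimnames")
  if (nrow(phi) != ncol(phi)) return("phi must be square")
  if (!isTRUE(all.equal(phi, t(phi), tolerance = 1e-10)))
    return("phi must be symmetric")
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12))
    return("kinship coefficients must lie in [0, 1]")
  if (any(diag(phi) < 0.5 - 1e-12))
    return("self-kinship must be at least 0.5")
  TRUE
})

#' Phenotype table with preparation state
#'
#' Per-individual covariates (age, sex, daily energy intake in kcal) plus one
#' column per food/trait variable, moving through the preparation states
#' \code{"raw"} (servings/day as recorded), \code{"energy_adjusted"}
#' (servings per 1000 kcal) and \code{"prepared"} (age-adjusted, normalized,
#' zero mean and unit variance). Rows excluded along the way are kept in an
#' exclusion report.
#'
#' @slot data \code{data.frame} with \code{individual_id}, \code{age},
#'   \code{sex}, \code{energy} and the trait columns.
#' @slot traits Character vector naming the trait columns.
#' @slot state One of \code{"raw"}, \code{"energy_adjusted"},
#'   \code{"prepared"}.
#' @slot exclusions \code{data.frame} with columns \code{individual_id} and
#'   \code{reason} for rows removed by filters.
#'
#' @seealso [phenotypeTable()], [filterEnergy()], [energyAdjust()],
#'   [prepareTraits()]
#' @export
setClass("PhenotypeTable",
         representation(data = "data.frame", traits = "character",
                        state = "character", exclusions = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  if (!all(c("individual_id", "age", "sex", "energy") %in% names(d)))
    return("data must have individual_id, age, sex and energy columns")
  if (anyDuplicated(d$individual_id))
    return("duplicate individual ids in phenotype table")
  if (!object@state %in% c("raw", "energy_adjusted", "prepared"))
    return("state must be raw, energy_adjusted or prepared")
  if (!all(object@traits %in% names(d)))
    return(paste("trait columns absent from data:",
                 paste(setdiff(object@traits, names(d)), collapse = ", ")))
  TRUE
})

#' Heritability model fit
#'
#' Posterior draws and summaries from the kinship-covariance random-effects
#' model. Heritability is \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}
#' (liability scale with \eqn{\sigma_e^2 \equiv 1} for the probit link).
#'
#' @slot draws \code{data.frame} of retained posterior samples with columns
#'   \code{chain}, \code{iter}, \code{sigma_g2}, \code{sigma_e2}, \code{h2}
#'   and one column per fixed effect.
#' @slot summary Named list: \code{h2_mean}, \code{h2_sd}, \code{h2_ci95},
#'   \code{sigma_g2_mean}, \code{sigma_e2_mean}.
#' @slot rhat Named numeric vector of split Gelman-Rubin statistics
#'   (\code{NA} when only one chain was run).
#' @slot nRetained Integer count of retained draws per chain.
#' @slot settings List echoing the sampler settings and seed.
#' @slot ml List with the classical arm's estimates (\code{sigma_g2},
#'   \code{sigma_e2}, \code{h2}, \code{loglik}, \code{lrt}, \code{p_value},
#'   flags), or empty when not requested.
#' @slot convergenceWarning Logical; \code{TRUE} when any monitored
#'   \eqn{\hat R} exceeded the threshold supplied to the fitter.
#'
#' @seealso [fitGaussianMCMC()], [fitProbitMCMC()], [fitGaussianML()]
#' @export
setClass("HeritabilityFit",
         representation(draws = "data.frame", summary = "list",
                        rhat = "numeric", nRetained = "integer",
                        settings = "list", ml = "list",
                        convergenceWarning = "logical"))

setValidity("HeritabilityFit", function(object) {
  d <- object@draws
  if (nrow(d)) {
    if (!all(c("chain", "iter", "sigma_g2", "sigma_e2", "h2") %in% names(d)))
      return("draws must have chain, iter, sigma_g2, sigma_e2, h2 columns")
    if (any(d$h2 < 0 | d$h2 > 1)) return("h2 draws must lie in [0, 1]")
    if (any(d$sigma_g2 < 0) || any(d$sigma_e2 < 0))
      return("variance draws must be nonnegative")
  }
  TRUE
})
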