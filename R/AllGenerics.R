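#' Number of individuals
#' @param x A [Pedigree-class] or [PhenotypeTable-class].
#' @return Integer count.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Individual identifiers
#' @param x A [Pedigree-class], [KinshipMatrix-class] or
#'   [PhenotypeTable-class].
#' @return Character vector of ids, in the object's storage order.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Founder identifiers of a pedigree
#' @param x A [Pedigree-class].
#' @return Character vector of ids of individuals with no recorded parent.
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' Family identifiers
#' @param x A [Pedigree-class] or [PhenotypeTable-class].
#' @return Character vector of distinct family ids.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' Pedigree table
#' @param x A [Pedigree-class].
#' @return The underlying \code{data.frame} (fid, iid, pat, mat, sex,
#'   generation).
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))

#' Kinship coefficients
#' @param x A [KinshipMatrix-class].
#' @return Symmetric numeric matrix of \eqn{\phi_{ij}}.
#' @export
setGeneric("kinshipCoefficients",
           function(x) standardGeneric("kinshipCoefficients"))

#' Additive relationship matrix
#'
#' Returns \eqn{A = 2\phi}, the covariance structure of additive genetic
#' effects, optionally with a small ridge added to the diagonal so that
#' Cholesky/eigen factorizations succeed on semi-definite pedigrees.
#'
#' @param x A [KinshipMatrix-class].
#' @param jitter Nonnegative ridge added to the diagonal (default
#'   \code{1e-8}).
#' @return Numeric matrix with individual ids as dimnames.
#' @export
setGeneric("relationshipMatrix",
           function(x, jitter = 1e-8) standardGeneric("relationshipMatrix"))

#' Phenotype data accessor
#' @param x A [PhenotypeTable-class].
#' @return The underlying \code{data.frame}.
#' @export
setGeneric("phenoData", function(x) standardGeneric("phenoData"))

#' Trait column names
#' @param x A [PhenotypeTable-class].
#' @return Character vector of trait column names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Preparation state of a phenotype table
#' @param x A [PhenotypeTable-class].
#' @return \code{"raw"}, \code{"energy_adjusted"} or \code{"prepared"}.
#' @export
setGeneric("prepState", function(x) standardGeneric("prepState"))

#' Exclusion report
#' @param x A [PhenotypeTable-class].
#' @return \code{data.frame} with \code{individual_id} and \code{reason} for
#'   every row removed by a filter.
#' @export
setGeneric("exclusionReport", function(x) standardGeneric("exclusionReport"))

#' Retained posterior draws
#' @param x A [HeritabilityFit-class].
#' @return \code{data.frame} of retained draws (chain, iter, sigma_g2,
#'   sigma_e2, h2, fixed effects).
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Posterior mean heritability
#' @param x A [HeritabilityFit-class].
#' @return Numeric scalar in \eqn{[0, 1]}.
#' @export
setGeneric("h2Mean", function(x) standardGeneric("h2Mean"))

#' 95\% credible interval for heritability
#' @param x A [HeritabilityFit-class].
#' @return Numeric length-2 vector (2.5\% and 97.5\% posterior quantiles).
#' @export
setGeneric("h2CI", function(x) standardGeneric("h2CI"))

#' Split Gelman-Rubin statistics of a fit
#' @param x A [HeritabilityFit-class].
#' @return Named numeric vector (h2, sigma_g2, sigma_e2).
#' @export
setGeneric("rhat", function(x) standardGeneric("rhat"))

#' Maximum-likelihood arm of a fit
#' @param x A [HeritabilityFit-class].
#' @return List with sigma_g2, sigma_e2, h2, loglik, lrt, p_value and flags,
#'   or an empty list when the classical arm was not run.
#' @export
setGeneric("mlEstimate", function(x) standardGeneric("mlEstimate"))
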