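#' Per-sex descriptive statistics
#'
#' Mean and standard deviation per sex for continuous columns, percent in
#' the modal (or given) level for categorical ones — the layout of a cohort
#' descriptives table.
#'
#' @param x A [PhenotypeTable-class] (any state) with a \code{sex} column.
#' @param variables Columns to describe (default: \code{age},
#'   \code{energy} and all traits).
#' @return Tidy \code{data.frame}: \code{variable}, \code{sex}, \code{n},
#'   \code{type} (\code{"continuous"}/\code{"categorical"}), \code{mean},
#'   \code{sd}, \code{level}, \code{percent}.
#' @export
describePhenotypes <- function(x, variables = NULL) {
  stopifnot(is(x, "PhenotypeTable"))
  d <- phenoData(x)
  if (is.null(variables))
    variables <- intersect(c("age", "energy", traitNames(x)), names(d))
  rows <- list()
  for (s in unique(d$sex)) {
    ds <- d[d$sex == s, , drop = FALSE]
    for (v in variables) {
      col <- ds[[v]]
      if (is.numeric(col)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, sex = s, n = sum(!is.na(col)), type = "continuous",
          mean = mean(col, na.rm = TRUE), sd = stats::sd(col, na.rm = TRUE),
          level = NA_character_, percent = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        tab <- table(col)
        lev <- names(tab)[which.max(tab)]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, sex = s, n = sum(!is.na(col)), type = "categorical",
          mean = NA_real_, sd = NA_real_, level = lev,
          percent = 100 * unname(tab[lev]) / sum(tab),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.runDefaults <- function() {
  list(prep = list(method = "inverse_normal", by_sex = FALSE,
                   energy_lo = 800, energy_hi = 4200),
       food_groups = list(),
       classes = pairClasses(),
       alpha = 0.05,
       traits = NULL,
       link = "gaussian",
       arm = "both",
       mcmc = list(n_iter = 20000, n_burnin = 10000, thin = 10,
                   n_chains = 2),
       seed = 1L)
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with keys \code{pedigree}, \code{phenotypes},
#' \code{output_dir}, and optionally \code{prep} (method, by_sex,
#' energy_lo/hi), \code{food_groups} (name: [items]), \code{classes},
#' \code{alpha}, \code{traits}, \code{link}, \code{arm}, \code{mcmc}
#' (n_iter, n_burnin, thin, n_chains) and \code{seed}. Missing options take
#' the package defaults.
#'
#' @param path YAML config path.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- .runDefaults()
  for (k in names(def)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
    else if (is.list(def[[k]]) && !is.null(names(def[[k]])))
      for (kk in names(def[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- def[[k]][[kk]]
  }
  for (k in c("pedigree", "phenotypes"))
    if (is.null(cfg[[k]]) || !file.exists(cfg[[k]]))
      stop("config key '", k, "' must point to an existing file")
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  cfg
}

#' Run the end-to-end familial-aggregation pipeline
#'
#' Mirrors the analysis order of a family study: read pedigree and
#' phenotypes, exclude energy misreporters, energy-adjust to servings per
#' 1000 kcal, aggregate food groups, age-adjust and normalize, classify
#' relative pairs, estimate familial correlations for every trait and pair
#' class, and fit the heritability model per trait. Row-count deltas are
#' logged after every filter so participant flow is auditable.
#'
#' Outputs written to \code{output_dir}: \code{exclusions.csv},
#' \code{descriptives.csv}, \code{pair_counts.csv},
#' \code{correlations.csv}, \code{heritability_<trait>.json} and
#' \code{manifest.json} (settings, seed, package version and an MD5 checksum
#' per output file).
#'
#' @param config Path to a YAML config or a list from [readRunConfig()].
#' @param quiet Suppress stage messages.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  say <- function(...) if (!quiet) message(...)
  outDir <- cfg$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- tryCatch({
    ped <- readPedigree(cfg$pedigree)
    pt <- readPhenotypes(cfg$phenotypes, traits = cfg$traits)
    say("read: ", nIndividuals(ped), " pedigree members, ",
        nIndividuals(pt), " phenotyped")

    stage <- "filter"
    n0 <- nIndividuals(pt)
    pt <- filterEnergy(pt, cfg$prep$energy_lo, cfg$prep$energy_hi)
    say("filter: ", n0, " -> ", nIndividuals(pt), " rows (",
        n0 - nIndividuals(pt), " excluded)")

    stage <- "describe"
    desc <- describePhenotypes(pt)

    stage <- "adjust"
    pt <- energyAdjust(pt)
    if (length(cfg$food_groups))
      pt <- aggregateGroups(pt, cfg$food_groups)
    traits <- if (is.null(cfg$traits)) traitNames(pt) else cfg$traits

    stage <- "prepare"
    pt <- prepareTraits(pt, traits = traits, method = cfg$prep$method,
                        bySex = isTRUE(cfg$prep$by_sex))

    stage <- "pairs"
    pairs <- classifyPairs(ped)
    say("pairs: ", nrow(pairs), " classified relative pairs")

    stage <- "correlations"
    corr <- correlationReport(pt, pairs, traits = traits,
                              classes = cfg$classes, alpha = cfg$alpha)

    stage <- "kinship"
    kin <- kinshipMatrix(ped)

    stage <- "heritability"
    fits <- list()
    for (tr in traits) {
      fit <- fitHeritability(pt, kin, tr, link = cfg$link, arm = cfg$arm,
                             nIter = cfg$mcmc$n_iter,
                             nBurnin = cfg$mcmc$n_burnin,
                             thin = cfg$mcmc$thin,
                             nChains = cfg$mcmc$n_chains,
                             seed = cfg$seed)
      fits[[tr]] <- fit
      say("heritability[", tr, "]: h2 = ",
          sprintf("%.2f%%", 100 * h2Mean(fit)))
    }
    list(pt = pt, desc = desc, pairs = pairs, corr = corr, fits = fits)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  paths <- c(exclusions = file.path(outDir, "exclusions.csv"),
             descriptives = file.path(outDir, "descriptives.csv"),
             pair_counts = file.path(outDir, "pair_counts.csv"),
             correlations = file.path(outDir, "correlations.csv"))
  utils::write.csv(exclusionReport(res$pt), paths["exclusions"],
                   row.names = FALSE)
  utils::write.csv(res$desc, paths["descriptives"], row.names = FALSE)
  utils::write.csv(pairCountTable(res$pairs), paths["pair_counts"],
                   row.names = FALSE)
  utils::write.csv(res$corr, paths["correlations"], row.names = FALSE)
  for (tr in names(res$fits)) {
    fit <- res$fits[[tr]]
    fp <- file.path(outDir, paste0("heritability_", tr, ".json"))
    paths[paste0("heritability_", tr)] <- fp
    s <- fit@summary
    jsonlite::write_json(list(
      trait = tr,
      h2_percent = if (length(s)) 100 * s$h2_mean else NULL,
      h2_posterior_sd = if (length(s)) s$h2_sd else NULL,
      h2_ci95 = if (length(s)) s$h2_ci95 else NULL,
      rhat = as.list(rhat(fit)),
      n_retained = fit@nRetained,
      convergence_warning = fit@convergenceWarning,
      ml = if (length(mlEstimate(fit)))
        mlEstimate(fit)[c("h2", "sigma_g2", "sigma_e2", "loglik", "lrt",
                          "p_value", "boundary", "flat_likelihood")]
      else NULL,
      settings = fit@settings), fp, auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  manifest <- list(
    package = "famagg",
    version = as.character(utils::packageVersion("famagg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    settings = cfg[setdiff(names(cfg), "output_dir")],
    files = lapply(stats::setNames(as.list(paths), names(paths)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
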