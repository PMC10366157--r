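#' Construct a Pedigree from a data frame
#'
#' Validates parent links, normalizes sex codes, adds unlisted parents as
#' founders, checks for cycles and assigns generation indices (founders 0,
#' every child one past its deepest parent). Generation order with ties broken
#' by individual id gives the deterministic processing order used by
#' [kinshipMatrix()].
#'
#' @param df \code{data.frame} with columns \code{fid}, \code{iid},
#'   \code{pat}, \code{mat}, \code{sex}. Parent codes \code{"0"}, \code{""}
#'   and \code{NA} mean unknown; sex codes \code{1}/\code{M}/\code{male},
#'   \code{2}/\code{F}/\code{female}, anything else unknown.
#' @return A [Pedigree-class] object.
#' @examples
#' trio <- data.frame(fid = "F1", iid = c("dad", "mum", "kid"),
#'                    pat = c(NA, NA, "dad"), mat = c(NA, NA, "mum"),
#'                    sex = c(1, 2, 1))
#' ped <- pedigree(trio)
#' founders(ped)
#' @export
pedigree <- function(df) {
  need <- c("fid", "iid", "pat", "mat", "sex")
  if (!all(need %in% names(df)))
    stop("pedigree data must have columns: ", paste(need, collapse = ", "))
  p <- data.frame(fid = as.character(df$fid), iid = as.character(df$iid),
                  pat = .parentCode(df$pat), mat = .parentCode(df$mat),
                  sex = .sexCode(df$sex), stringsAsFactors = FALSE)
  if (anyDuplicated(p$iid))
    stop("duplicate individual ids: ",
         paste(unique(p$iid[duplicated(p$iid)]), collapse = ", "))

  # unlisted parents become founders of the same family, sex from their role
  known <- p$iid
  addF <- setdiff(p$pat[!is.na(p$pat)], known)
  addM <- setdiff(p$mat[!is.na(p$mat)], known)
  if (length(addF) || length(addM)) {
    famOf <- function(ids, col) vapply(ids, function(id)
      p$fid[match(TRUE, p[[col]] == id)], character(1))
    extra <- data.frame(
      fid = c(famOf(addF, "pat"), famOf(addM, "mat")),
      iid = c(addF, addM),
      pat = NA_character_, mat = NA_character_,
      sex = c(rep("male", length(addF)), rep("female", length(addM))),
      stringsAsFactors = FALSE)
    p <- rbind(p, extra)
  }

  # fathers must be male, mothers female; fill in unknowns, flag conflicts
  sex <- stats::setNames(p$sex, p$iid)
  fa <- unique(p$pat[!is.na(p$pat)]); mo <- unique(p$mat[!is.na(p$mat)])
  if (length(bad <- intersect(fa, mo)))
    stop("individuals listed both as father and as mother: ",
         paste(bad, collapse = ", "))
  conflictF <- p$iid[!is.na(p$pat) & sex[p$pat] == "female"]
  conflictM <- p$iid[!is.na(p$mat) & sex[p$mat] == "male"]
  if (length(conflictF) || length(conflictM))
    stop("sex-inconsistent parent links for offspring rows: ",
         paste(unique(c(conflictF, conflictM)), collapse = ", "))
  sex[intersect(fa, names(sex)[sex == "unknown"])] <- "male"
  sex[intersect(mo, names(sex)[sex == "unknown"])] <- "female"
  p$sex <- unname(sex[p$iid])

  p$generation <- .generationIndex(p)
  p <- p[order(p$generation, p$iid), , drop = FALSE]
  rownames(p) <- NULL
  new("Pedigree", ped = p)
}

#' Read a PLINK-style pedigree file
#'
#' Accepts whitespace- or comma-delimited files with at least five columns
#' (family id, individual id, father id, mother id, sex); extra columns are
#' ignored. A header line is auto-detected. \code{0} or an empty field means
#' an unknown parent.
#'
#' @param path Path to the pedigree file.
#' @return A validated [Pedigree-class].
#' @seealso [pedigree()] for the validation rules.
#' @export
readPedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  splitOne <- function(x) {
    f <- if (sep == ",") strsplit(x, ",", fixed = TRUE)[[1]]
         else strsplit(trimws(x), "[ \t]+")[[1]]
    trimws(f)
  }
  first <- splitOne(lines[[1]])
  if (length(first) < 5)
    stop("pedigree file needs at least 5 columns (FID IID PAT MAT SEX)")
  hasHeader <- any(toupper(first) %in% c("FID", "IID", "PAT", "MAT", "SEX",
                                         "FAMILY_ID", "INDIVIDUAL_ID"))
  if (hasHeader) lines <- lines[-1]
  fields <- lapply(lines, splitOne)
  short <- vapply(fields, length, integer(1)) < 5
  if (any(short))
    stop("pedigree rows with fewer than 5 fields: lines ",
         paste(which(short) + hasHeader, collapse = ", "))
  df <- data.frame(fid = vapply(fields, `[[`, character(1), 1),
                   iid = vapply(fields, `[[`, character(1), 2),
                   pat = vapply(fields, `[[`, character(1), 3),
                   mat = vapply(fields, `[[`, character(1), 4),
                   sex = vapply(fields, `[[`, character(1), 5),
                   stringsAsFactors = FALSE)
  pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped A [Pedigree-class].
#' @param path Output path.
#' @param sep Field separator: \code{" "} (PLINK .fam style) or \code{","}.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path, sep = " ") {
  p <- pedTable(ped)
  out <- data.frame(p$fid, p$iid,
                    ifelse(is.na(p$pat), "0", p$pat),
                    ifelse(is.na(p$mat), "0", p$mat),
                    c(male = 1L, female = 2L, unknown = 0L)[p$sex])
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parentCode <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x %in% c("0", "", "NA")] <- NA_character_
  x
}

.sexCode <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out
}

# Kahn topological sort over parent->child edges; errors on any cycle,
# naming the individuals involved. Returns the generation index.
.generationIndex <- function(p) {
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$iid)
  fa <- idx[p$pat]; mo <- idx[p$mat]          # NA where missing
  nParents <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (pi in c(fa[i], mo[i])) if (!is.na(pi))
      children[[pi]] <- c(children[[pi]], i)
  }
  gen <- rep(NA_integer_, n)
  queue <- which(nParents == 0L)
  gen[queue] <- 0L
  remaining <- nParents
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    for (ch in children[[i]]) {
      gen[ch] <- max(gen[ch], gen[i] + 1L, na.rm = TRUE)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (anyNA(gen))
    stop("pedigree contains a cycle involving: ",
         paste(p$iid[is.na(gen)], collapse = ", "))
  gen
}

#' @describeIn nIndividuals Count of individuals in the pedigree.
#' @export
setMethod("nIndividuals", "Pedigree", function(x) nrow(x@ped))

#' @describeIn individualIds Ids in generation order.
#' @export
setMethod("individualIds", "Pedigree", function(x) x@ped$iid)

#' @describeIn founders Individuals with both parents unknown.
#' @export
setMethod("founders", "Pedigree",
          function(x) x@ped$iid[is.na(x@ped$pat) & is.na(x@ped$mat)])

#' @describeIn familyIds Distinct family ids in the pedigree.
#' @export
setMethod("familyIds", "Pedigree", function(x) unique(x@ped$fid))

#' @describeIn pedTable Underlying pedigree table.
#' @export
setMethod("pedTable", "Pedigree", function(x) x@ped)

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  sizes <- table(p$fid)
  cat("Pedigree with", nrow(p), "individuals in", length(sizes), "families\n")
  cat("  family size:", min(sizes), "-", max(sizes),
      sprintf("(mean %.2f)", mean(sizes)), "\n")
  cat("  founders:", sum(is.na(p$pat) & is.na(p$mat)),
      " generations: 0 -", max(p$generation), "\n")
  invisible(NULL)
})
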