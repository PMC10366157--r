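#' Canonical relative-pair classes
#'
#' The twelve pair classes recognized by [classifyPairs()], in reporting
#' order: the four sexed parent-offspring dyads, the three sibling sex
#' combinations, spouses, and the second-degree classes (grandparent,
#' avuncular, half-sibling, cousin).
#'
#' @return Character vector of class labels.
#' @export
pairClasses <- function() {
  c("father-son", "father-daughter", "mother-son", "mother-daughter",
    "sister-sister", "brother-brother", "brother-sister", "spouse",
    "grandparent", "avuncular", "half-sibling", "cousin")
}

# classes whose two members are statistically exchangeable (double-entry
# intraclass estimator); all others are role-distinguishable (interclass)
.exchangeableClasses <- function()
  c("sister-sister", "brother-brother", "half-sibling", "cousin")

#' Enumerate and classify relative pairs
#'
#' Scans every within-family pair of individuals and labels the classifiable
#' ones. Classification uses explicit ancestor-link rules (not kinship
#' thresholds), so inbreeding cannot mislabel a class:
#' \itemize{
#'   \item parent-offspring: a direct parent link, subclassified by the sex
#'     of both members (pairs with a child of unknown sex are omitted);
#'   \item full siblings: both parents recorded and shared, subclassified by
#'     sex combination;
#'   \item half-siblings: exactly one shared recorded parent;
#'   \item spouses: two individuals listed as father and mother of at least
#'     one common child;
#'   \item grandparent: parent of a parent;
#'   \item avuncular: full sibling of a parent;
#'   \item cousin: the pairs' parents include a full-sibling pair.
#' }
#' Rules are applied in that order and each pair receives at most one class;
#' pairs fitting none are omitted. For role-distinguishable classes
#' \code{id_a} holds the "senior" role (parent, grandparent, uncle/aunt, the
#' brother in brother-sister, the male spouse).
#'
#' @param ped A [Pedigree-class].
#' @return \code{data.frame} with columns \code{fid}, \code{id_a},
#'   \code{id_b}, \code{pair_class} and \code{degree} (\code{"first"},
#'   \code{"second"} or \code{"spousal"}).
#' @examples
#' trio <- pedigree(data.frame(fid = "F1", iid = c("d", "m", "k"),
#'                             pat = c(NA, NA, "d"), mat = c(NA, NA, "m"),
#'                             sex = c(1, 2, 2)))
#' classifyPairs(trio)
#' @export
classifyPairs <- function(ped) {
  p <- pedTable(ped)
  pat <- stats::setNames(p$pat, p$iid)
  mat <- stats::setNames(p$mat, p$iid)
  sex <- stats::setNames(p$sex, p$iid)

  fullSibs <- function(i, j) {
    !is.na(pat[i]) && !is.na(mat[i]) &&
      identical(unname(pat[i]), unname(pat[j])) &&
      identical(unname(mat[i]), unname(mat[j]))
  }
  sharedParents <- function(i, j) {
    s <- 0L
    if (!is.na(pat[i]) && !is.na(pat[j]) && pat[i] == pat[j]) s <- s + 1L
    if (!is.na(mat[i]) && !is.na(mat[j]) && mat[i] == mat[j]) s <- s + 1L
    s
  }
  parentsOf <- function(i) {
    pr <- c(pat[i], mat[i])
    unname(pr[!is.na(pr)])
  }

  # children index for spouse detection
  byParents <- split(p$iid, paste(ifelse(is.na(p$pat), "", p$pat),
                                  ifelse(is.na(p$mat), "", p$mat)))
  couples <- unique(p[!is.na(p$pat) & !is.na(p$mat), c("pat", "mat")])
  coupleKey <- paste(couples$pat, couples$mat)

  res <- vector("list", length(unique(p$fid)))
  k <- 0L
  for (fam in unique(p$fid)) {
    ids <- sort(p$iid[p$fid == fam])
    m <- length(ids)
    if (m < 2L) next
    rows <- list(); r <- 0L
    addPair <- function(a, b, cls, deg) {
      r <<- r + 1L
      rows[[r]] <<- data.frame(fid = fam, id_a = a, id_b = b,
                               pair_class = cls, degree = deg,
                               stringsAsFactors = FALSE)
    }
    for (u in seq_len(m - 1L)) for (v in seq((u + 1L), m)) {
      i <- ids[u]; j <- ids[v]
      # 1. parent-offspring
      po <- NULL
      if (!is.na(pat[j]) && pat[j] == i) po <- c(i, j)
      else if (!is.na(mat[j]) && mat[j] == i) po <- c(i, j)
      else if (!is.na(pat[i]) && pat[i] == j) po <- c(j, i)
      else if (!is.na(mat[i]) && mat[i] == j) po <- c(j, i)
      if (!is.null(po)) {
        ps <- sex[po[1]]; cs <- sex[po[2]]
        if (ps != "unknown" && cs != "unknown") {
          cls <- paste0(ifelse(ps == "male", "father-", "mother-"),
                        ifelse(cs == "male", "son", "daughter"))
          addPair(po[1], po[2], cls, "first")
        }
        next
      }
      # 2. full siblings
      if (fullSibs(i, j)) {
        si <- sex[i]; sj <- sex[j]
        if (si != "unknown" && sj != "unknown") {
          if (si == "female" && sj == "female")
            addPair(i, j, "sister-sister", "first")
          else if (si == "male" && sj == "male")
            addPair(i, j, "brother-brother", "first")
          else {
            bro <- if (si == "male") c(i, j) else c(j, i)
            addPair(bro[1], bro[2], "brother-sister", "first")
          }
        }
        next
      }
      # 3. half-siblings (exactly one shared recorded parent)
      if (sharedParents(i, j) == 1L) { addPair(i, j, "half-sibling", "second"); next }
      # 4. spouses: a common child
      sp <- (paste(i, j) %in% coupleKey) || (paste(j, i) %in% coupleKey)
      if (sp) {
        ord <- if (sex[i] == "male" || sex[j] == "female") c(i, j) else c(j, i)
        addPair(ord[1], ord[2], "spouse", "spousal")
        next
      }
      # 5. grandparent: parent of a parent
      gp <- NULL
      if (i %in% unlist(lapply(parentsOf(j), parentsOf))) gp <- c(i, j)
      else if (j %in% unlist(lapply(parentsOf(i), parentsOf))) gp <- c(j, i)
      if (!is.null(gp)) { addPair(gp[1], gp[2], "grandparent", "second"); next }
      # 6. avuncular: full sibling of a parent
      av <- NULL
      if (any(vapply(parentsOf(j), function(q) fullSibs(i, q), logical(1))))
        av <- c(i, j)
      else if (any(vapply(parentsOf(i), function(q) fullSibs(j, q), logical(1))))
        av <- c(j, i)
      if (!is.null(av)) { addPair(av[1], av[2], "avuncular", "second"); next }
      # 7. first cousins: a full-sibling pair among the parents
      pi <- parentsOf(i); pj <- parentsOf(j)
      isCousin <- FALSE
      for (a in pi) {
        for (b in pj) if (a != b && fullSibs(a, b)) { isCousin <- TRUE; break }
        if (isCousin) break
      }
      if (isCousin) addPair(i, j, "cousin", "second")
    }
    if (r) { k <- k + 1L; res[[k]] <- do.call(rbind, rows[seq_len(r)]) }
  }
  if (!k) return(data.frame(fid = character(), id_a = character(),
                            id_b = character(), pair_class = character(),
                            degree = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Tabulate relative pairs by class
#'
#' Counts pairs per class in the layout of a relative-pair information table:
#' parents/offspring pooled, the three sibling subtypes with their total, and
#' the second-degree classes.
#'
#' @param pairs Output of [classifyPairs()].
#' @return \code{data.frame} with columns \code{group} and \code{n_pairs}.
#' @export
pairCountTable <- function(pairs) {
  cnt <- function(cls) sum(pairs$pair_class %in% cls)
  data.frame(
    group = c("parents/offspring",
              "siblings (total)", "sister-sister", "brother-brother",
              "brother-sister", "spouse", "grandparent", "avuncular",
              "half-sibling", "cousin"),
    n_pairs = c(cnt(c("father-son", "father-daughter",
                      "mother-son", "mother-daughter")),
                cnt(c("sister-sister", "brother-brother", "brother-sister")),
                cnt("sister-sister"), cnt("brother-brother"),
                cnt("brother-sister"), cnt("spouse"), cnt("grandparent"),
                cnt("avuncular"), cnt("half-sibling"), cnt("cousin")),
    stringsAsFactors = FALSE)
}
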