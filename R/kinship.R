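#' Kinship matrix by the recursive tabular method
#'
#' Computes pairwise kinship coefficients for every individual in the
#' pedigree. Individuals are processed in generation order (ties broken by
#' individual id): founders have \eqn{\phi_{ii} = 0.5} and \eqn{\phi_{ij} = 0}
#' with everyone processed before them; for a non-founder \eqn{i} with parents
#' \eqn{f, m},
#' \deqn{\phi_{ij} = \tfrac12(\phi_{fj} + \phi_{mj}), \qquad
#'       \phi_{ii} = \tfrac12(1 + \phi_{fm}),}
#' a missing parent contributing 0 (half-founder rule). Individuals from
#' different families have kinship 0, so the matrix is computed family by
#' family and assembled block-diagonally.
#'
#' @param ped A [Pedigree-class].
#' @return A [KinshipMatrix-class] ordered family-by-family, within family by
#'   (generation, id).
#' @examples
#' trio <- pedigree(data.frame(fid = "F1", iid = c("d", "m", "k"),
#'                             pat = c(NA, NA, "d"), mat = c(NA, NA, "m"),
#'                             sex = c(1, 2, 2)))
#' kinshipCoefficients(kinshipMatrix(trio))["d", "k"]   # 0.25
#' @export
kinshipMatrix <- function(ped) {
  p <- pedTable(ped)
  blocks <- lapply(split(p, p$fid), .kinshipBlock)
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  at <- 0L
  for (b in blocks) {
    m <- nrow(b)
    phi[at + seq_len(m), at + seq_len(m)] <- b
    at <- at + m
  }
  new("KinshipMatrix", phi = phi)
}

# tabular method within one family; rows already validated as a DAG
.kinshipBlock <- function(p) {
  p <- p[order(p$generation, p$iid), , drop = FALSE]
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$iid)
  fa <- unname(idx[p$pat]); mo <- unname(idx[p$mat])
  phi <- matrix(0, n, n, dimnames = list(p$iid, p$iid))
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (is.na(f)) 0 else phi[f, j]) +
                    (if (is.na(m)) 0 else phi[m, j]))
      phi[i, j] <- row
      phi[j, i] <- row
    }
    phi[i, i] <- if (is.na(f) || is.na(m)) 0.5 else 0.5 * (1 + phi[f, m])
  }
  phi
}

#' Family-block additive relationship matrices
#'
#' Individuals from different families are unrelated, so the additive
#' relationship matrix is block diagonal by family. For large cohorts this
#' representation (one dense block per family) is far cheaper than the full
#' matrix and is accepted directly by the heritability fitters, whose
#' eigendecompositions then run block by block.
#'
#' @param ped A [Pedigree-class].
#' @param jitter Diagonal ridge per block (default \code{1e-8}).
#' @return An object of class \code{"famaggRelBlocks"}: a list of per-family
#'   matrices \eqn{2\phi}; \code{attr(, "ids")} gives the concatenated
#'   individual order.
#' @seealso [relationshipMatrix()] for the dense equivalent.
#' @export
relationshipBlocks <- function(ped, jitter = 1e-8) {
  p <- pedTable(ped)
  blocks <- lapply(split(p, p$fid), function(pf) {
    A <- 2 * .kinshipBlock(pf)
    diag(A) <- diag(A) + jitter
    A
  })
  structure(blocks,
            ids = unlist(lapply(blocks, rownames), use.names = FALSE),
            class = "famaggRelBlocks")
}

#' Inbreeding coefficients
#'
#' \eqn{f_i = 2\phi_{ii} - 1}, the kinship between an individual's parents.
#'
#' @param kin A [KinshipMatrix-class].
#' @return Named numeric vector.
#' @export
inbreeding <- function(kin) 2 * diag(kinshipCoefficients(kin)) - 1

#' Write kinship coefficients to CSV
#'
#' @param kin A [KinshipMatrix-class].
#' @param path Output path.
#' @param format \code{"long"} (columns \code{id_a}, \code{id_b},
#'   \code{phi}; upper triangle including the diagonal) or \code{"matrix"}
#'   (square matrix with an \code{id} column).
#' @return \code{path}, invisibly.
#' @export
writeKinship <- function(kin, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  phi <- kinshipCoefficients(kin)
  if (format == "long") {
    ut <- upper.tri(phi, diag = TRUE)
    out <- data.frame(id_a = rownames(phi)[row(phi)[ut]],
                      id_b = colnames(phi)[col(phi)[ut]],
                      phi = phi[ut])
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    out <- data.frame(id = rownames(phi), phi, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @describeIn kinshipCoefficients Kinship coefficient matrix accessor.
#' @export
setMethod("kinshipCoefficients", "KinshipMatrix", function(x) x@phi)

#' @describeIn individualIds Ids in kinship matrix order.
#' @export
setMethod("individualIds", "KinshipMatrix", function(x) rownames(x@phi))

#' @describeIn relationshipMatrix Additive relationship matrix
#'   \eqn{A = 2\phi} with a diagonal ridge.
#' @export
setMethod("relationshipMatrix", "KinshipMatrix", function(x, jitter = 1e-8) {
  A <- 2 * x@phi
  diag(A) <- diag(A) + jitter
  A
})

setMethod("show", "KinshipMatrix", function(object) {
  phi <- object@phi
  cat("KinshipMatrix for", nrow(phi), "individuals\n")
  f <- 2 * diag(phi) - 1
  cat("  inbred individuals:", sum(f > 1e-12),
      sprintf(" max f = %.5f\n", max(f)))
  invisible(NULL)
})
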