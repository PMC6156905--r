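#' Kinship coefficient matrix from a pedigree
#'
#' Computes the matrix of kinship coefficients \eqn{\phi_{ij}} — the
#' probability that one allele sampled from individual i and one from j are
#' identical by descent — by the standard recursion over a
#' parents-before-children ordering: founders have \eqn{\phi_{ii} = 1/2} and
#' \eqn{\phi_{ij} = 0} with everyone ordered before them; a non-founder i
#' with parents f and m has \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for
#' \eqn{j \ne i} and \eqn{\phi_{ii} = (1 + \phi_{fm})/2}.
#'
#' Individuals are ordered family-block-contiguously, so the matrix is block
#' diagonal by family and per-family blocks are contiguous slices. The
#' additive (numerator) relationship matrix used by the kinship mixed model
#' is `2 * phi`; [relationship_matrix()] returns it directly.
#'
#' @param ped A [pedigree()] (or data frame coercible to one).
#' @return An object of class `famgxm_kinship`: a list with `ids` (ordered
#'   individual ids), `family` (family id per individual) and `phi` (the
#'   symmetric kinship matrix with `ids` as dimnames).
#' @examples
#' trio <- pedigree(data.frame(
#'   family_id = "F1", individual_id = c("A", "B", "C"),
#'   father_id = c(NA, NA, "A"), mother_id = c(NA, NA, "B"),
#'   sex = c("male", "female", "female")
#' ))
#' kinship_matrix(trio)$phi
#' @export
kinship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  ord <- ped_topological_order(ped)
  ids <- ped$individual_id[ord]
  fam <- ped$family_id[ord]
  fa <- match(ped$father_id[ord], ids)
  mo <- match(ped$mother_id[ord], ids)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      if (i > 1) {
        j <- seq_len(i - 1L)
        v <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
        phi[i, j] <- v
        phi[j, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
  }
  structure(list(ids = ids, family = fam, phi = phi),
            class = "famgxm_kinship")
}

#' @export
print.famgxm_kinship <- function(x, ...) {
  cat(sprintf("<famgxm_kinship: %d individuals, %d families>\n",
              length(x$ids), length(unique(x$family))))
  invisible(x)
}

#' @param kin A `famgxm_kinship`.
#' @rdname kinship_matrix
#' @export
relationship_matrix <- function(kin) {
  stopifnot(inherits(kin, "famgxm_kinship"))
  2 * kin$phi
}

#' Eigendecomposition of the relationship matrix
#'
#' Precomputes the spectral decomposition of `2 * phi` used by
#' [fit_lme_kinship()]; computing it once and reusing it across many fits on
#' the same cohort (as the replicate scan does) avoids the dominant cost.
#'
#' @param kin A `famgxm_kinship`.
#' @return List of class `famgxm_kinship_eigen` with `ids`, eigenvalues
#'   `values` (floored at 0; small negative round-off is truncated) and
#'   eigenvectors `vectors`.
#' @export
kinship_eigen <- function(kin) {
  A <- relationship_matrix(kin)
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    abort("relationship matrix is not positive semidefinite",
          class = "famgxm_kinship_error")
  }
  structure(list(ids = kin$ids, values = pmax(e$values, 0),
                 vectors = e$vectors),
            class = "famgxm_kinship_eigen")
}
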