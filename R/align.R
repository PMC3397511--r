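# Rigid-body superposition: Kabsch least-squares fit and common-substructure
# (database-style) alignment of a molecule set onto a template.

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired atoms, by SVD of the cross-covariance matrix with the usual
#' reflection guard (det forced to +1).
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix to fit onto.
#' @param pairing optional 2-column integer matrix (mobile index, reference
#'   index); default pairs row i with row i.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `sweep(mobile %*% t(rotation), 2, translation, "+")` is the fit, and
#'   `rmsd` over the pairing.
#' @export
kabsch_superpose <- function(mobile, reference, pairing = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(pairing)) {
    stopifnot(nrow(mobile) == nrow(reference))
    pairing <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  }
  A <- mobile[pairing[, 1], , drop = FALSE]
  B <- reference[pairing[, 2], , drop = FALSE]
  if (nrow(A) < 3L) stop("need at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centered cloud must exceed 1
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2L)
    stop("paired atoms are collinear; superposition is underdetermined")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)        # so that fitted = A %*% t(R)
  tvec <- cb - as.vector(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Align a molecule set onto a template by common substructure
#'
#' Every molecule is rigidly transformed so that its scaffold atoms fit the
#' template's scaffold atoms in the least-squares sense (Kabsch). The
#' scaffold is located either by a SMARTS pattern (through the RDKit bridge)
#' or, when `scaffold = NULL`, by the `scaffold_map` stored on each molecule
#' (as produced by the synthetic generator). When a molecule has several
#' substructure matches (ring automorphisms), the match with the lowest
#' fitted RMSD wins.
#'
#' @param set a `qsar_molecule_set`.
#' @param template template molecule, or a compound id present in `set`.
#' @param scaffold SMARTS pattern, or `NULL` to use stored scaffold maps.
#' @param force if `TRUE`, molecules without a match are passed through
#'   untransformed instead of being dropped.
#' @return the aligned set; attribute `report` holds a data.frame (id, rmsd,
#'   n_matches, matched) and attribute `failures` the unmatched ids.
#' @export
scaffold_align <- function(set, template, scaffold = thiourea_scaffold_smarts(),
                           force = FALSE) {
  if (is.character(template)) {
    if (!template %in% names(set)) stop("template id not in set: ", template)
    template <- set[[template]]
  }
  ref_idx <- scaffold_atoms(template, scaffold)
  if (is.null(ref_idx)) stop("scaffold pattern does not match the template")
  ref <- coords(template)[ref_idx[[1]], , drop = FALSE]

  out <- vector("list", length(set))
  report <- data.frame(id = names(set), rmsd = NA_real_,
                       n_matches = 0L, matched = FALSE)
  for (i in seq_along(set)) {
    mol <- set[[i]]
    matches <- scaffold_atoms(mol, scaffold)
    report$n_matches[i] <- length(matches %||% list())
    if (is.null(matches) || length(matches) == 0L) {
      if (force) out[[i]] <- mol
      next
    }
    fits <- lapply(matches, function(m)
      kabsch_superpose(coords(mol)[m, , drop = FALSE], ref))
    best <- which.min(vapply(fits, `[[`, numeric(1), "rmsd"))
    tr <- fits[[best]]
    mol <- set_coords(mol, apply_transform(coords(mol), tr))
    mol$scaffold_map <- matches[[best]]
    report$rmsd[i] <- tr$rmsd
    report$matched[i] <- TRUE
    out[[i]] <- mol
  }
  failures <- report$id[!report$matched]
  keep <- !vapply(out, is.null, logical(1))
  aligned <- molecule_set(out[keep])
  attr(aligned, "report") <- report
  attr(aligned, "failures") <- failures
  aligned
}

scaffold_atoms <- function(mol, scaffold) {
  if (is.null(scaffold)) {
    if (is.null(mol$scaffold_map)) return(NULL)
    return(list(mol$scaffold_map))
  }
  m <- smarts_matches(mol, scaffold)
  if (length(m) == 0L) NULL else m
}
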