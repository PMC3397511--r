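# CoMFA probe-interaction fields (Lennard-Jones 6-12 steric, Coulomb
# electrostatic with distance-dependent dielectric) and CoMSIA Gaussian
# similarity fields, plus descriptor-block assembly with minimum-sigma column
# filtering and per-field block scaling.

#' Probe specification
#'
#' The standard probe: an sp3 carbon with charge +1.0 e and radius 1.0 A,
#' and unit hydrophobic/donor/acceptor weights for the CoMSIA fields.
#'
#' @param charge probe charge (e). @param radius probe radius (A).
#' @param hydrophobicity,donor,acceptor CoMSIA probe weights.
#' @param rstar,eps Lennard-Jones parameters of the steric probe (sp3 C).
#' @return `qsar_probe` object.
#' @export
probe_spec <- function(charge = 1.0, radius = 1.0, hydrophobicity = 1.0,
                       donor = 1.0, acceptor = 1.0, rstar = 1.70, eps = 0.107) {
  vals <- c(charge, radius, hydrophobicity, donor, acceptor, rstar, eps)
  stopifnot(all(is.finite(vals)))
  structure(list(charge = charge, radius = radius,
                 hydrophobicity = hydrophobicity, donor = donor,
                 acceptor = acceptor, rstar = rstar, eps = eps),
            class = "qsar_probe")
}

#' Bundled van der Waals parameter table
#'
#' Published Tripos-style Lennard-Jones parameters (R* in Angstrom, epsilon
#' in kcal/mol) per element. Users can swap the table via the `table`
#' argument of the field functions.
#'
#' @return data.frame with columns `element`, `rstar`, `eps`.
#' @export
vdw_params <- function() read.csv(qsar3d_file("vdw_params.csv"))

vdw_lookup <- function(elements, table = vdw_params()) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("no van der Waals parameters for element(s): ",
         paste(bad, collapse = ", "))
  }
  table[idx, c("rstar", "eps")]
}

# point-to-atom distance matrix (npoints x natoms)
point_atom_dist <- function(points, xyz) {
  sqrt(outer(rowSums(points^2), rowSums(xyz^2), "+") - 2 * points %*% t(xyz))
}

#' CoMFA steric field (Lennard-Jones 6-12)
#'
#' Probe-atom van der Waals interaction energy at every lattice point:
#' `sum_i eps_ip * ((R*_ip/r)^12 - 2 (R*_ip/r)^6)` with `R*_ip = R*_i + R*_p`
#' and `eps_ip = sqrt(eps_i * eps_p)`, clamped to `[-cutoff, +cutoff]`.
#'
#' @param mol a `qsar_molecule`.
#' @param grid a `qsar_grid`.
#' @param probe a `qsar_probe`.
#' @param cutoff truncation energy in kcal/mol (default 30).
#' @param table vdW parameter table (see [vdw_params()]).
#' @param clamp set `FALSE` to return the raw (untruncated) energies, used by
#'   the additivity property tests.
#' @return numeric vector over lattice points (kcal/mol).
#' @export
comfa_steric <- function(mol, grid, probe = probe_spec(), cutoff = 30,
                         table = vdw_params(), clamp = TRUE) {
  stopifnot(cutoff > 0)
  par <- vdw_lookup(mol$atoms$element, table)
  r <- point_atom_dist(grid_points(grid), coords(mol))
  r <- pmax(r, 1e-10)                       # on-atom points clamp, not NaN
  Rst <- matrix(par$rstar + probe$rstar, nrow(r), ncol(r), byrow = TRUE)
  epsm <- matrix(sqrt(par$eps * probe$eps), nrow(r), ncol(r), byrow = TRUE)
  frac6 <- (Rst / r)^6
  e <- rowSums(epsm * (frac6^2 - 2 * frac6))
  if (clamp) pmin(pmax(e, -cutoff), cutoff) else e
}

#' CoMFA electrostatic field (Coulomb)
#'
#' `sum_i 332.0 * q_i * q_probe / (D(r) * r)` in kcal/mol, with the
#' distance-dependent dielectric `D(r) = r` by default (constant `D = 1`
#' available), clamped to `[-cutoff, +cutoff]`. Lattice points falling inside
#' any atom's van der Waals radius are flagged in the `in_vdw` attribute;
#' [assemble_block()] uses the flag for the in-sphere column-mean convention.
#'
#' @inheritParams comfa_steric
#' @param dielectric `"distance"` (D(r)=r) or `"constant"` (D=1).
#' @return numeric vector over lattice points with attribute `in_vdw`
#'   (logical vector).
#' @export
comfa_electrostatic <- function(mol, grid, probe = probe_spec(), cutoff = 30,
                                dielectric = c("distance", "constant"),
                                table = vdw_params(), clamp = TRUE) {
  stopifnot(cutoff > 0)
  dielectric <- match.arg(dielectric)
  q <- mol$atoms$charge
  r <- point_atom_dist(grid_points(grid), coords(mol))
  r <- pmax(r, 1e-10)
  denom <- if (dielectric == "distance") r^2 else r
  e <- rowSums(sweep(1 / denom, 2, 332.0 * q * probe$charge, "*"))
  if (clamp) e <- pmin(pmax(e, -cutoff), cutoff)
  par <- vdw_lookup(mol$atoms$element, table)
  inside <- rowSums(r < matrix(par$rstar, nrow(r), ncol(r), byrow = TRUE)) > 0
  attr(e, "in_vdw") <- inside
  e
}

#' Rule-based CoMSIA atom weights
#'
#' Returns the natoms x 5 weight matrix (columns S, E, H, D, A) used by the
#' CoMSIA similarity fields:
#' * S - cube of the element vdW radius (probe contributes radius^3 = 1);
#' * E - Gasteiger partial charge;
#' * H - binary hydrophobicity: carbon bonded only to C/H/halogen, and
#'   halogens, get 1;
#' * D - heavy N/O atoms bearing at least one hydrogen get 1;
#' * A - oxygens, and nitrogens with a free lone pair (sum of bond orders
#'   < 4, counting aromatic bonds as 1.5), get 1.
#'
#' The H/D/A typing needs the bond table; molecules generated by the
#' synthetic module carry an explicit `comsia` weight matrix instead.
#'
#' @param mol a `qsar_molecule` with bonds.
#' @param table vdW parameter table for the steric radii.
#' @return numeric matrix natoms x 5 with colnames S, E, H, D, A.
#' @export
comsia_atom_weights <- function(mol, table = vdw_params()) {
  if (!is.null(mol$comsia)) return(mol$comsia)
  if (is.null(mol$bonds))
    stop("molecule ", mol$id, ": CoMSIA typing needs bonds (or a preset comsia matrix)")
  el <- mol$atoms$element
  n <- length(el)
  b <- mol$bonds
  nbrs <- lapply(seq_len(n), function(i) c(b$to[b$from == i], b$from[b$to == i]))
  ordsum <- vapply(seq_len(n), function(i)
    sum(b$order[b$from == i | b$to == i]), numeric(1))
  halogens <- c("F", "Cl", "Br", "I")
  has_h <- vapply(nbrs, function(v) any(el[v] == "H"), logical(1))
  hydrophobic <- (el %in% halogens) |
    (el == "C" & vapply(nbrs, function(v)
      all(el[v] %in% c("C", "H", halogens)), logical(1)))
  donor <- el %in% c("N", "O") & has_h
  acceptor <- el == "O" | (el == "N" & ordsum < 4)
  w <- cbind(S = vdw_lookup(el, table)$rstar^3,
             E = mol$atoms$charge,
             H = as.numeric(hydrophobic),
             D = as.numeric(donor),
             A = as.numeric(acceptor))
  rownames(w) <- NULL
  w
}

#' CoMSIA similarity field
#'
#' Gaussian-attenuated similarity index at lattice point q:
#' `-sum_i w_probe * w_i * exp(-alpha * r_iq^2)`. The negative sign makes
#' attractive similarity terms negative, mirroring the energy-like sign of
#' the CoMFA fields; there are no singularities at any distance.
#'
#' @inheritParams comfa_steric
#' @param kind one of `"S"`, `"E"`, `"H"`, `"D"`, `"A"`.
#' @param alpha attenuation factor (default 0.3).
#' @return numeric vector over lattice points.
#' @export
comsia_field <- function(mol, grid, kind = c("S", "E", "H", "D", "A"),
                         alpha = 0.3, probe = probe_spec(),
                         table = vdw_params()) {
  kind <- match.arg(kind)
  w <- comsia_atom_weights(mol, table)[, kind]
  wp <- switch(kind, S = probe$radius^3, E = probe$charge,
               H = probe$hydrophobicity, D = probe$donor, A = probe$acceptor)
  r2 <- point_atom_dist(grid_points(grid), coords(mol))^2
  -as.vector(exp(-alpha * r2) %*% (wp * w))
}

#' Assemble a descriptor block over a molecule set
#'
#' Computes the requested fields for every molecule on one shared lattice,
#' applies the in-sphere electrostatic convention, drops columns whose
#' standard deviation is below `min_sigma`, and applies per-field block
#' scaling (`comfa_std`: each field kind is rescaled so its total variance
#' over the kept columns is 1, giving the kinds equal a-priori weight in the
#' PLS).
#'
#' @param set aligned `qsar_molecule_set`.
#' @param grid shared `qsar_grid`; default `make_grid(set, spacing, padding)`.
#' @param model `"comfa"` (fields S = steric LJ, E = Coulomb) or `"comsia"`
#'   (Gaussian similarity fields).
#' @param fields which field kinds to compute; defaults: CoMFA `c("S","E")`,
#'   CoMSIA `c("S","E","H","D","A")`.
#' @param spacing,padding lattice geometry when `grid` is not supplied.
#' @param probe probe specification.
#' @param cutoff CoMFA truncation (kcal/mol).
#' @param alpha CoMSIA attenuation factor.
#' @param dielectric CoMFA electrostatic dielectric model.
#' @param electro_inside `"mean"` replaces electrostatic values at lattice
#'   points inside a molecule's vdW envelope by the column mean of the
#'   compounds whose envelope does not cover the point (SYBYL-style);
#'   `"clamp"` keeps the truncated Coulomb value.
#' @param min_sigma minimum column standard deviation; columns below it are
#'   dropped. Default 2.0 kcal/mol for CoMFA, 0 for CoMSIA.
#' @param scaling `"comfa_std"` or `"none"`.
#' @param table vdW parameter table.
#' @return a `qsar_block`: list with `X` (compounds x kept columns), `meta`
#'   (kept-column lattice index, coordinates and field kind), `all_meta`,
#'   `dropped` (logical over all columns), `scale` (per-field factors),
#'   `grid`, `model`, and the field parameters used.
#' @export
assemble_block <- function(set, grid = NULL, model = c("comfa", "comsia"),
                           fields = NULL, spacing = 2.0, padding = 4.0,
                           probe = probe_spec(), cutoff = 30, alpha = 0.3,
                           dielectric = "distance",
                           electro_inside = c("mean", "clamp"),
                           min_sigma = NULL,
                           scaling = c("comfa_std", "none"),
                           table = vdw_params()) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  electro_inside <- match.arg(electro_inside)
  if (is.null(fields))
    fields <- if (model == "comfa") c("S", "E") else c("S", "E", "H", "D", "A")
  if (is.null(min_sigma)) min_sigma <- if (model == "comfa") 2.0 else 0.0
  if (is.null(grid)) grid <- make_grid(set, spacing = spacing, padding = padding)
  np <- n_points(grid)
  n <- length(set)
  pts <- grid_points(grid)

  cols_per_field <- function(kind) {
    m <- matrix(0, n, np)
    inside <- matrix(FALSE, n, np)
    for (i in seq_len(n)) {
      v <- if (model == "comfa") {
        if (kind == "S")
          comfa_steric(set[[i]], grid, probe, cutoff, table)
        else {
          e <- comfa_electrostatic(set[[i]], grid, probe, cutoff,
                                   dielectric, table)
          inside[i, ] <- attr(e, "in_vdw")
          as.vector(e)
        }
      } else {
        comsia_field(set[[i]], grid, kind, alpha, probe, table)
      }
      m[i, ] <- v
    }
    if (model == "comfa" && kind == "E" && electro_inside == "mean" &&
        any(inside)) {
      for (j in which(colSums(inside) > 0)) {
        outside <- !inside[, j]
        fill <- if (any(outside)) mean(m[outside, j]) else 0
        m[inside[, j], j] <- fill
      }
    }
    m
  }

  blocks <- lapply(fields, cols_per_field)
  X <- do.call(cbind, blocks)
  all_meta <- data.frame(
    field = rep(fields, each = np),
    point = rep(seq_len(np), times = length(fields)),
    x = rep(pts[, 1], length(fields)),
    y = rep(pts[, 2], length(fields)),
    z = rep(pts[, 3], length(fields))
  )
  sds <- apply(X, 2, sd)
  dropped <- sds < min_sigma
  if (all(dropped))
    stop("all ", length(dropped), " columns dropped at min_sigma = ",
         min_sigma, "; lower min_sigma")
  Xk <- X[, !dropped, drop = FALSE]
  meta <- all_meta[!dropped, , drop = FALSE]
  scale_factors <- setNames(rep(1, length(fields)), fields)
  if (scaling == "comfa_std") {
    for (k in fields) {
      sel <- meta$field == k
      tot <- sum(apply(Xk[, sel, drop = FALSE], 2, var))
      if (tot > 0) {
        scale_factors[k] <- 1 / sqrt(tot)
        Xk[, sel] <- Xk[, sel, drop = FALSE] * scale_factors[k]
      }
    }
  }
  rownames(Xk) <- names(set)
  structure(list(X = Xk, meta = meta, all_meta = all_meta, dropped = dropped,
                 scale = scale_factors, grid = grid, model = model,
                 fields = fields, min_sigma = min_sigma, scaling = scaling,
                 probe = probe, cutoff = cutoff, alpha = alpha,
                 dielectric = dielectric),
            class = "qsar_block")
}

#' @export
print.qsar_block <- function(x, ...) {
  cat(sprintf("<%s block: %d compounds x %d columns (%d dropped of %d), fields %s>\n",
              toupper(x$model), nrow(x$X), ncol(x$X), sum(x$dropped),
              length(x$dropped), paste(x$fields, collapse = "+")))
  invisible(x)
}
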