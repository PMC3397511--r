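# Grids, CoMFA/CoMSIA field kernels and descriptor-block assembly.

test_that("make_grid geometry and monotonicity", {
  atom <- toy_molecule("a", c(0, 0, 0))
  g <- make_grid(atom, spacing = 2, padding = 4)
  expect_identical(g$counts, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))
  pts <- grid_points(g)
  expect_identical(nrow(pts), 125L)
  expect_true(any(rowSums(abs(pts)) == 0))   # lattice centered on the atom

  # enlarging padding never removes lattice points
  g2 <- make_grid(atom, spacing = 2, padding = 6)
  expect_true(all(g2$counts >= g$counts))

  # containment: every atom at least `padding` inside the box faces
  gen <- small_synth()
  g3 <- make_grid(gen$set, spacing = 2, padding = 4)
  pts3 <- grid_points(g3)
  lo <- apply(pts3, 2, min); hi <- apply(pts3, 2, max)
  xyz <- do.call(rbind, lapply(gen$set, coords))
  expect_true(all(sweep(xyz, 2, lo) >= 4 - 1e-9))
  expect_true(all(sweep(-xyz, 2, -hi) >= 4 - 1e-9))

  expect_error(make_grid(molecule_set(list())), "empty")
  # doubling spacing strictly reduces the lattice
  g4 <- make_grid(gen$set, spacing = 4, padding = 4)
  expect_lt(n_points(g4), n_points(g3))
})

one_point_grid <- function(at) grid_spec(origin = at, spacing = 1, counts = c(1, 1, 1))

test_that("CoMFA steric kernel matches the closed form", {
  carbon <- toy_molecule("c", c(0, 0, 0))
  # single carbon, probe at 4.0 A: eps * ((R*/r)^12 - 2 (R*/r)^6)
  pars <- vdw_params()
  eps <- sqrt(pars$eps[pars$element == "C"] * 0.107)
  Rst <- pars$rstar[pars$element == "C"] + 1.70
  frac <- (Rst / 4)^6
  expect_equal(comfa_steric(carbon, one_point_grid(c(4, 0, 0))),
               eps * (frac^2 - 2 * frac), tolerance = 1e-8)
  # decay: 50 A away the energy is numerically zero
  expect_lt(abs(comfa_steric(carbon, one_point_grid(c(50, 0, 0)))), 1e-6)
  # on-atom lattice point clamps to exactly +30
  expect_identical(comfa_steric(carbon, one_point_grid(c(0, 0, 0))), 30)
  # unknown element is named
  expect_error(comfa_steric(toy_molecule("x", c(0, 0, 0), elements = "Xx"),
                            one_point_grid(c(4, 0, 0))), "Xx")
})

test_that("CoMFA electrostatic kernel, clamping and in-sphere flags", {
  # all charges zero -> zero vector
  m0 <- toy_molecule("m0", rnorm(9))
  g <- make_grid(m0, spacing = 2, padding = 4)
  expect_true(all(comfa_electrostatic(m0, g) == 0))

  # single charge q = +0.5 at 2.0 A with D(r) = r: 332*0.5/4 = 41.5 -> clamp
  mq <- toy_molecule("mq", c(0, 0, 0), charges = 0.5)
  expect_identical(as.vector(comfa_electrostatic(mq, one_point_grid(c(2, 0, 0)))), 30)
  # at 4.0 A: 332*0.5/16 = 10.375, unclamped
  expect_equal(as.vector(comfa_electrostatic(mq, one_point_grid(c(4, 0, 0)))),
               332 * 0.5 / 16, tolerance = 1e-10)
  # constant dielectric: 332*0.5/6 at r = 6 (below the clamp)
  expect_equal(as.vector(comfa_electrostatic(mq, one_point_grid(c(6, 0, 0)),
                                             dielectric = "constant")),
               332 * 0.5 / 6, tolerance = 1e-10)

  # mirror-symmetric charge pair: equal contributions at the midpoint
  pair <- toy_molecule("pair", c(-3, 3, 0, 0, 0, 0), charges = c(0.2, 0.2))
  e <- comfa_electrostatic(pair, one_point_grid(c(0, 0, 0)))
  expect_equal(as.vector(e), 2 * 332 * 0.2 / 9, tolerance = 1e-10)

  # in-sphere flag marks points inside the vdW envelope
  e2 <- comfa_electrostatic(mq, one_point_grid(c(1, 0, 0)))
  expect_true(attr(e2, "in_vdw"))
  expect_false(attr(comfa_electrostatic(mq, one_point_grid(c(4, 0, 0))),
                    "in_vdw"))
})

test_that("CoMSIA kernel: closed form, sign, monotone decay", {
  carbon <- toy_molecule("c", c(0, 0, 0),
                         comsia = cbind(S = 1.7^3, E = 0, H = 1, D = 0, A = 1))
  # atom on the lattice point: exactly -w_probe * r^3
  expect_equal(as.vector(comsia_field(carbon, one_point_grid(c(0, 0, 0)), "S")),
               -1.7^3, tolerance = 1e-12)
  # closed form at distance d
  for (d in c(1, 2.5, 4)) {
    expect_equal(
      as.vector(comsia_field(carbon, one_point_grid(c(d, 0, 0)), "S")),
      -1.7^3 * exp(-0.3 * d^2), tolerance = 1e-12)
  }
  # strictly decreasing magnitude with distance; never positive
  vals <- sapply(seq(0, 6, by = 0.5), function(d)
    comsia_field(carbon, one_point_grid(c(d, 0, 0)), "S"))
  expect_true(all(diff(abs(vals)) < 0))
  expect_true(all(vals <= 0))
  expect_error(comsia_field(carbon, one_point_grid(c(0, 0, 0)), "Z"))
})

test_that("CoMSIA rule-based atom typing", {
  # ethanol-like fragment: C-C-O-H plus one H on the first carbon
  m <- molecule("frag",
                data.frame(element = c("C", "C", "O", "H", "H"),
                           x = c(0, 1.5, 2.6, 3.0, -0.6),
                           y = c(0, 0, 0.8, 0.2, 0.9), z = 0, charge = 0),
                bonds = data.frame(from = c(1, 2, 3, 1),
                                   to = c(2, 3, 4, 5), order = 1))
  w <- comsia_atom_weights(m)
  expect_identical(colnames(w), c("S", "E", "H", "D", "A"))
  expect_equal(unname(w[, "D"]), c(0, 0, 1, 0, 0))  # O-H donor
  expect_equal(unname(w[, "A"]), c(0, 0, 1, 0, 0))  # O acceptor
  # hydrophobic: C bonded to C/H only; not the C bonded to O, not the O
  expect_equal(unname(w[, "H"]), c(1, 0, 0, 0, 0))
  expect_equal(unname(w[, "S"]), c(1.7, 1.7, 1.52, 1.5, 1.5)^3,
               tolerance = 1e-12)
})

test_that("field additivity over disjoint fragments (pre-clamp)", {
  a <- toy_molecule("a", c(0, 0, 0), charges = 0.3)
  b <- toy_molecule("b", c(6, 0, 0), charges = -0.2)
  ab <- toy_molecule("ab", rbind(c(0, 0, 0), c(6, 0, 0)),
                     charges = c(0.3, -0.2))
  g <- grid_spec(c(-2, -2, -2), 2, c(4, 3, 3))
  expect_equal(comfa_steric(ab, g, clamp = FALSE),
               comfa_steric(a, g, clamp = FALSE) +
                 comfa_steric(b, g, clamp = FALSE), tolerance = 1e-10)
  expect_equal(as.vector(comfa_electrostatic(ab, g, clamp = FALSE)),
               as.vector(comfa_electrostatic(a, g, clamp = FALSE)) +
                 as.vector(comfa_electrostatic(b, g, clamp = FALSE)),
               tolerance = 1e-10)
})

test_that("rigid-motion invariance of all field kernels", {
  set.seed(17)
  mol <- toy_molecule("m", rnorm(15, sd = 2),
                      elements = c("C", "N", "O", "C", "Cl"),
                      charges = round(runif(5, -0.3, 0.3), 3),
                      comsia = cbind(S = rep(1.7^3, 5), E = runif(5, -0.3, 0.3),
                                     H = c(1, 0, 0, 1, 1), D = c(0, 1, 0, 0, 0),
                                     A = c(0, 1, 1, 0, 0)))
  probe_pts <- matrix(rnorm(15, sd = 3), ncol = 3)
  R <- random_rotation(5); tv <- c(1.5, -2, 0.5)
  mol_r <- qsar3d:::set_coords(mol, sweep(coords(mol) %*% t(R), 2, tv, "+"))
  for (i in seq_len(nrow(probe_pts))) {
    p0 <- one_point_grid(probe_pts[i, ])
    p1 <- one_point_grid(as.vector(R %*% probe_pts[i, ]) + tv)
    expect_equal(comfa_steric(mol_r, p1), comfa_steric(mol, p0),
                 tolerance = 1e-8)
    expect_equal(as.vector(comfa_electrostatic(mol_r, p1)),
                 as.vector(comfa_electrostatic(mol, p0)), tolerance = 1e-8)
    for (k in c("S", "E", "H", "D", "A"))
      expect_equal(comsia_field(mol_r, p1, k), comsia_field(mol, p0, k),
                   tolerance = 1e-8)
  }
  # pure translation: the whole lattice moves with the set
  g <- make_grid(mol, spacing = 2, padding = 4)
  g_shift <- grid_spec(g$origin + tv, g$spacing, g$counts)
  mol_t <- qsar3d:::set_coords(mol, sweep(coords(mol), 2, tv, "+"))
  expect_equal(comfa_steric(mol_t, g_shift), comfa_steric(mol, g),
               tolerance = 1e-8)
})

test_that("assemble_block filtering, scaling and metadata", {
  gen <- small_synth()
  set <- gen$set
  # identity: min_sigma 0, no scaling reproduces the raw concatenation
  g <- make_grid(set, spacing = 4, padding = 2)
  blk <- assemble_block(set, grid = g, model = "comfa", min_sigma = 0,
                        scaling = "none", electro_inside = "clamp")
  expect_identical(ncol(blk$X), as.integer(2L * n_points(g)))
  raw_s <- t(sapply(set, comfa_steric, grid = g))
  expect_equal(unname(blk$X[, seq_len(n_points(g))]), unname(raw_s),
               tolerance = 1e-12)
  expect_identical(sum(blk$dropped), 0L)

  # constant columns are dropped for any positive min_sigma
  blk2 <- assemble_block(set, grid = g, model = "comfa", min_sigma = 1e-9,
                         scaling = "none", electro_inside = "clamp")
  const_cols <- apply(blk$X, 2, sd) < 1e-9
  expect_identical(sum(blk2$dropped), sum(const_cols))

  # comfa_std: equal per-field total variance
  blk3 <- assemble_block(set, grid = g, model = "comfa", min_sigma = 0.5,
                         scaling = "comfa_std")
  v <- tapply(apply(blk3$X, 2, var), blk3$meta$field, sum)
  expect_equal(unname(v["S"]), unname(v["E"]), tolerance = 1e-10)
  expect_equal(unname(v[["S"]]), 1, tolerance = 1e-10)

  # all values clamped, none non-finite
  expect_true(all(is.finite(blk$X)))
  expect_true(all(blk$X >= -30 & blk$X <= 30))

  # all-dropped error suggests lowering min_sigma
  expect_error(assemble_block(set, grid = g, model = "comfa",
                              min_sigma = 1e6), "min_sigma")

  # CoMSIA block: finite, with all five field kinds present
  blk5 <- assemble_block(set, grid = g, model = "comsia")
  expect_setequal(unique(blk5$meta$field), c("S", "E", "H", "D", "A"))
  expect_true(all(is.finite(blk5$X)))
})

test_that("in-sphere electrostatic handling replaces by column mean", {
  mols <- lapply(1:4, function(i)
    toy_molecule(paste0("m", i), rbind(c(0, 0, 0), c(3 * i, 0, 0)),
                 charges = c(0.3, -0.1)))
  set <- molecule_set(mols)
  g <- one_point_grid(c(0.5, 0, 0))      # inside every first atom's envelope
  blk_mean <- assemble_block(set, grid = g, model = "comfa", min_sigma = 0,
                             scaling = "none", electro_inside = "mean")
  blk_clamp <- assemble_block(set, grid = g, model = "comfa", min_sigma = 0,
                              scaling = "none", electro_inside = "clamp")
  # all compounds are inside: fallback fill 0 for the E column
  expect_true(all(blk_mean$X[, 2] == 0))
  expect_false(all(blk_clamp$X[, 2] == 0))
})
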