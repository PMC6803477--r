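test_that("kabsch recovers planted rigid transforms and refuses reflections", {
  set.seed(101)
  X <- matrix(rnorm(30), 10, 3)
  # identity
  f0 <- kabsch(X, X)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  # planted rotation + translation, no noise
  for (i in 1:20) {
    R0 <- random_rotation()
    t0 <- rnorm(3, sd = 5)
    Y <- sweep(X %*% t(R0), 2, t0, "+")
    f <- kabsch(X, Y)
    expect_lt(max(abs(f$rotation - R0)), 1e-9)
    expect_lt(max(abs(f$translation - t0)), 1e-9)
    expect_lt(f$rmsd, 1e-9)
  }
  # orthonormality contract
  f <- kabsch(X, matrix(rnorm(30), 10, 3))
  expect_equal(t(f$rotation) %*% f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  # mirrored points: best proper rotation cannot be a reflection
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1), 4, 3, byrow = TRUE)
  Pm <- P
  Pm[, 3] <- -Pm[, 3]
  fm <- kabsch(P, Pm)
  expect_equal(det(fm$rotation), 1, tolerance = 1e-9)
  expect_gt(fm$rmsd, 0.1)
  # degenerate input
  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch agrees with the bio3d fitting oracle", {
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(rnorm(36), 12, 3)
    Y <- matrix(rnorm(36), 12, 3)
    f <- kabsch(X, Y)
    # bio3d::rmsd prints at 3 decimals; compare at that precision
    expect_equal(round(f$rmsd, 3),
                 suppressWarnings(bio3d::rmsd(as.vector(t(Y)),
                                              as.vector(t(X)), fit = TRUE)))
  }
})

test_that("anchor superposition aligns anchors and preserves CDR deviations", {
  tpl <- loop_template(8, phi = -57, psi = -47, cdr = "CDR1",
                       sequence = "ACDEFGHI")
  a <- make_loop(tpl, seed = 1, cdr_type = "a1")
  # rigid copy: everything coincides
  b <- random_rigid_motion(a, seed = 2)
  b2 <- anchor_superpose(a, b)
  expect_lt(max(abs(loop_backbone(b2, "all") - loop_backbone(a, "all"))),
            1e-9)
  # CDR-only perturbation survives the anchor fit unchanged
  pert <- a
  pert$cdr$xyz[4, "CA", ] <- pert$cdr$xyz[4, "CA", ] + c(0.5, 0, 0)
  p2 <- anchor_superpose(a, random_rigid_motion(pert, seed = 3))
  expect_lt(max(abs(loop_backbone(p2, "anchors") -
                    loop_backbone(a, "anchors"))), 1e-9)
  expect_equal(sqrt(sum((p2$cdr$xyz[4, "CA", ] - a$cdr$xyz[4, "CA", ])^2)),
               0.5, tolerance = 1e-9)
  # distance invariance under arbitrary rigid pre-motion
  d0 <- dtw_distance(a, pert)
  for (s in 4:8) {
    expect_equal(dtw_distance(a, random_rigid_motion(pert, seed = s)), d0,
                 tolerance = 1e-9)
  }
})

test_that("dtw distance: zero on identity, closed form on forced diagonal,
           symmetric and non-negative", {
  tpl <- loop_template(7, phi = -70, psi = -35, cdr = "CDR1",
                       sequence = "ACDEFGH")
  a <- make_loop(tpl, seed = 5, cdr_type = "a1")
  expect_equal(dtw_distance(a, a), 0, tolerance = 1e-12)
  # uniform CDR translation: optimal path is the diagonal and the score
  # equals the per-residue backbone RMS displacement
  b <- a
  shift <- c(0.12, -0.05, 0.08)
  for (i in seq_len(dim(b$cdr$xyz)[1])) {
    b$cdr$xyz[i, , ] <- sweep(b$cdr$xyz[i, , ], 2, shift, "+")
  }
  expect_equal(dtw_distance(a, b, superpose = FALSE),
               sqrt(sum(shift^2)), tolerance = 1e-9)
  # symmetry and non-negativity on noisy pairs
  for (s in 1:5) {
    x <- make_loop(tpl, seed = s, cdr_type = "a1", torsion_sd = 4)
    y <- make_loop(tpl, seed = s + 50, cdr_type = "a1", torsion_sd = 4)
    d_xy <- dtw_distance(x, y)
    expect_gte(d_xy, 0)
    expect_equal(d_xy, dtw_distance(y, x), tolerance = 1e-9)
  }
  expect_error(dtw_distance(a, a[c("cdr_type")]), class = "error")
})

test_that("dtw dynamic program matches exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    la <- sample(3:5, 1)
    lb <- sample(3:5, 1)
    a <- make_loop(loop_template(la, phi = -60, psi = -45, cdr = "CDR1"),
                   seed = rep, cdr_type = "a1", torsion_sd = 15)
    b <- make_loop(loop_template(lb, phi = -100, psi = 10, cdr = "CDR1"),
                   seed = rep + 100, cdr_type = "a1", torsion_sd = 15)
    b_fit <- anchor_superpose(a, b)
    oracle <- brute_dtw(oracle_cost_matrix(a$cdr$xyz, b_fit$cdr$xyz))
    expect_equal(dtw_distance(a, b), oracle$total / oracle$len,
                 tolerance = 1e-12)
  }
})

test_that("backbone RMSD has its closed form on displacement fixtures and is
           symmetric", {
  tpl <- loop_template(8, cdr = "CDR3", sequence = "ACDEFGHI")
  a <- make_loop(tpl, seed = 3, cdr_type = "a3")
  expect_equal(backbone_rmsd(a, a), 0, tolerance = 1e-12)
  # one CA displaced by d, anchors untouched, anchor fit: rmsd = d/sqrt(4L)
  L <- 8
  d <- 1.3
  b <- a
  b$cdr$xyz[3, "CA", ] <- b$cdr$xyz[3, "CA", ] + c(0, d, 0)
  expect_equal(backbone_rmsd(a, b, fit_on = "anchors"), d / sqrt(4 * L),
               tolerance = 1e-12)
  expect_equal(backbone_rmsd(a, b, fit_on = "anchors"),
               backbone_rmsd(b, a, fit_on = "anchors"), tolerance = 1e-12)
  expect_equal(backbone_rmsd(a, b, fit_on = "loop"),
               backbone_rmsd(b, a, fit_on = "loop"), tolerance = 1e-12)
  # loop fit never exceeds the anchor fit residual
  expect_lte(backbone_rmsd(a, b, fit_on = "loop"),
             backbone_rmsd(a, b, fit_on = "anchors") + 1e-12)
  short <- make_loop(loop_template(6, cdr = "CDR3", sequence = "ACDEFG"),
                     seed = 4, cdr_type = "a3")
  expect_error(backbone_rmsd(a, short), "length mismatch")
})

test_that("pseudo bond and dihedral angles match independent vector oracles", {
  expect_equal(pseudo_bond_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(pseudo_bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(pseudo_bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "degenerate")
  # planar cis -> 0, planar trans -> 180
  expect_equal(pseudo_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                               c(1, 0, 0)), 0)
  expect_equal(pseudo_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                               c(1, 0, 0)), 180)
  set.seed(23)
  for (i in 1:100) {
    p <- matrix(rnorm(9, sd = 3), 3, 3)
    expect_equal(pseudo_bond_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(pseudo_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 oracle_torsion(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-9)
    # chirality: mirroring negates the torsion
    qm <- q
    qm[, 3] <- -qm[, 3]
    expect_equal(pseudo_dihedral(qm[1, ], qm[2, ], qm[3, ], qm[4, ]),
                 -pseudo_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("phi/psi torsions round-trip the generator and match bio3d", {
  tpl <- loop_template(8, phi = -57, psi = -47, cdr = "CDR1",
                       sequence = "ACDEFGHI")
  l <- make_loop(tpl, seed = 1, cdr_type = "a1")
  span <- cdrcanon:::loop_span(l)
  pp <- phi_psi(span)
  n <- length(span$pos)
  expect_true(is.na(pp[1, "phi"]))
  expect_true(is.na(pp[n, "psi"]))
  interior <- 7:12   # CDR residues away from the anchors
  expect_equal(unname(pp[interior, "phi"]), rep(-57, 6), tolerance = 1e-6)
  expect_equal(unname(pp[interior, "psi"]), rep(-47, 6), tolerance = 1e-6)
  # against the bio3d torsion oracle on (C,N,CA,C) and (N,CA,C,N)
  for (i in c(3, 8, 14)) {
    phi_ref <- bio3d::torsion.xyz(c(span$xyz[i - 1, "C", ],
                                    span$xyz[i, "N", ],
                                    span$xyz[i, "CA", ],
                                    span$xyz[i, "C", ]))
    psi_ref <- bio3d::torsion.xyz(c(span$xyz[i, "N", ],
                                    span$xyz[i, "CA", ],
                                    span$xyz[i, "C", ],
                                    span$xyz[i + 1, "N", ]))
    expect_equal(pp[i, "phi"], phi_ref[!is.na(phi_ref)], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(pp[i, "psi"], psi_ref[!is.na(psi_ref)], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # two residues: only psi(1) and phi(2) defined
  pp2 <- phi_psi(span$xyz[1:2, , ])
  expect_true(is.na(pp2[1, "phi"]) && is.na(pp2[2, "psi"]))
  expect_false(is.na(pp2[1, "psi"]) || is.na(pp2[2, "phi"]))
  # a chain break undefines the torsions across the junction
  broken <- span$xyz
  broken[9:n, , ] <- broken[9:n, , ] + 5
  ppb <- phi_psi(broken)
  expect_true(is.na(ppb[8, "psi"]) && is.na(ppb[9, "phi"]))
})

test_that("loop anchor transform is rigid-invariant and round-trips", {
  for (s in 1:10) {
    l <- make_torso(if (s %% 2) "extended" else "kinked", seed = s)
    v <- lat(l)
    # invariance under global rigid motion
    v2 <- lat(random_rigid_motion(l, seed = s + 100))
    expect_lt(max(abs(v - v2)), 1e-6)
    # round trip: frame(105) carried by the transform reproduces frame(117)
    f1 <- cdrcanon:::residue_frame(l$cdr$xyz[match("105", l$cdr$pos), , ])
    f2 <- cdrcanon:::residue_frame(l$cdr$xyz[match("117", l$cdr$pos), , ])
    R <- cdrcanon:::rot_zyz(v[["phi"]], v[["psi"]], v[["theta"]])
    expect_lt(max(abs(f1$axes %*% R - f2$axes)), 1e-9)
    expect_lt(max(abs(f1$origin + as.numeric(f1$axes %*% v[1:3]) -
                      f2$origin)), 1e-9)
  }
  # pure translation between identical frames: zero rotation
  l <- make_torso("extended", seed = 1)
  i105 <- match("105", l$cdr$pos)
  i117 <- match("117", l$cdr$pos)
  fake <- l
  shift <- c(3, -1, 2)
  fake$cdr$xyz[i117, , ] <- sweep(fake$cdr$xyz[i105, , ], 2, shift, "+")
  v <- lat(fake)
  # acos conditioning near the identity leaves ~1e-6 degrees of residue
  expect_equal(unname(v[c("phi", "psi", "theta")]), c(0, 0, 0),
               tolerance = 1e-5)
  f1 <- cdrcanon:::residue_frame(fake$cdr$xyz[i105, , ])
  expect_equal(unname(v[1:3]), as.numeric(t(f1$axes) %*% shift),
               tolerance = 1e-9)
})

test_that("torso classification follows the sign of alpha116", {
  expect_identical(torso_class(150, -35), "extended")
  expect_identical(torso_class(150, 35), "kinked")
  expect_identical(torso_class(150, 0), "extended")
  g <- torso_geometry(make_torso("extended", seed = 4))
  expect_identical(g$torso_class, "extended")
  expect_lt(g$alpha116, 0)
  expect_gt(g$tau116, 0)
  expect_lt(g$tau116, 180)
  expect_identical(rownames(g$torso_phi_psi), paste0("T", 1:7))
})
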