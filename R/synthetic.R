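# Synthetic loop generator: idealized CDR backbones built from torsion
# profiles (NeRF chain construction), with planted cluster structure,
# planted torso classes, exact-RMSD perturbations and separable sequence
# classes. Every generator is seed-deterministic and its fixtures pass the
# structure_io quality filters unless a defect is injected on purpose.

# Idealized backbone internal coordinates (Angstrom / degrees).
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8)

# Run code with a local, restored RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# NeRF atom placement: position d bonded to c with given bond length,
# angle b-c-d and torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- rad(angle); tor <- rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an n-residue backbone (n x 4 x 3, atoms N/CA/C/O) from phi/psi
# torsion vectors (omega fixed trans at 180).
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2, all(is.finite(phi[-1])),
            all(is.finite(psi[-n])))
  g <- BB_GEOM
  xyz <- array(NA_real_, c(n, 4L, 3L),
               dimnames = list(NULL, BB_ATOMS, c("x", "y", "z")))
  xyz[1, "N", ] <- c(0, 0, 0)
  xyz[1, "CA", ] <- c(g$b_n_ca, 0, 0)
  a <- rad(g$a_n_ca_c)
  xyz[1, "C", ] <- xyz[1, "CA", ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1)) {
    xyz[i + 1, "N", ] <- place_atom(xyz[i, "N", ], xyz[i, "CA", ],
                                    xyz[i, "C", ], g$b_c_n, g$a_ca_c_n,
                                    psi[i])
    xyz[i + 1, "CA", ] <- place_atom(xyz[i, "CA", ], xyz[i, "C", ],
                                     xyz[i + 1, "N", ], g$b_n_ca,
                                     g$a_c_n_ca, 180)
    xyz[i + 1, "C", ] <- place_atom(xyz[i, "C", ], xyz[i + 1, "N", ],
                                    xyz[i + 1, "CA", ], g$b_ca_c,
                                    g$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    tor_o <- if (i < n) psi[i] + 180 else 180
    xyz[i, "O", ] <- place_atom(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                g$b_c_o, g$a_ca_c_o, tor_o)
  }
  xyz
}

#' Loop template: torsion profile for an idealized CDR loop
#'
#' Describes the backbone of a CDR loop plus its ten anchor residues as
#' per-residue phi/psi torsions (omega is fixed trans). Anchors default to
#' an extended beta conformation so that loops built from different CDR
#' torsion profiles still superpose on their anchors.
#'
#' @param cdr_length CDR length in residues (anchors excluded).
#' @param phi,psi CDR torsions in degrees; scalars are recycled.
#' @param cdr `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param anchor_phi,anchor_psi Anchor torsions (degrees).
#' @param sequence Optional CDR sequence (length `cdr_length`); when NULL,
#'   [make_loop()] samples one.
#' @return A `loop_template`.
#' @export
loop_template <- function(cdr_length, phi = -60, psi = -40, cdr = "CDR3",
                          anchor_phi = -139, anchor_psi = 135,
                          sequence = NULL) {
  stopifnot(cdr_length >= 1)
  phi <- rep_len(phi, cdr_length)
  psi <- rep_len(psi, cdr_length)
  if (!is.null(sequence)) stopifnot(nchar(sequence) == cdr_length)
  structure(list(
    cdr = cdr, cdr_length = as.integer(cdr_length),
    phi = c(rep(anchor_phi, 5), phi, rep(anchor_phi, 5)),
    psi = c(rep(anchor_psi, 5), psi, rep(anchor_psi, 5)),
    sequence = sequence), class = "loop_template")
}

# Anchor position labels flanking a CDR window.
anchor_positions <- function(cdr) {
  w <- CDR_WINDOWS[[cdr]]
  list(n = as.character((w[1] - 5):(w[1] - 1)),
       c = as.character((w[2] + 1):(w[2] + 5)))
}

#' Build one synthetic CDR loop from a template
#'
#' Constructs the Cartesian backbone of anchors + CDR from the template
#' torsions (NeRF chain construction, idealized bond geometry), then adds
#' isotropic Gaussian coordinate noise of standard deviation `noise_sd`
#' to the CDR atoms only. Structural (conformational) noise is available
#' separately as `torsion_sd`, Gaussian perturbation of the CDR phi/psi
#' torsions: it bends the loop while keeping ideal bond geometry, so the
#' continuity filter still passes. B-factors are set to 30 and the
#' resolution metadata to 2.0 Angstrom, so fixtures without Cartesian
#' noise pass every quality filter.
#'
#' @param template A [loop_template()].
#' @param noise_sd Coordinate noise SD in Angstrom (>= 0); per-atom
#'   Cartesian jitter. Large values can break the peptide-bond
#'   continuity filter by construction.
#' @param torsion_sd Torsion noise SD in degrees (>= 0) on the CDR
#'   phi/psi angles.
#' @param seed Integer seed; the same seed reproduces the loop exactly.
#' @param cdr_type CDR type label for the loop (must match the template's
#'   window, e.g. `"a3"` for CDR3).
#' @param source Provenance string.
#' @return A `cdr_loop`.
#' @export
make_loop <- function(template, noise_sd = 0, seed = 1, cdr_type = "a3",
                      source = "synt:A", torsion_sd = 0) {
  stopifnot(inherits(template, "loop_template"), noise_sd >= 0,
            torsion_sd >= 0, normalize_cdr(cdr_type) == template$cdr)
  n_cdr <- template$cdr_length
  with_seed(seed, {
    phi <- template$phi
    psi <- template$psi
    if (torsion_sd > 0) {
      cdr_tors <- 5 + seq_len(n_cdr)
      phi[cdr_tors] <- phi[cdr_tors] + stats::rnorm(n_cdr, sd = torsion_sd)
      psi[cdr_tors] <- psi[cdr_tors] + stats::rnorm(n_cdr, sd = torsion_sd)
    }
    xyz <- build_backbone(phi, psi)
    cdr_idx <- 5 + seq_len(n_cdr)
    if (noise_sd > 0) {
      xyz[cdr_idx, , ] <- xyz[cdr_idx, , ] +
        stats::rnorm(length(xyz[cdr_idx, , ]), sd = noise_sd)
    }
    seq_cdr <- template$sequence
    if (is.null(seq_cdr)) {
      seq_cdr <- paste(sample(AA20, n_cdr, replace = TRUE), collapse = "")
    }
    anch <- anchor_positions(template$cdr)
    pos_cdr <- imgt_positions(template$cdr, n_cdr)
    new_cdr_loop(
      cdr_type = cdr_type,
      cdr = new_segment(pos_cdr, split_seq(seq_cdr),
                        xyz[cdr_idx, , , drop = FALSE]),
      anchors_n = new_segment(anch$n, rep("G", 5), xyz[1:5, , , drop = FALSE]),
      anchors_c = new_segment(anch$c, rep("G", 5),
                              xyz[5 + n_cdr + 1:5, , , drop = FALSE]),
      source = source, resolution = 2.0)
  })
}

# Distinct CDR torsion profiles used for planted families.
FAMILY_TORSIONS <- list(
  c(phi = -57, psi = -47),    # alpha-helical
  c(phi = -139, psi = 135),   # beta-extended
  c(phi = 60, psi = 45),      # left-handed helical
  c(phi = -100, psi = 20),
  c(phi = 70, psi = -60),
  c(phi = -150, psi = 60))

#' Generate a planted-cluster loop dataset
#'
#' Builds `k` families of loops. Every member of a family shares that
#' family's torsion profile plus per-member Gaussian torsion noise
#' (smooth conformational noise that keeps the backbone continuous), so
#' intra-family DTW distances are small while inter-family distances are
#' large. Calibration is asserted at generation time: the noiseless family
#' templates must be pairwise farther than `3 * eps` in DTW score and
#' every intra-family distance must stay below `eps / 2`; generation fails
#' otherwise rather than emit an uncalibrated fixture.
#'
#' Family sequences are drawn from disjoint residue alphabets;
#' `unique_fraction` controls how many distinct sequences a family has
#' (e.g. 1 yields a pseudo-class fixture). With `share_sequence = TRUE`
#' one sequence string is reused across the first two families, planting a
#' two-conformation sequence for the variability analysis.
#'
#' @param k Number of families (<= 6).
#' @param per_family Members per family.
#' @param cdr_length CDR length (default 8).
#' @param torsion_sd Torsion noise SD in degrees (default 2).
#' @param eps The DBSCAN radius the fixture is calibrated against
#'   (default 1.0).
#' @param unique_fraction Fraction of members carrying distinct sequences
#'   per family (default 1: all distinct); scalar or length-k vector.
#' @param share_sequence Plant one sequence shared between families 1 and
#'   2 (default FALSE).
#' @param cdr_type CDR type label of the loops (default `"a1"`).
#' @param seed Integer seed.
#' @return A `planted_loops` list: `loops`, `truth` (integer family
#'   labels), `ids`, `seed`, `eps`.
#' @export
make_cluster_set <- function(k = 3, per_family = 7, cdr_length = 8,
                             torsion_sd = 2, eps = 1.0,
                             unique_fraction = 1, share_sequence = FALSE,
                             cdr_type = "a1", seed = 1) {
  stopifnot(k >= 2, k <= length(FAMILY_TORSIONS), per_family >= 1)
  cdr_win <- normalize_cdr(cdr_type)
  unique_fraction <- rep_len(unique_fraction, k)
  templates <- lapply(seq_len(k), function(f) {
    loop_template(cdr_length, phi = FAMILY_TORSIONS[[f]]["phi"],
                  psi = FAMILY_TORSIONS[[f]]["psi"], cdr = cdr_win)
  })
  ref_loops <- lapply(seq_len(k), function(f) {
    make_loop(templates[[f]], noise_sd = 0, seed = 1, cdr_type = cdr_type)
  })
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- dtw_distance(ref_loops[[i]], ref_loops[[j]])
      if (d <= 3 * eps) {
        stop(sprintf(
          "templates %d and %d too close: DTW %.2f A <= 3 * eps", i, j, d))
      }
    }
  }
  # disjoint per-family alphabets (and one decoy alphabet slot)
  split_aa <- split(AA20, cut(seq_along(AA20), k + 1, labels = FALSE))
  loops <- list()
  truth <- integer(0)
  shared_seq <- NULL
  with_seed(seed, {
    for (f in seq_len(k)) {
      n_unique <- max(1L, ceiling(per_family * unique_fraction[f]))
      pool <- unique(vapply(seq_len(50 * n_unique), function(i) {
        paste(sample(split_aa[[f]], cdr_length, replace = TRUE),
              collapse = "")
      }, character(1)))[seq_len(n_unique)]
      for (m in seq_len(per_family)) {
        seq_m <- pool[((m - 1) %% n_unique) + 1]
        if (share_sequence && f <= 2 && m == 1) {
          if (is.null(shared_seq)) shared_seq <- seq_m
          seq_m <- shared_seq
        }
        tpl <- templates[[f]]
        tpl$sequence <- seq_m
        loop <- make_loop(tpl, noise_sd = 0, torsion_sd = torsion_sd,
                          seed = sample.int(2^31 - 1, 1),
                          cdr_type = cdr_type,
                          source = sprintf("f%d%02d:A", f, m))
        loops[[length(loops) + 1L]] <- loop
        truth <- c(truth, f)
      }
    }
  })
  # intra-family calibration: all member pairs stay within eps / 2
  for (f in seq_len(k)) {
    idx <- which(truth == f)
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1)) {
        d <- dtw_distance(loops[[idx[b]]], loops[[idx[a]]])
        if (d >= eps / 2) {
          stop(sprintf(
            "intra-family DTW %.2f A >= eps / 2; reduce torsion_sd", d))
        }
      }
    }
  }
  structure(list(loops = loops, truth = truth,
                 ids = vapply(loops, loop_id, character(1)),
                 seed = seed, eps = eps),
            class = "planted_loops")
}

#' Build a CDR3 loop with a planted kinked or extended torso
#'
#' Generates a 13-residue CDR3-like loop whose pseudo dihedral angle
#' alpha_116 has the requested sign (negative for extended, positive for
#' kinked), with tau_116 inside (0, 180). Torsions near position 116 are
#' jittered per seed; when the sampled geometry falls on the wrong side,
#' the loop is mirrored (a chirality flip negates every pseudo dihedral),
#' which preserves bond lengths and filter validity.
#'
#' @param kind `"kinked"` or `"extended"`.
#' @param seed Integer seed.
#' @param cdr_type `"b3"` (default) or another CDR3 label.
#' @return A `cdr_loop` whose [torso_geometry()] class equals `kind`.
#' @export
make_torso <- function(kind = c("kinked", "extended"), seed = 1,
                       cdr_type = "b3") {
  kind <- match.arg(kind)
  result <- NULL
  with_seed(seed, {
    for (attempt in 1:50) {
      phi <- stats::runif(13, -150, -50)
      psi <- stats::runif(13, 60, 170)
      tpl <- loop_template(13, phi = phi, psi = psi, cdr = "CDR3")
      tpl$sequence <- paste(sample(AA20, 13, replace = TRUE), collapse = "")
      loop <- make_loop(tpl, noise_sd = 0,
                        seed = sample.int(2^31 - 1, 1),
                        cdr_type = cdr_type,
                        source = sprintf("t%03d:A", attempt))
      g <- tryCatch(torso_geometry(loop), error = function(e) NULL)
      if (is.null(g) || abs(g$alpha116) < 10 || abs(g$alpha116) > 170) next
      wrong_side <- (kind == "kinked") != (g$alpha116 > 0)
      if (wrong_side) loop <- mirror_loop(loop)
      result <- loop
      break
    }
  })
  if (is.null(result)) stop("failed to generate a torso fixture")
  result
}

# Reflect all coordinates through the z = 0 plane (negates torsions).
mirror_loop <- function(loop) {
  ref <- function(seg) {
    seg$xyz[, , 3] <- -seg$xyz[, , 3]
    seg
  }
  loop$cdr <- ref(loop$cdr)
  loop$anchors_n <- ref(loop$anchors_n)
  loop$anchors_c <- ref(loop$anchors_c)
  loop
}

#' Generate separable labelled sequence classes
#'
#' Each class lives on its own disjoint residue alphabet and consists of
#' a consensus sequence plus distinct single-position (or, if exhausted,
#' double-position) mutations of it, so class membership is recoverable
#' by construction even when any one member is held out. Optional decoy
#' sequences come from a further disjoint alphabet and are labelled
#' `"unclustered"`.
#'
#' @param n_classes Number of classes.
#' @param seqs_per_class Distinct sequences per class.
#' @param length Sequence length.
#' @param n_decoys Decoy (unclustered) sequences (default 0).
#' @param seed Integer seed.
#' @return Tibble: `sequence`, `label` (class1..classN or
#'   `"unclustered"`).
#' @export
make_sequence_classes <- function(n_classes = 2, seqs_per_class = 10,
                                  length = 6, n_decoys = 0, seed = 1) {
  stopifnot(n_classes >= 1, n_classes + (n_decoys > 0) <= 6)
  groups <- split(AA20, cut(seq_along(AA20), n_classes + 1, labels = FALSE))
  # class members are a consensus plus enumerated single-position (then
  # double-position) mutations within the class alphabet, so every member
  # is close to the class profile and far from every other class
  draw_class <- function(alphabet, n) {
    consensus <- sample(alphabet, length, replace = TRUE)
    variants <- character(0)
    for (pos in seq_len(length)) {
      for (alt in setdiff(alphabet, consensus[pos])) {
        v <- consensus
        v[pos] <- alt
        variants <- c(variants, paste(v, collapse = ""))
      }
    }
    if (n - 1 > base::length(variants)) {
      for (p1 in seq_len(length - 1)) {
        for (p2 in (p1 + 1):length) {
          for (alt in setdiff(alphabet, consensus[p1])) {
            v <- consensus
            v[p1] <- alt
            v[p2] <- setdiff(alphabet, consensus[p2])[1]
            variants <- c(variants, paste(v, collapse = ""))
          }
        }
      }
    }
    if (n - 1 > base::length(variants)) stop("class too large for alphabet")
    c(paste(consensus, collapse = ""),
      sample(variants)[seq_len(n - 1)])
  }
  draw_decoys <- function(alphabet, n) {
    pool <- character(0)
    while (base::length(pool) < n) {
      pool <- unique(c(pool, vapply(seq_len(4 * n), function(i) {
        paste(sample(alphabet, length, replace = TRUE), collapse = "")
      }, character(1))))
    }
    pool[seq_len(n)]
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_classes), function(cl) {
      tibble::tibble(sequence = draw_class(groups[[cl]], seqs_per_class),
                     label = sprintf("class%d", cl))
    })
    if (n_decoys > 0) {
      rows[[base::length(rows) + 1L]] <- tibble::tibble(
        sequence = draw_decoys(groups[[n_classes + 1]], n_decoys),
        label = "unclustered")
    }
    do.call(rbind, rows)
  })
}

#' Displace one loop from another at an exact backbone RMSD
#'
#' Returns a copy of `loop` with one CDR CA atom displaced by
#' `rmsd * sqrt(4 L)` along x, where L is the CDR length: with anchors
#' untouched and an anchor-based fit, the backbone RMSD to the original
#' is exactly `rmsd` by construction.
#'
#' @param loop A `cdr_loop`.
#' @param rmsd Target anchor-fit backbone RMSD in Angstrom.
#' @param residue Which CDR residue's CA to displace (default 1).
#' @return The displaced loop.
#' @export
displace_loop <- function(loop, rmsd, residue = 1) {
  n <- dim(loop$cdr$xyz)[1]
  stopifnot(residue >= 1, residue <= n)
  d <- rmsd * sqrt(4 * n)
  loop$cdr$xyz[residue, "CA", ] <- loop$cdr$xyz[residue, "CA", ] + c(d, 0, 0)
  loop
}

#' Apply a random rigid motion to a loop
#'
#' @param loop A `cdr_loop`.
#' @param seed Integer seed.
#' @return The rigidly moved loop (conformation unchanged).
#' @export
random_rigid_motion <- function(loop, seed = 1) {
  with_seed(seed, {
    axis <- vunit(stats::rnorm(3))
    ang <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    t <- stats::rnorm(3, sd = 10)
    apply_rigid(loop, R, t)
  })
}
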