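# helper: quick loop set with controlled sequences and conformations
family_loops <- function(n, family, sequences, cdr_length = 8,
                         cdr_type = "a1", seed_base = 0) {
  tors <- cdrcanon:::FAMILY_TORSIONS[[family]]
  lapply(seq_len(n), function(i) {
    tpl <- loop_template(cdr_length, phi = tors["phi"], psi = tors["psi"],
                         cdr = cdrcanon:::normalize_cdr(cdr_type),
                         sequence = sequences[((i - 1) %% length(sequences)) + 1])
    make_loop(tpl, torsion_sd = 2, seed = seed_base + i,
              cdr_type = cdr_type, source = sprintf("s%d%02d:A", family, i))
  })
}

test_that("pairwise matrix equals elementwise recomputation and is
           permutation-equivariant", {
  loops <- family_loops(4, 1, c("AAAAAAAA", "CCCCCCCC"))
  loops <- c(loops, family_loops(2, 2, "DDDDDDDD", seed_base = 50))
  dm <- pairwise_matrix(loops)
  expect_identical(dim(dm$values), c(6L, 6L))
  expect_equal(diag(dm$values), setNames(rep(0, 6), dm$ids))
  expect_equal(dm$values, t(dm$values))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(dm$values[i, j], dtw_distance(loops[[i]], loops[[j]]),
                   tolerance = 1e-12)
    }
  }
  perm <- c(3, 1, 6, 2, 5, 4)
  dmp <- pairwise_matrix(loops[perm])
  expect_equal(unname(dmp$values), unname(dm$values[perm, perm]))
  # two identical loops -> zero 2x2 matrix
  two <- list(loops[[1]], loops[[1]])
  expect_equal(unname(pairwise_matrix(two)$values), matrix(0, 2, 2),
               tolerance = 1e-12)
})

test_that("incompatible CDR types are refused; equivalent pairs cluster
           jointly", {
  a1 <- family_loops(2, 1, "AAAAAAAA")
  a2 <- family_loops(2, 2, "CCCCCCCC", cdr_type = "a2")
  expect_error(pairwise_matrix(c(a1, a2)), "incompatible")
  L1 <- family_loops(2, 2, "DDDDDDDD", cdr_type = "L1", seed_base = 9)
  expect_error(pairwise_matrix(c(a1, L1), mode = "tcr_only"), "incompatible")
  expect_silent(pairwise_matrix(c(a1, L1), mode = "joint"))
})

test_that("dbscan recovers planted families exactly and marks sparse data
           as noise", {
  ds <- make_cluster_set(k = 3, per_family = 7, seed = 3)
  dm <- pairwise_matrix(ds$loops)
  db <- dbscan_precomputed(dm, eps = 1.0, min_pts = 5)
  expect_true(all(db$labels > 0))
  expect_identical(partition_of(db$labels), partition_of(ds$truth))
  # all points farther than eps: everything is noise
  far <- matrix(5, 8, 8)
  diag(far) <- 0
  db2 <- dbscan_precomputed(far, eps = 1.0, min_pts = 5)
  expect_true(all(db2$labels == 0L))
})

test_that("dbscan matches an independently written reference on random
           matrices", {
  set.seed(99)
  for (rep in 1:50) {
    n <- 12
    pts <- matrix(runif(n * 2, 0, 4), n, 2)
    d <- as.matrix(dist(pts))
    eps <- runif(1, 0.5, 2)
    min_pts <- sample(2:4, 1)
    mine <- dbscan_precomputed(d, eps, min_pts)
    ref <- reference_dbscan(d, eps, min_pts)
    # identical core sets, identical core partitions, identical noise
    ref_core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                       logical(1))
    expect_identical(mine$core, ref_core)
    expect_identical(partition_of(mine$labels, which(ref_core)),
                     partition_of(ref, which(ref_core)))
    expect_identical(which(mine$labels == 0L), which(ref == 0L))
    # every border point sits within eps of a core point of its cluster
    for (i in which(!ref_core & mine$labels > 0L)) {
      nbrs <- which(d[i, ] <= eps & ref_core)
      expect_true(mine$labels[i] %in% mine$labels[nbrs])
    }
  }
})

test_that("cluster membership is invariant to input order", {
  ds <- make_cluster_set(k = 3, per_family = 7, seed = 5)
  dm <- pairwise_matrix(ds$loops)
  base <- dbscan_precomputed(dm, 1.0, 5)
  set.seed(1)
  for (rep in 1:3) {
    perm <- sample(length(ds$loops))
    dmp <- pairwise_matrix(ds$loops[perm])
    got <- dbscan_precomputed(dmp, 1.0, 5)
    expect_identical(partition_of(got$labels[order(perm)]),
                     partition_of(base$labels))
  }
})

test_that("shrinking eps never merges clusters", {
  ds <- make_cluster_set(k = 3, per_family = 7, seed = 8)
  dm <- pairwise_matrix(ds$loops)
  labels_small <- dbscan_precomputed(dm, 0.5, 5)$labels
  labels_big <- dbscan_precomputed(dm, 2.0, 5)$labels
  # each small-eps cluster is contained in exactly one big-eps cluster
  for (cl in setdiff(unique(labels_small), 0L)) {
    inside <- labels_big[labels_small == cl]
    expect_length(unique(inside), 1)
  }
})

test_that("designation applies size and unique-sequence rules per mode", {
  # 6 structures, 3 unique sequences -> canonical (tcr_only)
  loops <- family_loops(6, 1, c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD"))
  dm <- pairwise_matrix(loops)
  cat1 <- designate(rep(1L, 6), loops, dm, mode = "tcr_only", eps = 1)
  expect_length(cat1$classes, 1)
  expect_identical(cat1$classes[[1]]$kind, "canonical")
  expect_false(grepl("\\*$", cat1$classes[[1]]$name))

  # 5 structures, 1 unique sequence -> pseudo-class, name ends "*"
  loops5 <- family_loops(5, 1, "AAAAAAAA")
  dm5 <- pairwise_matrix(loops5)
  cat2 <- designate(rep(1L, 5), loops5, dm5, mode = "tcr_only", eps = 1)
  expect_identical(cat2$classes[[1]]$kind, "pseudo")
  expect_true(grepl("\\*$", cat2$classes[[1]]$name))

  # 4 structures -> below the size rule, demoted
  loops4 <- family_loops(4, 1, c("AAAAAAAA", "CCCCCCCC"))
  cat3 <- designate(rep(1L, 4), loops4, pairwise_matrix(loops4),
                    mode = "tcr_only", eps = 1)
  expect_length(cat3$classes, 0)
  expect_length(cat3$unclustered, 4)

  # joint mode: 5 unique sequences -> unclustered, 6 -> valid
  seqs5 <- c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD", "EEEEEEEE", "FFFFFFFF")
  loops_j5 <- family_loops(6, 1, seqs5)
  cat4 <- designate(rep(1L, 6), loops_j5, pairwise_matrix(loops_j5),
                    mode = "joint", eps = 0.82)
  expect_length(cat4$classes, 0)
  loops_j6 <- family_loops(6, 1, c(seqs5, "GGGGGGGG"))
  cat5 <- designate(rep(1L, 6), loops_j6, pairwise_matrix(loops_j6),
                    mode = "joint", eps = 0.82)
  expect_length(cat5$classes, 1)

  # partition property: classes + unclustered = input, disjoint
  ds <- make_cluster_set(k = 3, per_family = 7, seed = 2,
                         unique_fraction = c(1, 1, 1 / 7))
  cl <- cluster_loops(ds$loops, eps = 1.0)
  all_ids <- c(unlist(lapply(cl$catalog$classes, `[[`, "members")),
               cl$catalog$unclustered)
  expect_setequal(all_ids, cl$matrix$ids)
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("class names follow the lettering convention", {
  # two length-6 a1 groups with 8 and 3 unique sequences -> A then B
  seqs_a <- sprintf("AAAAA%s", c("A", "C", "D", "E", "F", "G", "H", "I"))
  seqs_b <- sprintf("CCCCC%s", c("A", "C", "D"))
  loops <- c(family_loops(8, 1, seqs_a, cdr_length = 6),
             family_loops(8, 2, seqs_b, cdr_length = 6, seed_base = 40))
  labels <- rep(c(1L, 2L), each = 8)
  cat <- designate(labels, loops, pairwise_matrix(loops),
                   mode = "tcr_only", eps = 1)
  names_by_unique <- sapply(cat$classes, function(cl) cl$name)
  uniq <- sapply(cat$classes, function(cl) cl$n_unique)
  expect_identical(names_by_unique[order(-uniq)],
                   c("\u03b11-6-A", "\u03b11-6-B"))

  # tie on unique count broken by member count
  loops_t <- c(family_loops(6, 1, c("AAAAAA", "CCCCCC"), cdr_length = 6),
               family_loops(5, 2, c("DDDDDD", "EEEEEE"), cdr_length = 6,
                            seed_base = 70))
  cat_t <- designate(rep(c(1L, 2L), c(6, 5)), loops_t,
                     pairwise_matrix(loops_t), mode = "tcr_only", eps = 1)
  a_cl <- Filter(function(cl) cl$name == "\u03b11-6-A", cat_t$classes)[[1]]
  expect_length(a_cl$members, 6)

  # joint name carries both CDR labels and the observed length list
  jcat <- structure(list(classes = list(list(
    name = NA, members = paste0("m", 1:7), sequences = paste0("s", 1:7),
    n_unique = 7, representative = "m1", kind = "canonical",
    cdr_types = c("L1", "a1"), lengths = c(11L, 12L))),
    unclustered = character(), mode = "joint", eps = 0.82),
    class = "class_catalog")
  named <- name_classes(jcat)
  expect_identical(named$classes[[1]]$name, "\u03b11,L1-11,12-A")
})

test_that("the representative is the medoid, ties to the smallest id", {
  expect_identical(representative("only", matrix(0, 1, 1,
                                                 dimnames = list("only", "only"))), "only")
  d <- matrix(c(0, 0.2, 0.2,
                0.2, 0, 0.5,
                0.2, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(representative(c("A", "B", "C"), d), "A")
  # brute-force oracle on random matrices
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    ids <- paste0("id", sample(100, n))
    m <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    sums <- rowSums(m[sort(ids), sort(ids)])
    oracle <- sort(ids)[which.min(sums)]
    expect_identical(representative(ids, m), oracle)
  }
})

test_that("catalogs match via shared members or sequence-identical proxies", {
  seqs <- c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD")
  set_a <- family_loops(6, 1, seqs)
  cat_a <- designate(rep(1L, 6), set_a, pairwise_matrix(set_a),
                     mode = "tcr_only", eps = 1)

  # shared member: reuse two of a's loops in b
  set_b <- c(set_a[1:2], family_loops(4, 1, seqs, seed_base = 30))
  cat_b <- designate(rep(1L, 6), set_b, pairwise_matrix(set_b),
                     mode = "tcr_only", eps = 1)
  m1 <- match_catalogs(cat_a, cat_b, set_a, set_b)
  expect_identical(m1$evidence, "shared_member")

  # proxy: disjoint structures, same sequences, same conformation family
  set_c <- family_loops(6, 1, seqs, seed_base = 60)
  for (i in seq_along(set_c)) set_c[[i]]$source <- sprintf("zz%02d:C", i)
  cat_c <- designate(rep(1L, 6), set_c, pairwise_matrix(set_c),
                     mode = "tcr_only", eps = 1)
  m2 <- match_catalogs(cat_a, cat_c, set_a, set_c)
  expect_identical(m2$evidence, "sequence_proxy")

  # no shared member, no proxy (different family, different sequences)
  set_d <- family_loops(6, 2, c("KKKKKKKK", "MMMMMMMM"), seed_base = 90)
  cat_d <- designate(rep(1L, 6), set_d, pairwise_matrix(set_d),
                     mode = "tcr_only", eps = 1)
  m3 <- match_catalogs(cat_a, cat_d, set_a, set_d)
  expect_equal(nrow(m3), 0)
})

test_that("catalog JSON serialization round-trips", {
  ds <- make_cluster_set(k = 3, per_family = 7, seed = 4)
  cl <- cluster_loops(ds$loops, eps = 1.0)
  path <- tempfile(fileext = ".json")
  write_catalog_json(cl$catalog, path)
  back <- read_catalog_json(path)
  expect_identical(length(back$classes), length(cl$catalog$classes))
  expect_identical(lapply(back$classes, `[[`, "name"),
                   lapply(cl$catalog$classes, `[[`, "name"))
  expect_identical(lapply(back$classes, `[[`, "members"),
                   lapply(cl$catalog$classes, `[[`, "members"))
  expect_identical(back$mode, cl$catalog$mode)
})
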