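# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the quantity under test is computed.

# Brute-force DTW: enumerate every monotone boundary-to-boundary warping
# path over a cost matrix; return the minimal total cost and the length of
# the best path (ties: first found in diagonal/vertical/horizontal order).
brute_dtw <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(total = Inf, len = NA_integer_)
  recurse <- function(i, j, total, len) {
    total <- total + cost[i, j]
    if (i == n && j == m) {
      if (total < best$total) best <<- list(total = total, len = len)
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, total, len + 1)
    if (i < n) recurse(i + 1, j, total, len + 1)
    if (j < m) recurse(i, j + 1, total, len + 1)
  }
  recurse(1L, 1L, 0, 1L)
  best
}

# Local DTW cost matrix between two loops already in a common frame:
# RMS of the four backbone-atom distances per residue pair (recomputed
# here from the raw arrays, not via the package internals).
oracle_cost_matrix <- function(xa, xb) {
  n <- dim(xa)[1]; m <- dim(xb)[1]
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- sqrt(mean(vapply(1:4, function(k) {
        sum((xa[i, k, ] - xb[j, k, ])^2)
      }, numeric(1))))
    }
  }
  out
}

# Textbook DBSCAN (visited-set seed expansion) written independently of
# the package's flood-fill implementation. Returns labels (0 = noise).
reference_dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  labels <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  region <- function(p) which(d[p, ] <= eps)
  for (p in seq_len(n)) {
    if (visited[p]) next
    visited[p] <- TRUE
    nb <- region(p)
    if (length(nb) < min_pts) {
      labels[p] <- 0L
      next
    }
    cl <- cl + 1L
    labels[p] <- cl
    seeds <- setdiff(nb, p)
    while (length(seeds)) {
      q <- seeds[1]; seeds <- seeds[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- region(q)
        if (length(nbq) >= min_pts) seeds <- union(seeds, nbq)
      }
      if (is.na(labels[q]) || labels[q] == 0L) labels[q] <- cl
    }
  }
  labels
}

# Partition of a label vector as a canonical set of member-index sets.
partition_of <- function(labels, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(labels) else subset
  sets <- lapply(split(idx, labels[idx]), sort)
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# A random proper rotation matrix (Rodrigues form).
random_rotation <- function() {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

# Independent interior-angle oracle: acos of the normalized dot product.
oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Independent torsion oracle built on projections onto the plane normal
# to the central bond (different construction from the atan2-of-normals
# formula used in the package).
oracle_torsion <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  ang <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
  s <- sign(sum(cross3(u, w) * b))
  # IUPAC convention: cis = 0, sign from the right-hand rule about b
  ang * 180 / pi * ifelse(s == 0, 1, s)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# A clean synthetic chain (as parsed from disk) for filter-injection
# tests: one alpha chain containing a CDR1 loop.
clean_chain <- function(seed = 1) {
  tpl <- loop_template(8, phi = -57, psi = -47, cdr = "CDR1",
                       sequence = "ACDEFGHI")
  l <- make_loop(tpl, noise_sd = 0, seed = seed, cdr_type = "a1",
                 source = "fix1:A")
  path <- tempfile(fileext = ".pdb")
  write_loops_pdb(l, path, chains = "A")
  on.exit(unlink(path))
  read_structure(path, chain_info = data.frame(
    chain = "A", receptor_class = "TCR", chain_type = "alpha"))[[1]]
}
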