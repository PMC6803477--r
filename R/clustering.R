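# Pairwise DTW distance matrices, DBSCAN on precomputed distances,
# canonical/pseudo-class designation, class naming and cross-catalog
# matching.

#' Pairwise DTW distance matrix over a loop set
#'
#' @param loops List of `cdr_loop` objects of one CDR type, or (in joint
#'   mode) of a TCR/antibody equivalent pair (a1/L1, a2/L2, a3/L3, b1/H1,
#'   b2/H2, b3/H3).
#' @param mode `"tcr_only"` or `"joint"`.
#' @return A `dist_matrix`: list with `ids` (loop identifiers, input
#'   order) and `values` (symmetric matrix of DTW scores in Angstrom,
#'   zero diagonal).
#' @export
pairwise_matrix <- function(loops, mode = c("tcr_only", "joint")) {
  mode <- match.arg(mode)
  if (length(loops) < 2) stop("need at least 2 loops")
  types <- vapply(loops, function(l) l$cdr_type, character(1))
  if (!cdr_compatible(types, mode)) {
    stop("incompatible CDR types for mode ", mode, ": ",
         paste(unique(types), collapse = ", "))
  }
  ids <- make.unique(vapply(loops, loop_id, character(1)), sep = "#")
  n <- length(loops)
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- dtw_distance(loops[[i]], loops[[j]])
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  structure(list(ids = ids, values = values), class = "dist_matrix")
}

#' DBSCAN on a precomputed distance matrix
#'
#' Deterministic density-based clustering. A core point has at least
#' `min_pts` neighbours within `eps` (itself included). Clusters are the
#' connected components of core points at distance `eps` or less; border
#' points (non-core points within `eps` of a core point) are assigned to
#' the cluster of their first core neighbour in input order. Everything
#' else is noise.
#'
#' @param dmat A `dist_matrix` or a plain symmetric matrix.
#' @param eps Neighbourhood radius in Angstrom.
#' @param min_pts Minimum neighbourhood size for a core point (default 5).
#' @return List with `labels` (integer vector, 0 = noise, clusters
#'   numbered by first appearance in input order) and `core` (logical).
#' @export
dbscan_precomputed <- function(dmat, eps, min_pts = 5) {
  values <- if (inherits(dmat, "dist_matrix")) dmat$values else as.matrix(dmat)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(values)
  nb <- values <= eps
  core <- unname(rowSums(nb) >= min_pts)
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    # flood-fill over core points
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      nbrs <- which(nb[p, ] & core & labels == 0L)
      labels[nbrs] <- cl
      queue <- c(queue, nbrs)
    }
  }
  # border points: first core neighbour in input order decides
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- which(nb[i, ] & core)
    if (length(cn)) labels[i] <- labels[cn[1]]
  }
  list(labels = labels, core = core)
}

unique_sequences <- function(loops) unique(toupper(
  vapply(loops, function(l) l$sequence, character(1))))

#' Designate DBSCAN clusters as canonical classes, pseudo-classes or
#' unclustered
#'
#' TCR-only mode: a cluster with at least `min_structures` members and at
#' least two unique CDR sequences is a canonical class; with at least
#' `min_structures` members but a single unique sequence it is a
#' pseudo-class (its name carries a trailing `*`). Joint (TCR + antibody)
#' mode: a cluster is valid only with at least `min_unique_joint` unique
#' sequences. Members of demoted clusters are moved to the unclustered
#' set. Class names follow the field convention (see [name_classes()]).
#'
#' @param labels Integer labels from [dbscan_precomputed()].
#' @param loops The clustered loops, in matrix order.
#' @param dmat The `dist_matrix` used for clustering (for representatives).
#' @param mode `"tcr_only"` or `"joint"`.
#' @param eps The eps used, recorded in the catalog.
#' @param min_structures Minimum cluster size (default 5).
#' @param min_unique_tcr Minimum unique sequences for a TCR-only canonical
#'   class (default 2).
#' @param min_unique_joint Minimum unique sequences for a joint-mode class
#'   (default 6).
#' @return A `class_catalog`.
#' @export
designate <- function(labels, loops, dmat, mode = c("tcr_only", "joint"),
                      eps = NA_real_, min_structures = 5,
                      min_unique_tcr = 2, min_unique_joint = 6) {
  mode <- match.arg(mode)
  ids <- if (inherits(dmat, "dist_matrix")) dmat$ids else
    make.unique(vapply(loops, loop_id, character(1)), sep = "#")
  classes <- list()
  unclustered <- ids[labels == 0L]
  for (cl in sort(unique(labels[labels > 0L]))) {
    members <- ids[labels == cl]
    mem_loops <- loops[labels == cl]
    useq <- unique_sequences(mem_loops)
    kind <- NA_character_
    if (mode == "tcr_only") {
      if (length(members) >= min_structures && length(useq) >= min_unique_tcr) {
        kind <- "canonical"
      } else if (length(members) >= min_structures && length(useq) == 1) {
        kind <- "pseudo"
      }
    } else {
      if (length(useq) >= min_unique_joint) kind <- "canonical"
    }
    if (is.na(kind)) {
      unclustered <- c(unclustered, members)
      next
    }
    classes[[length(classes) + 1L]] <- list(
      name = NA_character_,
      members = members,
      sequences = useq,
      n_unique = length(useq),
      representative = representative(members, dmat),
      kind = kind,
      cdr_types = sort(unique(vapply(mem_loops, function(l) l$cdr_type,
                                     character(1)))),
      lengths = sort(unique(nchar(vapply(mem_loops, function(l) l$sequence,
                                         character(1))))))
  }
  catalog <- structure(list(classes = classes,
                            unclustered = ids[ids %in% unclustered],
                            mode = mode, eps = eps),
                       class = "class_catalog")
  name_classes(catalog)
}

#' Assign nomenclature-compliant class names
#'
#' Classes are grouped by CDR type label(s) and observed length set; within
#' a group they are ordered by unique-sequence count (descending; ties by
#' member count, then by lexicographically smallest member id) and
#' lettered A, B, C, ... The name is
#' `<type(s)>-<length(s)>-<letter>`, e.g. `α1-6-B` for the length-6 CDRα1
#' class with the second-largest number of unique sequences, or
#' `α1,L1-11,12-A` for a joint class; pseudo-class names end in `*`.
#'
#' @param catalog A `class_catalog`.
#' @return The catalog with `name` filled on every class.
#' @export
name_classes <- function(catalog) {
  if (!length(catalog$classes)) return(catalog)
  info <- lapply(catalog$classes, function(cl) {
    types <- cl$cdr_types[order(match(cl$cdr_types, CDR_TYPE_ORDER))]
    list(stem = paste0(paste(vapply(types, cdr_display, character(1)),
                             collapse = ","), "-",
                       paste(cl$lengths, collapse = ",")),
         n_unique = cl$n_unique, n_members = length(cl$members),
         first_id = min(cl$members))
  })
  stems <- vapply(info, function(x) x$stem, character(1))
  for (stem in unique(stems)) {
    idx <- which(stems == stem)
    ord <- idx[order(-vapply(info[idx], function(x) x$n_unique, numeric(1)),
                     -vapply(info[idx], function(x) x$n_members, numeric(1)),
                     vapply(info[idx], function(x) x$first_id, character(1)))]
    for (k in seq_along(ord)) {
      i <- ord[k]
      suffix <- if (catalog$classes[[i]]$kind == "pseudo") "*" else ""
      catalog$classes[[i]]$name <- paste0(stem, "-", LETTERS[k], suffix)
    }
  }
  catalog
}

#' @export
print.class_catalog <- function(x, ...) {
  cat(sprintf("<class_catalog> mode %s, eps %s: %d classes, %d unclustered\n",
              x$mode, format(x$eps), length(x$classes),
              length(x$unclustered)))
  for (cl in x$classes) {
    cat(sprintf("  %-14s %-9s %3d members, %3d unique seqs, rep %s\n",
                cl$name, cl$kind, length(cl$members), cl$n_unique,
                cl$representative))
  }
  invisible(x)
}

#' Medoid representative of a class
#'
#' The member minimizing the sum of distances to all other members; ties
#' are broken by the lexicographically smallest id.
#'
#' @param members Character vector of member loop ids.
#' @param dmat The `dist_matrix` covering them.
#' @return The representative loop id.
#' @export
representative <- function(members, dmat) {
  if (!length(members)) stop("empty class")
  if (length(members) == 1) return(members)
  values <- if (inherits(dmat, "dist_matrix")) dmat$values else as.matrix(dmat)
  members <- sort(members)
  sums <- rowSums(values[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' Membership table of a catalog
#'
#' @param catalog A `class_catalog`.
#' @return Tibble: loop_id, class (or `"unclustered"`), kind,
#'   representative flag.
#' @export
catalog_membership <- function(catalog) {
  rows <- lapply(catalog$classes, function(cl) {
    tibble::tibble(loop_id = cl$members, class = cl$name, kind = cl$kind,
                   is_representative = cl$members == cl$representative)
  })
  rows[[length(rows) + 1L]] <- tibble::tibble(
    loop_id = catalog$unclustered, class = "unclustered",
    kind = "unclustered", is_representative = FALSE)
  do.call(rbind, rows)
}

# class label ("unclustered" or class name) per loop id
catalog_label_of <- function(catalog, ids) {
  mem <- catalog_membership(catalog)
  mem$class[match(ids, mem$loop_id)]
}

#' Match classes across two catalogs
#'
#' Two classes are analogous if they share a member (same structure:chain
#' loop id), or — when the foreign representative was filtered out of the
#' other set — via a sequence-identical proxy: a member of one class whose
#' CDR sequence equals the other class's representative sequence and whose
#' backbone RMSD to that representative is at most `rmsd_max`.
#'
#' @param catalog_a,catalog_b `class_catalog` objects.
#' @param loops_a,loops_b The loop sets behind each catalog.
#' @param rmsd_max Proxy RMSD cutoff in Angstrom (default 1.0).
#' @param fit_on Superposition set for the proxy RMSD (default `"loop"`).
#' @return Tibble: class_a, class_b, evidence
#'   (`shared_member` or `sequence_proxy`).
#' @export
match_catalogs <- function(catalog_a, catalog_b, loops_a, loops_b,
                           rmsd_max = 1.0, fit_on = "loop") {
  by_id <- function(loops) {
    ids <- make.unique(vapply(loops, loop_id, character(1)), sep = "#")
    stats::setNames(loops, ids)
  }
  la <- by_id(loops_a); lb <- by_id(loops_b)
  out <- list()
  for (ca in catalog_a$classes) {
    for (cb in catalog_b$classes) {
      shared <- intersect(ca$members, cb$members)
      if (length(shared)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          class_a = ca$name, class_b = cb$name, evidence = "shared_member")
        next
      }
      # proxy: a member of a sequence-identical to b's representative
      rep_b <- lb[[cb$representative]]
      hit <- FALSE
      if (!is.null(rep_b)) {
        for (mid in ca$members) {
          ml <- la[[mid]]
          if (is.null(ml) || toupper(ml$sequence) != toupper(rep_b$sequence))
            next
          if (backbone_rmsd(ml, rep_b, fit_on = fit_on) <= rmsd_max) {
            hit <- TRUE
            break
          }
        }
      }
      if (!hit && !is.null(la[[ca$representative]])) {
        rep_a <- la[[ca$representative]]
        for (mid in cb$members) {
          ml <- lb[[mid]]
          if (is.null(ml) || toupper(ml$sequence) != toupper(rep_a$sequence))
            next
          if (backbone_rmsd(ml, rep_a, fit_on = fit_on) <= rmsd_max) {
            hit <- TRUE
            break
          }
        }
      }
      if (hit) {
        out[[length(out) + 1L]] <- tibble::tibble(
          class_a = ca$name, class_b = cb$name, evidence = "sequence_proxy")
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(class_a = character(), class_b = character(),
                          evidence = character()))
  }
  do.call(rbind, out)
}

#' Cluster a loop set into a class catalog
#'
#' Convenience wrapper: pairwise DTW matrix, DBSCAN, designation and
#' naming in one call.
#'
#' @param loops List of `cdr_loop` objects.
#' @param eps DBSCAN radius in Angstrom (1.0 for TCR-only clustering; the
#'   joint-mode per-CDR defaults are in [run_config()]).
#' @param mode `"tcr_only"` or `"joint"`.
#' @param min_structures,min_unique_tcr,min_unique_joint Designation rules,
#'   see [designate()].
#' @param min_pts DBSCAN core-point threshold (defaults to
#'   `min_structures`).
#' @return List with `catalog` (a `class_catalog`), `matrix`
#'   (`dist_matrix`) and `labels`.
#' @export
cluster_loops <- function(loops, eps = 1.0, mode = c("tcr_only", "joint"),
                          min_structures = 5, min_unique_tcr = 2,
                          min_unique_joint = 6, min_pts = min_structures) {
  mode <- match.arg(mode)
  dmat <- pairwise_matrix(loops, mode = mode)
  db <- dbscan_precomputed(dmat, eps = eps, min_pts = min_pts)
  catalog <- designate(db$labels, loops, dmat, mode = mode, eps = eps,
                       min_structures = min_structures,
                       min_unique_tcr = min_unique_tcr,
                       min_unique_joint = min_unique_joint)
  list(catalog = catalog, matrix = dmat, labels = db$labels)
}

#' Serialize a class catalog to JSON
#' @param catalog A `class_catalog`.
#' @param path Output file.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(list(
    mode = catalog$mode, eps = catalog$eps,
    classes = lapply(catalog$classes, function(cl) {
      cl[c("name", "members", "sequences", "n_unique", "representative",
           "kind", "cdr_types", "lengths")]
    }),
    unclustered = catalog$unclustered
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a class catalog written by [write_catalog_json()]
#' @param path Input file.
#' @export
read_catalog_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(list(
    classes = lapply(x$classes, function(cl) {
      list(name = cl$name, members = unlist(cl$members),
           sequences = unlist(cl$sequences), n_unique = cl$n_unique,
           representative = cl$representative, kind = cl$kind,
           cdr_types = unlist(cl$cdr_types), lengths = unlist(cl$lengths))
    }),
    unclustered = as.character(unlist(x$unclustered)),
    mode = x$mode,
    eps = if (is.null(x$eps)) NA_real_ else x$eps
  ), class = "class_catalog")
}
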