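# Conformational variability of sequence-identical CDR loops:
# multi-cluster occupancy and maximum pairwise backbone RMSD.

#' Group loops by identical CDR sequence
#'
#' Loops of the same CDR type sharing an identical sequence
#' (case-insensitive, anchors excluded) form a group; only groups with at
#' least two member structures are returned.
#'
#' @param loops List of `cdr_loop` objects.
#' @return Tibble: cdr_type, sequence, n_structures, loop_ids (list
#'   column), member_index (list column of indices into `loops`).
#' @export
group_by_sequence <- function(loops) {
  if (!length(loops)) {
    return(tibble::tibble(cdr_type = character(), sequence = character(),
                          n_structures = integer(), loop_ids = list(),
                          member_index = list()))
  }
  ids <- make.unique(vapply(loops, loop_id, character(1)), sep = "#")
  key <- paste(vapply(loops, function(l) l$cdr_type, character(1)),
               toupper(vapply(loops, function(l) l$sequence, character(1))),
               sep = "|")
  rows <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cdr_type = parts[1], sequence = parts[2],
      n_structures = length(idx),
      loop_ids = list(ids[idx]), member_index = list(idx))
  }
  if (!length(rows)) {
    return(tibble::tibble(cdr_type = character(), sequence = character(),
                          n_structures = integer(), loop_ids = list(),
                          member_index = list()))
  }
  do.call(rbind, rows)
}

#' Fraction of sequence-identical groups spanning multiple clusters
#'
#' For each group of sequence-identical loops, counts the distinct
#' cluster labels its members occupy in the catalog (`"unclustered"`
#' counts as a label) and reports the fraction of groups occupying more
#' than one.
#'
#' @param groups Output of [group_by_sequence()].
#' @param catalog A `class_catalog` covering the grouped loops.
#' @return List with `fraction` (of groups that are multi-cluster),
#'   `n_groups`, `n_multi` and `per_group` (tibble with `n_clusters`,
#'   `clusters` and `multi_cluster` columns added).
#' @export
multi_cluster_fraction <- function(groups, catalog) {
  if (!nrow(groups)) {
    return(list(fraction = NA_real_, n_groups = 0L, n_multi = 0L,
                per_group = groups))
  }
  occ <- lapply(groups$loop_ids, function(ids) {
    sort(unique(catalog_label_of(catalog, ids)))
  })
  groups$clusters <- vapply(occ, paste, character(1), collapse = ";")
  groups$n_clusters <- lengths(occ)
  groups$multi_cluster <- groups$n_clusters > 1L
  list(fraction = mean(groups$multi_cluster),
       n_groups = nrow(groups),
       n_multi = sum(groups$multi_cluster),
       per_group = groups)
}

#' Maximum pairwise backbone RMSD within a sequence-identical group
#'
#' All members share one sequence, hence one length; the RMSD of every
#' pair is computed with a loop-backbone fit and the maximum returned.
#'
#' @param member_index Integer indices of the group members in `loops`
#'   (or one row of the [group_by_sequence()] tibble).
#' @param loops The full loop list.
#' @param fit_on Superposition set for [backbone_rmsd()] (default
#'   `"loop"`, comparing loop conformations irrespective of anchors).
#' @return Maximum pairwise RMSD in Angstrom.
#' @export
max_pairwise_rmsd <- function(member_index, loops, fit_on = "loop") {
  if (is.data.frame(member_index)) {
    member_index <- member_index$member_index[[1]]
  }
  if (is.list(member_index)) member_index <- member_index[[1]]
  stopifnot(length(member_index) >= 2)
  members <- loops[member_index]
  worst <- 0
  for (i in seq_len(length(members) - 1)) {
    for (j in (i + 1):length(members)) {
      worst <- max(worst, backbone_rmsd(members[[i]], members[[j]],
                                        fit_on = fit_on))
    }
  }
  worst
}

#' Conformational-variability summary table
#'
#' One row per sequence-identical group: cluster occupancy and maximum
#' pairwise backbone RMSD, plus a similarity flag at `similar_max`
#' (default: groups whose members stay within 1 Angstrom are "similar").
#'
#' @param loops List of `cdr_loop` objects.
#' @param catalog A `class_catalog` covering them.
#' @param fit_on Superposition set for the RMSDs.
#' @param similar_max Reporting threshold in Angstrom (default 1.0).
#' @return Tibble: cdr_type, sequence, n_structures, n_clusters,
#'   cluster_names, max_rmsd, similar.
#' @export
variability_summary <- function(loops, catalog, fit_on = "loop",
                                similar_max = 1.0) {
  groups <- group_by_sequence(loops)
  if (!nrow(groups)) {
    return(tibble::tibble(cdr_type = character(), sequence = character(),
                          n_structures = integer(), n_clusters = integer(),
                          cluster_names = character(), max_rmsd = numeric(),
                          similar = logical()))
  }
  mc <- multi_cluster_fraction(groups, catalog)$per_group
  mc$max_rmsd <- vapply(mc$member_index, max_pairwise_rmsd, numeric(1),
                        loops = loops, fit_on = fit_on)
  tibble::tibble(cdr_type = mc$cdr_type, sequence = mc$sequence,
                 n_structures = mc$n_structures, n_clusters = mc$n_clusters,
                 cluster_names = mc$clusters, max_rmsd = mc$max_rmsd,
                 similar = mc$max_rmsd < similar_max)
}
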