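# One-hot encoding + PCA of CDR sequences and position frequency matrices
# with hydrophobicity classes.

# Default WebLogo-style hydrophobicity palette classes.
HYDROPATHY_CLASS <- c(
  R = "hydrophilic", K = "hydrophilic", D = "hydrophilic",
  E = "hydrophilic", N = "hydrophilic", Q = "hydrophilic",
  S = "neutral", G = "neutral", H = "neutral", T = "neutral",
  A = "neutral", P = "neutral",
  Y = "hydrophobic", V = "hydrophobic", M = "hydrophobic",
  C = "hydrophobic", L = "hydrophobic", F = "hydrophobic",
  I = "hydrophobic", W = "hydrophobic")

#' One-hot encode CDR sequences by IMGT position
#'
#' Each feature is a (position, residue) indicator; sequences of
#' different lengths share the IMGT frame (a gap at a position simply
#' carries no feature), so every row sums to its sequence length.
#'
#' @param sequences Character vector of CDR sequences.
#' @param cdr CDR window (`"CDR1"`/`"CDR2"`/`"CDR3"` or a type label).
#' @return 0/1 matrix, rows = sequences, columns named `"<pos>:<aa>"`.
#' @export
one_hot_matrix <- function(sequences, cdr) {
  cdr_win <- normalize_cdr(cdr)
  feats <- lapply(sequences, function(s) {
    aa <- split_seq(s)
    paste0(imgt_positions(cdr_win, length(aa)), ":", aa)
  })
  cols <- unique(unlist(feats))
  cols <- cols[order(imgt_key(sub(":.*$", "", cols)), sub("^.*:", "", cols))]
  m <- matrix(0L, length(sequences), length(cols),
              dimnames = list(sequences, cols))
  for (i in seq_along(feats)) m[i, feats[[i]]] <- 1L
  m
}

#' PCA of one-hot encoded CDR sequences
#'
#' Mean-centers the one-hot matrix and decomposes its covariance
#' (eigen-decomposition via `prcomp`). Components are ordered by variance
#' and sign-fixed so the largest-magnitude loading of each component is
#' positive; duplicated sequences map to identical coordinates.
#'
#' @param sequences Character vector of CDR sequences (>= 3 distinct).
#' @param groups Group labels (e.g. `"TCR"` / `"antibody"`), recycled if
#'   scalar.
#' @param cdr CDR window or type label.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (tibble: sequence, group, PC1..),
#'   `explained_variance` (per-component variances, all components) and
#'   `loadings`.
#' @export
one_hot_pca <- function(sequences, groups, cdr, n_components = 2) {
  if (length(groups) == 1) groups <- rep(groups, length(sequences))
  stopifnot(length(groups) == length(sequences))
  if (length(unique(toupper(sequences))) < 3) {
    stop("need at least 3 distinct sequences")
  }
  m <- one_hot_matrix(sequences, cdr)
  if (all(apply(m, 2, stats::var) == 0)) {
    stop("zero variance: all sequences identical")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- tibble::as_tibble(scores[, seq_len(k), drop = FALSE])
  out <- tibble::add_column(out, sequence = sequences, group = groups,
                            .before = 1)
  list(scores = out, explained_variance = pc$sdev^2,
       loadings = rot[, seq_len(k), drop = FALSE])
}

#' Position frequency matrix of a sequence set
#'
#' Per-IMGT-position residue frequencies over the unique sequences, with
#' the hydrophobicity class of each residue (hydrophilic R/K/D/E/N/Q,
#' neutral S/G/H/T/A/P, hydrophobic Y/V/M/C/L/F/I/W). Frequencies at each
#' position sum to 1 over the residues observed there.
#'
#' @param sequences Character vector of CDR sequences.
#' @param cdr CDR window or type label.
#' @return Tibble: position, residue, frequency, hydropathy.
#' @export
frequency_matrix <- function(sequences, cdr) {
  if (!length(sequences)) stop("empty sequence set")
  cdr_win <- normalize_cdr(cdr)
  sequences <- unique(toupper(sequences))
  long <- do.call(rbind, lapply(sequences, function(s) {
    aa <- split_seq(s)
    data.frame(position = imgt_positions(cdr_win, length(aa)), residue = aa)
  }))
  per_pos <- table(long$position)
  counts <- stats::aggregate(list(n = rep(1L, nrow(long))),
                             long[c("position", "residue")], sum)
  counts$frequency <- counts$n / as.numeric(per_pos[counts$position])
  counts <- counts[order(imgt_key(counts$position), counts$residue), ]
  tibble::tibble(position = counts$position, residue = counts$residue,
                 frequency = counts$frequency,
                 hydropathy = unname(HYDROPATHY_CLASS[counts$residue]))
}
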