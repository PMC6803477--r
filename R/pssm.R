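# Per-class position-specific scoring matrices, sequence scoring and
# canonical-form prediction, leave-one-out cross-validation, blind-test
# correctness and repertoire sequence filtering.
#
# The score of amino acid a at IMGT position i is
#   s(a, i) = log2(p_{a,i} / b_a),  b_a = 0.05 for every residue,
# with p_{a,i} estimated from the unique sequences of the class. A query
# of length l scores P_c = sum_i s(a, i); a pair (i, a) never observed in
# the class contributes -1.

PSSM_BACKGROUND <- 0.05

split_seq <- function(seq) strsplit(toupper(seq), "")[[1]]

#' Build a position-specific scoring matrix for one canonical class
#'
#' Residue probabilities are estimated per IMGT position over the
#' *unique* sequences of the class (duplicates carry no extra weight);
#' positions are labelled by [imgt_positions()] from each sequence's
#' length, so classes mixing lengths share the IMGT frame. Scores are
#' log2 odds against a flat background of 0.05 per residue.
#'
#' @param sequences Character vector of CDR sequences (anchors excluded).
#' @param class_name Name of the class the PSSM models.
#' @param cdr `"CDR1"`, `"CDR2"` or `"CDR3"` (sets the IMGT frame). Can
#'   also be a CDR type label such as `"a3"`.
#' @return A `cdr_pssm`: list with `class_name`, `cdr`, `positions`,
#'   `scores` (position x residue matrix, NA where unobserved),
#'   `probs` (same shape), `lengths`, `n_training`.
#' @export
build_pssm <- function(sequences, class_name, cdr) {
  if (!length(sequences)) stop("empty training set")
  cdr_win <- normalize_cdr(cdr)
  sequences <- unique(toupper(sequences))
  counts <- list()
  cover <- list()
  for (s in sequences) {
    aa <- split_seq(s)
    pos <- imgt_positions(cdr_win, length(aa))
    for (k in seq_along(aa)) {
      key <- pos[k]
      if (is.null(counts[[key]])) {
        counts[[key]] <- stats::setNames(numeric(length(AA20)), AA20)
        cover[[key]] <- 0
      }
      counts[[key]][aa[k]] <- counts[[key]][aa[k]] + 1
      cover[[key]] <- cover[[key]] + 1
    }
  }
  positions <- names(counts)[order(imgt_key(names(counts)))]
  probs <- matrix(NA_real_, length(positions), length(AA20),
                  dimnames = list(positions, AA20))
  for (p in positions) {
    cnt <- counts[[p]]
    probs[p, ] <- ifelse(cnt > 0, cnt / cover[[p]], NA_real_)
  }
  structure(list(class_name = class_name, cdr = cdr_win,
                 positions = positions,
                 scores = log2(probs / PSSM_BACKGROUND),
                 probs = probs,
                 lengths = sort(unique(nchar(sequences))),
                 n_training = length(sequences)),
            class = "cdr_pssm")
}

# "a3"/"H1"/... -> "CDR3"/"CDR1"; passes CDR1/2/3 through.
normalize_cdr <- function(cdr) {
  if (cdr %in% names(CDR_WINDOWS)) return(cdr)
  if (cdr %in% CDR_TYPES) return(paste0("CDR", substr(cdr, 2, 2)))
  stop("unknown CDR specifier: ", cdr)
}

#' @export
print.cdr_pssm <- function(x, ...) {
  cat(sprintf("<cdr_pssm> %s (%s): %d positions, lengths {%s}, %d unique seqs\n",
              x$class_name, x$cdr, length(x$positions),
              paste(x$lengths, collapse = ","), x$n_training))
  invisible(x)
}

#' Score a CDR sequence against a class PSSM
#'
#' Sums the per-position scores over the query's IMGT positions; a
#' position/residue pair never observed in the class contributes exactly
#' -1. A query whose length is not among the class's training lengths is
#' not scoreable and returns NA (the caller skips that class).
#'
#' @param pssm A `cdr_pssm`.
#' @param seq CDR sequence (anchors excluded).
#' @return `P_c` in bits, or NA when the length is not covered.
#' @export
score_sequence <- function(pssm, seq) {
  aa <- split_seq(seq)
  if (!(length(aa) %in% pssm$lengths)) return(NA_real_)
  pos <- imgt_positions(pssm$cdr, length(aa))
  total <- 0
  for (k in seq_along(aa)) {
    s <- if (pos[k] %in% pssm$positions) pssm$scores[pos[k], aa[k]] else NA
    total <- total + if (is.na(s)) -1 else s
  }
  total
}

#' Build PSSMs for every canonical class of a catalog
#'
#' @param catalog A `class_catalog`.
#' @param cdr CDR window of the catalog's loops (e.g. `"CDR1"` or a type
#'   label like `"a1"`).
#' @return Named list of `cdr_pssm`, one per canonical class.
#' @export
build_class_pssms <- function(catalog, cdr) {
  classes <- Filter(function(cl) cl$kind == "canonical", catalog$classes)
  pssms <- lapply(classes, function(cl) build_pssm(cl$sequences, cl$name, cdr))
  stats::setNames(pssms, vapply(classes, function(cl) cl$name, character(1)))
}

#' Predict the canonical class of CDR sequences
#'
#' An exact sequence match to any class (canonical or pseudo) takes
#' precedence over PSSM scoring — a pseudo-class can *only* be assigned
#' this way. Otherwise the query is scored against every PSSM covering
#' its length and assigned to the best-scoring class if `P_c > 1`
#' (CDRa3: `P_c >= l`, the query length); ties are broken by larger
#' training count, then name order. Below-threshold or length-uncovered
#' queries are left unassigned.
#'
#' @param sequences Character vector of CDR sequences.
#' @param cdr_type CDR type of the queries (e.g. `"a1"`); the a3-specific
#'   threshold applies when this is `"a3"`.
#' @param catalog The `class_catalog` the PSSMs were built from (used for
#'   exact-sequence matching); may be NULL to disable exact matching.
#' @param pssms Named list of `cdr_pssm` from [build_class_pssms()].
#' @param exact_match Allow exact-sequence short-circuit (default TRUE).
#' @return Tibble: sequence, cdr, assigned (class name or NA), score
#'   (`P_c` in bits, NA for exact matches and unscoreable queries),
#'   rationale (`exact_sequence`, `pssm`, `below_threshold`,
#'   `no_length_match`).
#' @export
predict_canonical <- function(sequences, cdr_type, catalog = NULL, pssms,
                              exact_match = TRUE) {
  exact_lookup <- NULL
  if (exact_match && !is.null(catalog) && length(catalog$classes)) {
    ord <- order(vapply(catalog$classes, function(cl) cl$kind != "canonical",
                        logical(1)),
                 -vapply(catalog$classes, function(cl) cl$n_unique, numeric(1)),
                 vapply(catalog$classes, function(cl) cl$name, character(1)))
    exact_lookup <- list()
    for (cl in catalog$classes[ord]) {
      for (s in toupper(cl$sequences)) {
        if (is.null(exact_lookup[[s]])) exact_lookup[[s]] <- cl$name
      }
    }
  }
  rows <- lapply(sequences, function(seq) {
    squery <- toupper(seq)
    if (!is.null(exact_lookup) && !is.null(exact_lookup[[squery]])) {
      return(tibble::tibble(sequence = seq, cdr = cdr_type,
                            assigned = exact_lookup[[squery]], score = NA_real_,
                            rationale = "exact_sequence"))
    }
    scores <- vapply(pssms, score_sequence, numeric(1), seq = squery)
    ok <- !is.na(scores)
    if (!any(ok)) {
      return(tibble::tibble(sequence = seq, cdr = cdr_type,
                            assigned = NA_character_, score = NA_real_,
                            rationale = "no_length_match"))
    }
    n_train <- vapply(pssms, function(p) p$n_training, numeric(1))
    cand <- which(ok)
    cand <- cand[order(-scores[cand], -n_train[cand], names(pssms)[cand])]
    best <- cand[1]
    p_c <- unname(scores[best])
    l <- nchar(squery)
    pass <- if (identical(cdr_type, "a3")) p_c >= l else p_c > 1
    tibble::tibble(sequence = seq, cdr = cdr_type,
                   assigned = if (pass) names(pssms)[best] else NA_character_,
                   score = p_c,
                   rationale = if (pass) "pssm" else "below_threshold")
  })
  do.call(rbind, rows)
}

#' Leave-one-out cross-validation of the PSSM predictor
#'
#' Each unique sequence is held out in turn; the PSSM of its class is
#' rebuilt without it and the predictor is applied. A prediction is a
#' true positive when a class-member sequence is assigned to its own
#' class, a false positive when any sequence is assigned to a different
#' class (including unclustered sequences gaining an assignment), a true
#' negative when an unclustered sequence stays unassigned, and a false
#' negative when a class-member sequence stays unassigned.
#'
#' @param data Data frame with columns `sequence` and `label` (class name
#'   or `"unclustered"`); sequences must be unique.
#' @param cdr_type CDR type label of the sequences (e.g. `"a1"`).
#' @param exact_match Passed to [predict_canonical()].
#' @return List with `counts` (TP, FP, TN, FN), `accuracy`
#'   ((TP + TN) / total) and `predictions` (per-sequence tibble).
#' @export
loocv <- function(data, cdr_type, exact_match = TRUE) {
  data <- as.data.frame(data)
  stopifnot(all(c("sequence", "label") %in% names(data)),
            !anyDuplicated(toupper(data$sequence)))
  cdr_win <- normalize_cdr(cdr_type)
  n <- nrow(data)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    class_names <- setdiff(unique(train$label), "unclustered")
    pssms <- stats::setNames(lapply(class_names, function(cn) {
      build_pssm(train$sequence[train$label == cn], cn, cdr_win)
    }), class_names)
    catalog <- structure(list(classes = lapply(class_names, function(cn) {
      list(name = cn, sequences = unique(toupper(
        train$sequence[train$label == cn])),
        n_unique = length(unique(toupper(train$sequence[train$label == cn]))),
        kind = "canonical")
    }), unclustered = character(), mode = "tcr_only", eps = NA_real_),
    class = "class_catalog")
    pred <- predict_canonical(data$sequence[i], cdr_type, catalog, pssms,
                              exact_match = exact_match)
    truth <- data$label[i]
    outcome <- if (truth == "unclustered") {
      if (is.na(pred$assigned)) "TN" else "FP"
    } else {
      if (is.na(pred$assigned)) "FN"
      else if (pred$assigned == truth) "TP" else "FP"
    }
    rows[[i]] <- tibble::tibble(sequence = data$sequence[i], truth = truth,
                                assigned = pred$assigned, score = pred$score,
                                outcome = outcome)
  }
  predictions <- do.call(rbind, rows)
  counts <- c(TP = sum(predictions$outcome == "TP"),
              FP = sum(predictions$outcome == "FP"),
              TN = sum(predictions$outcome == "TN"),
              FN = sum(predictions$outcome == "FN"))
  list(counts = counts,
       accuracy = (counts[["TP"]] + counts[["TN"]]) / n,
       predictions = predictions)
}

#' Is a class assignment structurally correct for a known native loop?
#'
#' A prediction counts as correct when the backbone RMSD between the
#' native CDR structure and *any* member of the assigned class is at most
#' `rmsd_max` (inclusive).
#'
#' @param native The native `cdr_loop`.
#' @param members List of `cdr_loop` members of the assigned class.
#' @param rmsd_max Cutoff in Angstrom (default 1.0).
#' @param fit_on Superposition set for [backbone_rmsd()] (default
#'   `"loop"`).
#' @return TRUE/FALSE, or NA when the class has no comparable (equal
#'   length) member.
#' @export
blind_correct <- function(native, members, rmsd_max = 1.0, fit_on = "loop") {
  if (!length(members)) return(NA)
  rmsds <- vapply(members, function(m) {
    if (nchar(m$sequence) != nchar(native$sequence)) return(NA_real_)
    backbone_rmsd(native, m, fit_on = fit_on)
  }, numeric(1))
  if (all(is.na(rmsds))) return(NA)
  min(rmsds, na.rm = TRUE) <= rmsd_max
}

#' Filter annotated repertoire sequences before prediction
#'
#' Keeps records with a productive CDR3 rearrangement, CDR1 and CDR2 of at
#' least five residues and CDR3 of at least eight residues (all bounds
#' inclusive). Records missing a CDR field are rejected.
#'
#' @param records Data frame with columns `cdr1`, `cdr2`, `cdr3`,
#'   `productive` (logical).
#' @param min_cdr12 Minimum CDR1/CDR2 length (default 5).
#' @param min_cdr3 Minimum CDR3 length (default 8).
#' @return List with `kept` (tibble), `rejected` (tibble with a `reason`
#'   column) and `tally` (named counts per reason).
#' @export
ngs_filter <- function(records, min_cdr12 = 5, min_cdr3 = 8) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("cdr1", "cdr2", "cdr3", "productive") %in% names(records)))
  missing_field <- is.na(records$cdr1) | is.na(records$cdr2) |
    is.na(records$cdr3) | !nzchar(records$cdr1) | !nzchar(records$cdr2) |
    !nzchar(records$cdr3)
  reason <- rep(NA_character_, nrow(records))
  reason[missing_field] <- "missing_cdr"
  unprod <- !missing_field & !records$productive
  reason[unprod] <- "unproductive"
  todo <- is.na(reason)
  reason[todo & nchar(records$cdr1) < min_cdr12] <- "cdr1_short"
  todo <- is.na(reason)
  reason[todo & nchar(records$cdr2) < min_cdr12] <- "cdr2_short"
  todo <- is.na(reason)
  reason[todo & nchar(records$cdr3) < min_cdr3] <- "cdr3_short"
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected,
       tally = c(kept = nrow(kept), table(rejected$reason)))
}

#' Serialize PSSMs to JSON
#' @param pssms Named list of `cdr_pssm`.
#' @param path Output file.
#' @export
write_pssms_json <- function(pssms, path) {
  jsonlite::write_json(lapply(unname(pssms), function(p) {
    obs <- which(!is.na(p$scores), arr.ind = TRUE)
    list(class_name = p$class_name, cdr = p$cdr, positions = p$positions,
         lengths = p$lengths, n_training = p$n_training,
         entries = data.frame(
           position = rownames(p$scores)[obs[, 1]],
           residue = colnames(p$scores)[obs[, 2]],
           prob = p$probs[obs], score = p$scores[obs]))
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read PSSMs written by [write_pssms_json()]
#' @param path Input file.
#' @export
read_pssms_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pssms <- lapply(x, function(p) {
    positions <- unlist(p$positions)
    probs <- matrix(NA_real_, length(positions), length(AA20),
                    dimnames = list(positions, AA20))
    for (e in p$entries) probs[e$position, e$residue] <- e$prob
    structure(list(class_name = p$class_name, cdr = p$cdr,
                   positions = positions,
                   scores = log2(probs / PSSM_BACKGROUND), probs = probs,
                   lengths = unlist(p$lengths), n_training = p$n_training),
              class = "cdr_pssm")
  })
  stats::setNames(pssms, vapply(pssms, function(p) p$class_name, character(1)))
}
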