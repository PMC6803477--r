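# Parsing IMGT-renumbered structures and extracting quality-filtered CDR
# loops with their anchor residues.

# REMARK 2 resolution from a PDB header; NA when absent or not applicable.
read_pdb_resolution <- function(path) {
  head_lines <- readLines(path, n = 300L, warn = FALSE)
  rl <- grep("^REMARK   2 RESOLUTION", head_lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  tail_str <- substring(rl[1], 23)
  m <- regmatches(tail_str, regexpr("[0-9]+\\.?[0-9]*", tail_str))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

# Alt-loc resolution on a bio3d atom table: keep the highest-occupancy
# conformer of each (chain, resno, insert, elety); ties -> first in file.
select_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (dup_key in unique(key[duplicated(key)])) {
    idx <- which(key == dup_key)
    occ <- atoms$o[idx]
    occ[is.na(occ)] <- 1
    keep[idx] <- FALSE
    keep[idx[which.max(occ)]] <- TRUE
  }
  atoms[keep, , drop = FALSE]
}

# (resno, insert) -> IMGT label; PDB insertion letters map to ".1", ".2", ...
embedded_imgt_label <- function(resno, insert) {
  ins <- !is.na(insert) & nzchar(insert)
  ifelse(ins, paste0(resno, ".", match(insert, LETTERS)), as.character(resno))
}

#' Read an IMGT-renumbered structure into chain records
#'
#' Parses a PDB file (via bio3d), keeps protein chains, applies
#' alternate-location selection (highest occupancy, tie broken by file
#' order) and records the REMARK 2 resolution. Residue numbering is taken
#' from the coordinate records themselves (`numbering = "embedded"`, the
#' STCRDab/SAbDab convention) or from a sidecar table mapping author
#' numbering to IMGT positions.
#'
#' @param path PDB file.
#' @param numbering `"embedded"`, or a data frame / TSV path with columns
#'   `chain`, `author_resid`, `author_icode`, `imgt_position`.
#' @param chain_info Optional data frame with columns `chain`,
#'   `receptor_class` (TCR/antibody/nanobody) and `chain_type`
#'   (alpha/beta/heavy/light). Receptor metadata is never inferred from
#'   coordinates.
#' @return List of `receptor_chain` records; chains without any IMGT
#'   mapping are skipped with a warning.
#' @export
read_structure <- function(path, numbering = "embedded", chain_info = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file ", path, ": ",
                             conditionMessage(e)))
  resolution <- read_pdb_resolution(path)
  structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)

  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- select_altloc(atoms)
  atoms$aa1 <- suppressWarnings(bio3d::aa321(atoms$resid))

  sidecar <- NULL
  if (!identical(numbering, "embedded")) {
    sidecar <- if (is.character(numbering)) {
      utils::read.delim(numbering, stringsAsFactors = FALSE,
                        colClasses = "character")
    } else as.data.frame(numbering, stringsAsFactors = FALSE)
    need <- c("chain", "author_resid", "author_icode", "imgt_position")
    if (!all(need %in% names(sidecar))) {
      stop("sidecar numbering table must have columns: ",
           paste(need, collapse = ", "))
    }
  }

  chains <- list()
  for (ch in unique(atoms$chain)) {
    cat_atoms <- atoms[atoms$chain == ch, , drop = FALSE]
    # protein chains only: majority of residues must be standard amino acids
    res_key <- paste(cat_atoms$resno, cat_atoms$insert)
    first_of_res <- !duplicated(res_key)
    if (mean(cat_atoms$aa1[first_of_res] != "X") < 0.5) next

    if (is.null(sidecar)) {
      cat_atoms$imgt <- embedded_imgt_label(cat_atoms$resno, cat_atoms$insert)
    } else {
      sc <- sidecar[sidecar$chain == ch, , drop = FALSE]
      if (!nrow(sc)) {
        warning("chain ", ch, " has no IMGT mapping in sidecar; skipped")
        next
      }
      icode <- ifelse(is.na(cat_atoms$insert), "", cat_atoms$insert)
      sc_icode <- ifelse(is.na(sc$author_icode), "", sc$author_icode)
      idx <- match(paste(cat_atoms$resno, icode),
                   paste(sc$author_resid, sc_icode))
      cat_atoms$imgt <- sc$imgt_position[idx]
      cat_atoms <- cat_atoms[!is.na(cat_atoms$imgt), , drop = FALSE]
      if (!nrow(cat_atoms)) {
        warning("chain ", ch, " has no IMGT mapping in sidecar; skipped")
        next
      }
    }

    # group atoms into residues, preserving file order
    res_key <- paste(cat_atoms$resno, cat_atoms$insert)
    res_start <- which(!duplicated(res_key))
    n_res <- length(res_start)
    pos <- cat_atoms$imgt[res_start]
    aa <- cat_atoms$aa1[res_start]
    xyz <- array(NA_real_, c(n_res, 4L, 3L),
                 dimnames = list(NULL, BB_ATOMS, c("x", "y", "z")))
    bfac <- matrix(NA_real_, n_res, 4L, dimnames = list(NULL, BB_ATOMS))
    res_idx <- cumsum(!duplicated(res_key))
    for (k in seq_len(nrow(cat_atoms))) {
      role <- cat_atoms$elety[k]
      if (role %in% BB_ATOMS) {
        i <- res_idx[k]
        xyz[i, role, ] <- c(cat_atoms$x[k], cat_atoms$y[k], cat_atoms$z[k])
        bfac[i, role] <- cat_atoms$b[k]
      }
    }

    receptor_class <- "TCR"; chain_type <- NA_character_
    if (!is.null(chain_info)) {
      ci <- chain_info[chain_info$chain == ch, , drop = FALSE]
      if (nrow(ci)) {
        receptor_class <- ci$receptor_class[1]
        chain_type <- ci$chain_type[1]
      }
    }

    chains[[length(chains) + 1L]] <- structure(list(
      structure_id = structure_id, chain_id = ch,
      receptor_class = receptor_class, chain_type = chain_type,
      resolution = resolution,
      residues = list(pos = pos, aa = aa, xyz = xyz, bfac = bfac,
                      complete = apply(!is.na(xyz), 1, all))
    ), class = "receptor_chain")
  }
  chains
}

#' @export
print.receptor_chain <- function(x, ...) {
  cat(sprintf("<receptor_chain> %s:%s  %s/%s  %d residues  resolution %.2f A\n",
              x$structure_id, x$chain_id, x$receptor_class,
              x$chain_type, length(x$residues$pos), x$resolution))
  invisible(x)
}

rejection <- function(code, detail, chain = NULL, cdr = NA_character_) {
  structure(list(
    code = code, detail = detail,
    structure_id = if (is.null(chain)) NA_character_ else chain$structure_id,
    chain_id = if (is.null(chain)) NA_character_ else chain$chain_id,
    cdr = cdr), class = "cdr_rejection")
}

#' @export
print.cdr_rejection <- function(x, ...) {
  cat(sprintf("<cdr_rejection> %s:%s %s  %s: %s\n", x$structure_id,
              x$chain_id, x$cdr, x$code, x$detail))
  invisible(x)
}

#' Is an extraction result a rejection?
#' @param x Result of [extract_loop()].
#' @export
is_rejection <- function(x) inherits(x, "cdr_rejection")

#' Extract one CDR loop from a chain, applying the quality filters
#'
#' Selects the IMGT CDR window residues (CDR1 27–38, CDR2 56–65,
#' CDR3 105–117) plus five anchor residues on each side, and accepts the
#' loop only if the structure resolution is at most `resolution_max`, no
#' backbone atom is missing over the loop-plus-anchor span, no backbone
#' B-factor exceeds `bfactor_max`, and every consecutive peptide C–N bond
#' over the span is shorter than `bond_max` (loop continuity). Structures
#' without a recorded resolution (e.g. NMR) fail the resolution filter.
#'
#' @param chain A `receptor_chain`.
#' @param cdr `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param resolution_max Resolution cutoff in Angstrom (default 2.8).
#' @param bfactor_max Backbone B-factor cutoff (default 80).
#' @param bond_max Peptide-bond length cutoff in Angstrom (default 1.37);
#'   bonds at or above this length are chain breaks.
#' @param bound_state Optional metadata flag stored on the loop.
#' @return A `cdr_loop`, or a `cdr_rejection` whose `code` is one of
#'   `RESOLUTION`, `MISSING_BACKBONE`, `HIGH_BFACTOR`, `CHAIN_BREAK`,
#'   `MISSING_ANCHORS`.
#' @export
extract_loop <- function(chain, cdr = c("CDR1", "CDR2", "CDR3"),
                         resolution_max = 2.8, bfactor_max = 80,
                         bond_max = 1.37, bound_state = NA) {
  cdr <- match.arg(cdr)
  res <- chain$residues
  in_window <- !is.na(imgt_window_of(res$pos)) & imgt_window_of(res$pos) == cdr
  idx <- which(in_window)
  if (!length(idx)) {
    return(rejection("MISSING_ANCHORS", paste("no residues in", cdr, "window"),
                     chain, cdr))
  }
  first <- min(idx); last <- max(idx)
  if (first - 5 < 1 || last + 5 > length(res$pos)) {
    return(rejection("MISSING_ANCHORS",
                     "fewer than 5 residues flanking the CDR window",
                     chain, cdr))
  }
  span <- (first - 5):(last + 5)

  if (is.na(chain$resolution) || chain$resolution > resolution_max) {
    return(rejection("RESOLUTION",
                     sprintf("resolution %s > %.1f A",
                             format(chain$resolution), resolution_max),
                     chain, cdr))
  }
  if (!all(res$complete[span])) {
    bad <- span[!res$complete[span]][1]
    return(rejection("MISSING_BACKBONE",
                     paste("missing backbone atom at IMGT", res$pos[bad]),
                     chain, cdr))
  }
  b <- res$bfac[span, , drop = FALSE]
  if (any(b > bfactor_max, na.rm = TRUE)) {
    bad <- span[which(apply(b > bfactor_max, 1, any))[1]]
    return(rejection("HIGH_BFACTOR",
                     sprintf("backbone B-factor > %g at IMGT %s",
                             bfactor_max, res$pos[bad]),
                     chain, cdr))
  }
  for (k in span[-length(span)]) {
    d <- sqrt(sum((res$xyz[k + 1, "N", ] - res$xyz[k, "C", ])^2))
    if (d >= bond_max) {
      return(rejection("CHAIN_BREAK",
                       sprintf("C-N bond %.3f A >= %.2f A after IMGT %s",
                               d, bond_max, res$pos[k]),
                       chain, cdr))
    }
  }

  take <- function(i) new_segment(res$pos[i], res$aa[i],
                                  res$xyz[i, , , drop = FALSE],
                                  res$bfac[i, , drop = FALSE])
  if (is.na(chain$chain_type)) {
    stop("chain_type is required to label the CDR (provide chain_info)")
  }
  new_cdr_loop(
    cdr_type = cdr_type_label(chain$chain_type, cdr),
    cdr = take(first:last),
    anchors_n = take((first - 5):(first - 1)),
    anchors_c = take((last + 1):(last + 5)),
    source = paste0(chain$structure_id, ":", chain$chain_id),
    resolution = chain$resolution,
    bound_state = bound_state)
}

#' Extract all CDR loops from a set of chains
#'
#' @param chains List of `receptor_chain` records.
#' @param cdrs Which CDRs to extract (default all three).
#' @param ... Filter cutoffs passed to [extract_loop()].
#' @return List with `loops` (accepted `cdr_loop`s) and `rejections`
#'   (tibble: structure, chain, cdr, code, detail).
#' @export
extract_loops <- function(chains, cdrs = c("CDR1", "CDR2", "CDR3"), ...) {
  loops <- list()
  rej <- list()
  for (chain in chains) {
    for (cdr in cdrs) {
      r <- extract_loop(chain, cdr, ...)
      if (is_rejection(r)) {
        rej[[length(rej) + 1L]] <- tibble::tibble(
          structure = r$structure_id, chain = r$chain_id, cdr = r$cdr,
          code = r$code, detail = r$detail)
      } else {
        loops[[length(loops) + 1L]] <- r
      }
    }
  }
  list(loops = loops,
       rejections = if (length(rej)) do.call(rbind, rej) else
         tibble::tibble(structure = character(), chain = character(),
                        cdr = character(), code = character(),
                        detail = character()))
}
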