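# IMGT window definitions, CDR type labels and position labelling.

# IMGT residue windows for the three CDRs (inclusive bounds).
CDR_WINDOWS <- list(CDR1 = c(27L, 38L), CDR2 = c(56L, 65L), CDR3 = c(105L, 117L))

# Backbone atom roles, in the fixed order used throughout the package.
BB_ATOMS <- c("N", "CA", "C", "O")

# Twenty standard amino acids (one-letter).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# chain_type -> one-letter CDR type prefix
CHAIN_CDR_PREFIX <- c(alpha = "a", beta = "b", heavy = "H", light = "L")

# Display form of the prefix used in class names (Greek for TCR chains).
CDR_DISPLAY_PREFIX <- c(a = "\u03b1", b = "\u03b2", H = "H", L = "L")

# beta/heavy and alpha/light chains are treated as equivalent pairs when
# TCR and antibody loops are clustered jointly.
EQUIVALENT_CDR <- c(a1 = "L1", a2 = "L2", a3 = "L3",
                    b1 = "H1", b2 = "H2", b3 = "H3",
                    L1 = "a1", L2 = "a2", L3 = "a3",
                    H1 = "b1", H2 = "b2", H3 = "b3")

CDR_TYPES <- names(EQUIVALENT_CDR)

# Canonical ordering of CDR type labels in joint class names (TCR first).
CDR_TYPE_ORDER <- c("a1", "a2", "a3", "b1", "b2", "b3",
                    "L1", "L2", "L3", "H1", "H2", "H3")

#' IMGT position labels for a CDR sequence of a given length
#'
#' Assigns IMGT position labels to the residues of a CDR loop of known
#' length. Shorter-than-window loops are gapped symmetrically (positions are
#' taken from both ends of the window, the gap sits at the loop apex), which
#' is the IMGT convention. Loops longer than the CDR3 window receive
#' insertion labels `111.1, 111.2, ...` ascending after position 111 and
#' `... 112.2, 112.1` descending before position 112.
#'
#' @param cdr One of `"CDR1"`, `"CDR2"`, `"CDR3"`.
#' @param length CDR length in residues (anchors excluded).
#' @return Character vector of `length` position labels, in loop order.
#' @examples
#' imgt_positions("CDR1", 5)
#' imgt_positions("CDR3", 15)
#' @export
imgt_positions <- function(cdr = c("CDR1", "CDR2", "CDR3"), length) {
  cdr <- match.arg(cdr)
  stopifnot(is.numeric(length), length >= 1)
  length <- as.integer(length)
  w <- CDR_WINDOWS[[cdr]]
  slots <- seq.int(w[1], w[2])
  nw <- base::length(slots)
  if (length <= nw) {
    k <- ceiling(length / 2)
    m <- length - k
    lab <- c(slots[seq_len(k)], if (m > 0) slots[seq.int(nw - m + 1L, nw)])
    return(as.character(lab))
  }
  if (cdr != "CDR3") {
    stop("insertions beyond the IMGT window are only supported for CDR3")
  }
  n_ins <- length - nw
  k <- ceiling(n_ins / 2)
  m <- n_ins - k
  c(as.character(105:111),
    paste0("111.", seq_len(k)),
    if (m > 0) paste0("112.", rev(seq_len(m))),
    as.character(112:117))
}

# Numeric sort key reproducing IMGT loop order: 111.k ascend after 111,
# 112.k descend before 112.
imgt_key <- function(labels) {
  base <- as.numeric(sub("\\..*$", "", labels))
  ins <- ifelse(grepl("\\.", labels), as.numeric(sub("^.*\\.", "", labels)), 0)
  ifelse(base <= 111, base + ins * 1e-3, base - ins * 1e-3)
}

# Which CDR window a (possibly inserted) position label belongs to, or NA.
imgt_window_of <- function(labels) {
  base <- as.numeric(sub("\\..*$", "", labels))
  out <- rep(NA_character_, length(labels))
  for (cdr in names(CDR_WINDOWS)) {
    w <- CDR_WINDOWS[[cdr]]
    out[base >= w[1] & base <= w[2]] <- cdr
  }
  out
}

# "a" + "CDR1" -> "a1"
cdr_type_label <- function(chain_type, cdr) {
  prefix <- CHAIN_CDR_PREFIX[[chain_type]]
  paste0(prefix, substr(cdr, 4, 4))
}

# "a1" -> "α1" (display form used in class names)
cdr_display <- function(cdr_type) {
  paste0(CDR_DISPLAY_PREFIX[substr(cdr_type, 1, 1)], substr(cdr_type, 2, 2))
}

# Are two CDR types clusterable together in the given mode?
cdr_compatible <- function(types, mode = c("tcr_only", "joint")) {
  mode <- match.arg(mode)
  u <- unique(types)
  if (length(u) == 1) return(TRUE)
  mode == "joint" && length(u) == 2 && EQUIVALENT_CDR[[u[1]]] == u[2]
}
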