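# The cdr_loop container: one extracted CDR loop with backbone coordinates,
# five anchor residues on each side, and provenance metadata.

# A loop segment holds n residues: position labels, one-letter codes, a
# (n x 4 x 3) backbone coordinate array (atom order N, CA, C, O) and a
# (n x 4) B-factor matrix.
new_segment <- function(pos, aa, xyz, bfac = NULL) {
  n <- length(pos)
  stopifnot(length(aa) == n, identical(dim(xyz), c(n, 4L, 3L)))
  if (is.null(bfac)) bfac <- matrix(30, n, 4)
  stopifnot(identical(dim(bfac), c(n, 4L)))
  dimnames(xyz) <- list(NULL, BB_ATOMS, c("x", "y", "z"))
  dimnames(bfac) <- list(NULL, BB_ATOMS)
  list(pos = as.character(pos), aa = toupper(aa), xyz = xyz, bfac = bfac)
}

#' Construct a CDR loop record
#'
#' Bundles the CDR residues of one loop with its five N-terminal and five
#' C-terminal anchor residues and provenance metadata. Most users obtain
#' these from [extract_loops()] or the synthetic generators rather than
#' calling this directly.
#'
#' @param cdr_type CDR type label: one of `a1,a2,a3,b1,b2,b3,L1,L2,L3,H1,H2,H3`.
#' @param cdr,anchors_n,anchors_c Residue segments as returned by the
#'   internal constructor: lists with `pos`, `aa`, `xyz` (n x 4 x 3, atoms
#'   N/CA/C/O) and `bfac` (n x 4).
#' @param source Provenance string `"<pdb>:<chain>"`.
#' @param resolution Structure resolution in Angstrom.
#' @param bound_state Optional flag (metadata only, never inferred).
#' @return An object of class `cdr_loop`.
#' @export
new_cdr_loop <- function(cdr_type, cdr, anchors_n, anchors_c, source,
                         resolution = NA_real_, bound_state = NA) {
  stopifnot(cdr_type %in% CDR_TYPES,
            length(anchors_n$pos) == 5L, length(anchors_c$pos) == 5L,
            length(cdr$pos) >= 1L)
  for (seg in list(cdr, anchors_n, anchors_c)) {
    if (!all(is.finite(seg$xyz))) stop("non-finite coordinates in loop segment")
  }
  structure(list(
    cdr_type = cdr_type,
    sequence = paste(cdr$aa, collapse = ""),
    cdr = cdr,
    anchors_n = anchors_n,
    anchors_c = anchors_c,
    source = source,
    resolution = resolution,
    bound_state = bound_state
  ), class = "cdr_loop")
}

#' @export
print.cdr_loop <- function(x, ...) {
  cat(sprintf("<cdr_loop> %s %s  %s (%d aa)  resolution %.2f A\n",
              x$source, x$cdr_type, x$sequence, nchar(x$sequence),
              x$resolution))
  invisible(x)
}

#' Identifier of a loop: source plus CDR type
#' @param loop A `cdr_loop`.
#' @return Character scalar, e.g. `"5hhm:E/a1"`.
#' @export
loop_id <- function(loop) paste0(loop$source, "/", loop$cdr_type)

# Flattened backbone coordinates as a (4n x 3) matrix, residues in order,
# atoms N, CA, C, O within each residue.
seg_matrix <- function(seg) {
  n <- dim(seg$xyz)[1]
  m <- matrix(NA_real_, 4L * n, 3L)
  for (i in seq_len(n)) m[(4L * i - 3L):(4L * i), ] <- seg$xyz[i, , ]
  m
}

seg_set_matrix <- function(seg, m) {
  n <- dim(seg$xyz)[1]
  for (i in seq_len(n)) seg$xyz[i, , ] <- m[(4L * i - 3L):(4L * i), ]
  seg
}

#' Backbone coordinates of a loop
#'
#' @param loop A `cdr_loop`.
#' @param part `"cdr"` (loop residues only), `"anchors"` (the 10 anchor
#'   residues, N-side first) or `"all"` (anchors_n, cdr, anchors_c in chain
#'   order).
#' @return Numeric matrix (4 rows per residue; atoms N, CA, C, O) with 3
#'   columns.
#' @export
loop_backbone <- function(loop, part = c("cdr", "anchors", "all")) {
  part <- match.arg(part)
  switch(part,
    cdr = seg_matrix(loop$cdr),
    anchors = rbind(seg_matrix(loop$anchors_n), seg_matrix(loop$anchors_c)),
    all = rbind(seg_matrix(loop$anchors_n), seg_matrix(loop$cdr),
                seg_matrix(loop$anchors_c)))
}

# All residues of the loop span in chain order as one segment.
loop_span <- function(loop) {
  list(pos = c(loop$anchors_n$pos, loop$cdr$pos, loop$anchors_c$pos),
       aa = c(loop$anchors_n$aa, loop$cdr$aa, loop$anchors_c$aa),
       xyz = {
         n1 <- dim(loop$anchors_n$xyz)[1]
         n2 <- dim(loop$cdr$xyz)[1]
         n3 <- dim(loop$anchors_c$xyz)[1]
         a <- array(NA_real_, c(n1 + n2 + n3, 4L, 3L),
                    dimnames = list(NULL, BB_ATOMS, c("x", "y", "z")))
         a[seq_len(n1), , ] <- loop$anchors_n$xyz
         a[n1 + seq_len(n2), , ] <- loop$cdr$xyz
         a[n1 + n2 + seq_len(n3), , ] <- loop$anchors_c$xyz
         a
       })
}

# Apply a rigid transform (y = R x + t) to every atom of a loop.
apply_rigid <- function(loop, rotation, translation) {
  tf <- function(seg) {
    m <- seg_matrix(seg)
    seg_set_matrix(seg, sweep(m %*% t(rotation), 2, translation, "+"))
  }
  loop$cdr <- tf(loop$cdr)
  loop$anchors_n <- tf(loop$anchors_n)
  loop$anchors_c <- tf(loop$anchors_c)
  loop
}

seg_to_list <- function(seg) {
  list(pos = seg$pos, aa = seg$aa,
       xyz = round(as.vector(seg$xyz), 6), bfac = as.vector(seg$bfac))
}

seg_from_list <- function(x) {
  n <- length(x$pos)
  new_segment(x$pos, x$aa,
              array(as.numeric(x$xyz), c(n, 4L, 3L)),
              matrix(as.numeric(x$bfac), n, 4L))
}

#' Serialize loops to JSON-lines
#'
#' One loop per line; coordinates rounded to 1e-6 Angstrom. The writer is
#' deterministic: identical loops give byte-identical files.
#'
#' @param loops List of `cdr_loop` objects.
#' @param path Output file.
#' @export
write_loops_jsonl <- function(loops, path) {
  lines <- vapply(loops, function(l) {
    jsonlite::toJSON(list(
      cdr_type = l$cdr_type, source = l$source,
      resolution = l$resolution, bound_state = l$bound_state,
      cdr = seg_to_list(l$cdr),
      anchors_n = seg_to_list(l$anchors_n),
      anchors_c = seg_to_list(l$anchors_c)
    ), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read loops from a JSON-lines file written by [write_loops_jsonl()]
#' @param path Input file.
#' @return List of `cdr_loop` objects.
#' @export
read_loops_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    new_cdr_loop(x$cdr_type,
                 seg_from_list(x$cdr),
                 seg_from_list(x$anchors_n),
                 seg_from_list(x$anchors_c),
                 source = x$source,
                 resolution = if (is.null(x$resolution)) NA_real_ else x$resolution,
                 bound_state = if (is.null(x$bound_state)) NA else x$bound_state)
  })
}
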