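# Pipeline orchestration: run configuration with the published default
# constants, PDB fixture writing, and the staged commands tying
# extraction, clustering, PSSM building, prediction and reporting
# together.

#' Run configuration with the published default constants
#'
#' Collects every tunable of the pipeline with its default: the
#' structural quality cutoffs (resolution 2.8 A, backbone B-factor 80,
#' peptide bond 1.37 A), the TCR-only DBSCAN radius (1.0 A), the joint
#' TCR/antibody per-CDR radii (a1/L1 0.82, a2/L2 1.0, a3/L3 0.91,
#' b1/H1 0.8, b2/H2 0.63 A), the cluster designation rules (minimum five
#' structures; two unique sequences TCR-only; six unique sequences
#' joint), the prediction threshold (P_c > 1; P_c >= length for CDRa3 is
#' built into the predictor), the blind-test RMSD cutoff (1.0 A), the
#' RMSD fit set and the seed.
#'
#' @param ... Overrides by name; an unknown key is an error naming it.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    resolution_max = 2.8,
    bfactor_max = 80,
    bond_max = 1.37,
    eps_tcr = 1.0,
    eps_joint = c(a1 = 0.82, a2 = 1.0, a3 = 0.91, b1 = 0.8, b2 = 0.63),
    min_structures = 5,
    min_unique_tcr = 2,
    min_unique_joint = 6,
    pc_min = 1,
    rmsd_match = 1.0,
    fit_on = "loop",
    exact_match = TRUE,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  num <- unlist(cfg[c("resolution_max", "bfactor_max", "bond_max", "eps_tcr",
                      "eps_joint", "min_structures", "min_unique_tcr",
                      "min_unique_joint", "rmsd_match")])
  if (any(num <= 0)) stop("config: numeric parameters must be positive")
  structure(cfg, class = "run_config")
}

#' Write loops as a PDB fixture file
#'
#' Serializes one or more loops (anchors + CDR, backbone atoms only) as
#' chains of a PDB file with a REMARK 2 resolution header, so the file
#' round-trips through [read_structure()] / [extract_loop()]. IMGT
#' insertion labels (`111.1`, ...) become PDB insertion codes A, B, ...
#'
#' @param loops A `cdr_loop` or list of them.
#' @param path Output PDB path.
#' @param chains Chain identifier per loop (default A, B, ...).
#' @param resolution Resolution written to the header (default: first
#'   loop's, or 2.0).
#' @export
write_loops_pdb <- function(loops, path, chains = NULL, resolution = NULL) {
  if (inherits(loops, "cdr_loop")) loops <- list(loops)
  if (is.null(chains)) chains <- LETTERS[seq_along(loops)]
  if (is.null(resolution)) {
    resolution <- if (is.finite(loops[[1]]$resolution))
      loops[[1]]$resolution else 2.0
  }
  xyz <- c(); resno <- c(); resid <- c(); elety <- c()
  chain <- c(); insert <- c(); b <- c()
  for (li in seq_along(loops)) {
    span <- loop_span(loops[[li]])
    bfac <- rbind(loops[[li]]$anchors_n$bfac, loops[[li]]$cdr$bfac,
                  loops[[li]]$anchors_c$bfac)
    for (i in seq_along(span$pos)) {
      lab <- span$pos[i]
      base <- sub("\\..*$", "", lab)
      ins <- if (grepl("\\.", lab)) {
        LETTERS[as.integer(sub("^.*\\.", "", lab))]
      } else ""
      for (at in BB_ATOMS) {
        xyz <- c(xyz, span$xyz[i, at, ])
        resno <- c(resno, as.integer(base))
        resid <- c(resid, bio3d::aa123(span$aa[i]))
        elety <- c(elety, at)
        chain <- c(chain, chains[li])
        insert <- c(insert, ins)
        b <- c(b, bfac[i, at])
      }
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = resno, resid = resid,
                   eleno = seq_along(resno), elety = elety, chain = chain,
                   insert = insert, o = rep(1, length(resno)), b = b)
  lines <- readLines(tmp)
  unlink(tmp)
  writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                       resolution), lines), path)
  invisible(path)
}

log_stage <- function(dir, command, params) {
  path <- file.path(dir, "run_log.json")
  entry <- list(command = command, params = params,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  existing <- if (file.exists(path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else list()
  existing[[length(existing) + 1L]] <- entry
  jsonlite::write_json(existing, path, auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic PDB fixtures + truth),
#' `extract` (PDB directory -> loops JSONL + rejection CSV),
#' `cluster` (loops -> class catalog JSON + distance matrix CSV +
#' membership CSV), `build-pssms` (catalog -> PSSM JSON), `predict`
#' (PSSMs + sequence TSV/FASTA -> prediction TSV), `loocv` (catalog ->
#' metrics JSON), `torso` (CDR3 loops -> torso geometry CSV) and
#' `variability` (loops + catalog -> variability CSV). Every stage
#' appends its effective parameters to `run_log.json` in the output
#' directory.
#'
#' @param command Stage name.
#' @param config A [run_config()].
#' @param input Input path (stage-specific; directory or file).
#' @param output Output directory (created if needed).
#' @param preset For `simulate`: `"clusters"`, `"torso"` or `"pssm"`.
#' @param cdr_type CDR type label for stages that need one (default
#'   `"a1"`; `torso` defaults to CDR3 types).
#' @param mode Clustering mode for `cluster` (default `"tcr_only"`).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "extract", "cluster",
                                     "build-pssms", "predict", "loocv",
                                     "torso", "variability"),
                         config = run_config(), input = NULL, output = ".",
                         preset = "clusters", cdr_type = "a1",
                         mode = "tcr_only") {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  if (command == "simulate") {
    if (preset == "clusters") {
      ds <- make_cluster_set(k = 3, per_family = 7, cdr_type = cdr_type,
                             eps = config$eps_tcr, seed = config$seed)
      for (i in seq_along(ds$loops)) {
        l <- ds$loops[[i]]
        pdb_id <- sub(":.*$", "", l$source)
        write_loops_pdb(l, file.path(output, paste0(pdb_id, ".pdb")),
                        chains = sub("^.*:", "", l$source))
      }
      utils::write.table(
        data.frame(chain = "A", receptor_class = "TCR",
                   chain_type = if (substr(cdr_type, 1, 1) == "a") "alpha"
                   else "beta"),
        file.path(output, "chain_info.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      jsonlite::write_json(list(truth = ds$truth, ids = ds$ids,
                                seed = ds$seed, eps = ds$eps),
                           file.path(output, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      out$truth <- file.path(output, "truth.json")
    } else if (preset == "torso") {
      loops <- c(lapply(1:10, function(s) make_torso("extended", seed = s)),
                 lapply(1:10, function(s) make_torso("kinked", seed = s)))
      write_loops_jsonl(loops, file.path(output, "torso_loops.jsonl"))
      jsonlite::write_json(list(kind = rep(c("extended", "kinked"),
                                           each = 10)),
                           file.path(output, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      out$loops <- file.path(output, "torso_loops.jsonl")
    } else if (preset == "pssm") {
      data <- make_sequence_classes(n_classes = 2, seqs_per_class = 10,
                                    n_decoys = 5, seed = config$seed)
      utils::write.table(data, file.path(output, "sequences.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      out$sequences <- file.path(output, "sequences.tsv")
    } else stop("unknown simulate preset: ", preset)
  }

  if (command == "extract") {
    pdbs <- list.files(input, pattern = "\\.pdb$", full.names = TRUE)
    if (!length(pdbs)) stop("no PDB files in ", input)
    ci_path <- file.path(input, "chain_info.tsv")
    chain_info <- if (file.exists(ci_path)) {
      utils::read.delim(ci_path, stringsAsFactors = FALSE)
    } else NULL
    chains <- unlist(lapply(sort(pdbs), read_structure,
                            chain_info = chain_info), recursive = FALSE)
    res <- extract_loops(chains, resolution_max = config$resolution_max,
                         bfactor_max = config$bfactor_max,
                         bond_max = config$bond_max)
    write_loops_jsonl(res$loops, file.path(output, "loops.jsonl"))
    utils::write.csv(res$rejections, file.path(output, "rejections.csv"),
                     row.names = FALSE)
    out$loops <- file.path(output, "loops.jsonl")
    out$rejections <- file.path(output, "rejections.csv")
  }

  if (command == "cluster") {
    loops <- read_loops_jsonl(input)
    types <- unique(vapply(loops, function(l) l$cdr_type, character(1)))
    eps <- if (mode == "joint") {
      key <- intersect(names(config$eps_joint),
                       c(types, EQUIVALENT_CDR[types]))
      config$eps_joint[[key[1]]]
    } else config$eps_tcr
    cl <- cluster_loops(loops, eps = eps, mode = mode,
                        min_structures = config$min_structures,
                        min_unique_tcr = config$min_unique_tcr,
                        min_unique_joint = config$min_unique_joint)
    write_catalog_json(cl$catalog, file.path(output, "catalog.json"))
    utils::write.csv(data.frame(id = cl$matrix$ids, cl$matrix$values,
                                check.names = FALSE),
                     file.path(output, "distance_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(catalog_membership(cl$catalog),
                     file.path(output, "membership.csv"), row.names = FALSE)
    out$catalog <- file.path(output, "catalog.json")
  }

  if (command == "build-pssms") {
    catalog <- read_catalog_json(input)
    types <- unlist(lapply(catalog$classes, function(cl) cl$cdr_types))
    pssms <- build_class_pssms(catalog, cdr = types[1])
    write_pssms_json(pssms, file.path(output, "pssms.json"))
    out$pssms <- file.path(output, "pssms.json")
  }

  if (command == "predict") {
    # input: c(pssms.json, sequences file [tsv with columns sequence
    # (+ optional cdr), or FASTA])
    pssms <- read_pssms_json(input[1])
    seq_file <- input[2]
    if (grepl("\\.(fa|fasta)$", seq_file, ignore.case = TRUE)) {
      if (!requireNamespace("Biostrings", quietly = TRUE)) {
        stop("FASTA input requires the Biostrings package")
      }
      ss <- Biostrings::readAAStringSet(seq_file)
      seqs <- as.character(ss)
      cdrs <- sub("^.*cdr=([A-Za-z0-9]+).*$", "\\1", names(ss))
    } else {
      tab <- utils::read.delim(seq_file, stringsAsFactors = FALSE)
      seqs <- tab$sequence
      cdrs <- if ("cdr" %in% names(tab)) tab$cdr else
        rep(cdr_type, length(seqs))
    }
    preds <- do.call(rbind, lapply(unique(cdrs), function(ct) {
      predict_canonical(seqs[cdrs == ct], ct, catalog = NULL,
                        pssms = pssms, exact_match = FALSE)
    }))
    preds <- preds[match(seqs, preds$sequence), ]
    utils::write.table(preds, file.path(output, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$predictions <- file.path(output, "predictions.tsv")
  }

  if (command == "loocv") {
    # input: c(catalog.json) — LOOCV over canonical + unclustered unique
    # sequences; unclustered sequences are recovered from the loops file
    # given as input[2]
    catalog <- read_catalog_json(input[1])
    loops <- read_loops_jsonl(input[2])
    ids <- make.unique(vapply(loops, loop_id, character(1)), sep = "#")
    seq_of <- vapply(loops, function(l) toupper(l$sequence), character(1))
    rows <- list()
    for (cl in catalog$classes) {
      if (cl$kind != "canonical") next
      for (s in cl$sequences) {
        rows[[length(rows) + 1L]] <- data.frame(sequence = s,
                                                label = cl$name)
      }
    }
    for (s in unique(seq_of[ids %in% catalog$unclustered])) {
      rows[[length(rows) + 1L]] <- data.frame(sequence = s,
                                              label = "unclustered")
    }
    data <- do.call(rbind, rows)
    data <- data[!duplicated(toupper(data$sequence)), ]
    ct <- loops[[1]]$cdr_type
    cv <- loocv(data, cdr_type = ct, exact_match = config$exact_match)
    jsonlite::write_json(list(counts = as.list(cv$counts),
                              accuracy = cv$accuracy),
                         file.path(output, "loocv.json"),
                         auto_unbox = TRUE, digits = NA)
    out$loocv <- file.path(output, "loocv.json")
  }

  if (command == "torso") {
    loops <- read_loops_jsonl(input)
    report <- torso_report(loops)
    utils::write.csv(report, file.path(output, "torso.csv"),
                     row.names = FALSE)
    out$torso <- file.path(output, "torso.csv")
  }

  if (command == "variability") {
    loops <- read_loops_jsonl(input[1])
    catalog <- read_catalog_json(input[2])
    summary <- variability_summary(loops, catalog, fit_on = config$fit_on,
                                   similar_max = config$rmsd_match)
    utils::write.csv(summary, file.path(output, "variability.csv"),
                     row.names = FALSE)
    out$variability <- file.path(output, "variability.csv")
  }

  log_stage(output, command,
            c(unclass(config), list(input = paste(input, collapse = ";"),
                                    preset = preset, cdr_type = cdr_type,
                                    mode = mode)))
  invisible(out)
}
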