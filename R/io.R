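## Atom-name dialect normalization: PDB v2 names (O1P/O2P, asterisk
## primes) onto the v3 dialect used internally.
normalize_atom_names <- function(nm) {
  nm <- gsub("*", "'", nm, fixed = TRUE)
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm
}

normalize_resnames <- function(rn) {
  rn <- toupper(trimws(rn))
  map <- c(RA = "A", RG = "G", RC = "C", RU = "U",
           A5 = "A", G5 = "G", C5 = "C", U5 = "U",
           A3 = "A", G3 = "G", C3 = "C", U3 = "U")
  hit <- rn %in% names(map)
  rn[hit] <- map[rn[hit]]
  rn
}

#' Read conformations from a (multi-model) PDB file
#'
#' One [conformation()] per MODEL record (single-model files yield one),
#' in file order. Atom-name dialects are normalized on input (`O1P`/`O2P`
#' to `OP1`/`OP2`, asterisk primes to apostrophes), so atom maps resolve
#' identically for either dialect. Parsing is delegated to
#' \pkg{bio3d}.
#'
#' @param path PDB file path.
#' @return list of conformations.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  nm <- normalize_atom_names(at$elety)
  rn <- normalize_resnames(at$resid)
  resid <- at$resno
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  lapply(seq_len(nmod), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    conformation(resid, rn, nm, co)
  })
}

#' Write conformations to a multi-model PDB file
#'
#' @param frames a [conformation()] or list of conformations sharing one
#'   topology.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(frames, path) {
  if (inherits(frames, "conformation")) frames <- list(frames)
  ref <- frames[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    f <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, f$name[i], paste0(f$resname[i]), f$resid[i],
        f$x[i], f$y[i], f$z[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' eRMSD profile of a trajectory
#'
#' Computes the eRMSD of every frame against the reference together with
#' the folded indicator at the given threshold.
#'
#' @param frames list of [conformation()] frames.
#' @param reference native reference conformation.
#' @param threshold folding threshold (default 0.7).
#' @return data frame with columns `frame`, `ermsd`, `folded`.
#' @export
ermsd_trajectory <- function(frames, reference, threshold = 0.7) {
  e <- vapply(frames, ermsd, numeric(1), reference = reference)
  data.frame(frame = seq_along(frames), ermsd = e, folded = e < threshold)
}

#' Write a state timeline as CSV
#'
#' Columns: frame, time, state, weight and the eight feature columns.
#'
#' @param timeline a `state_timeline`.
#' @param path output path.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(as.data.frame(timeline), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes feature extraction and state classification, the eRMSD
#' folded/unfolded partition, the folding free-energy estimate, and
#' (when an observable table is supplied) the NMR chi-square score, and
#' writes the report bundle: `timeline.csv`, `populations.json`,
#' `dgfold.json`, `chi2.json` and `run_log.txt` into the output directory.
#' Every JSON report embeds the thresholds and settings used.
#'
#' @param frames list of [conformation()] frames, or a path readable by
#'   [read_structures()].
#' @param reference reference conformation (or PDB path); defaults to the
#'   first frame.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param map atom map.
#' @param cfg classifier configuration.
#' @param weights optional per-frame weights (e.g. unbiasing factors).
#' @param observables optional observable table (data frame or TSV path).
#' @param temperature Kelvin (default 298).
#' @param threshold eRMSD folding threshold (default 0.7).
#' @param n_blocks,n_resamples bootstrap settings.
#' @param seed seed for the bootstrap resampling.
#' @return list with `timeline`, `populations`, `ermsd`, `dg`, `chi2`
#'   (class `tf_report`).
#' @export
run_pipeline <- function(frames, reference = NULL, out_dir = NULL,
                         map = default_atom_map(),
                         cfg = classifier_config(), weights = NULL,
                         observables = NULL, temperature = 298,
                         threshold = 0.7, n_blocks = 16,
                         n_resamples = 1000, seed = 1) {
  if (is.character(frames)) frames <- read_structures(frames)
  if (is.character(reference)) reference <- read_structures(reference)[[1]]
  if (is.null(reference)) reference <- frames[[1]]
  if (is.null(weights)) weights <- rep(1, length(frames))

  timeline <- classify_trajectory(frames, map, reference, cfg,
                                  weights = weights)
  pops <- attr(timeline, "populations")
  etab <- ermsd_trajectory(frames, reference, threshold)
  dg <- dg_fold(etab$folded, weights = weights, n_blocks = n_blocks,
                n_resamples = n_resamples, temperature = temperature,
                seed = seed)
  chi2 <- NULL
  if (!is.null(observables)) {
    if (is.character(observables))
      observables <- read_observable_table(observables)
    chi2 <- chi2_total(observables, frames, weights)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_timeline_csv(timeline, file.path(out_dir, "timeline.csv"))
    jsonlite::write_json(
      list(populations = as.list(pops),
           thresholds_A = unclass(cfg)[c("hb", "bph_native", "n7_relaxed",
                                         "bph_back", "far", "n1_back",
                                         "rmsd_loop_cut", "rmsd_all_cut")]),
      file.path(out_dir, "populations.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(
      c(summary(dg),
        list(interval = dg$interval, n_frames = dg$n_frames,
             n_blocks = dg$n_blocks, n_resamples = dg$n_resamples,
             ermsd_threshold = threshold, seed = seed)),
      file.path(out_dir, "dgfold.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(chi2))
      jsonlite::write_json(
        list(total_chi2 = chi2$total_chi2, by_class = chi2$by_class,
             weighting = chi2$weighting, skipped = chi2$skipped),
        file.path(out_dir, "chi2.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(
      paste("tetrafold", as.character(utils::packageVersion("tetrafold"))),
      paste("frames:", length(frames)),
      paste("temperature_K:", temperature),
      paste("ermsd_threshold:", threshold),
      paste("n_blocks:", n_blocks), paste("n_resamples:", n_resamples),
      paste("seed:", seed)),
      file.path(out_dir, "run_log.txt"))
  }
  structure(list(timeline = timeline, populations = pops, ermsd = etab,
                 dg = dg, chi2 = chi2), class = "tf_report")
}

#' @export
print.tf_report <- function(x, ...) {
  cat("tetrafold pipeline report\n")
  cat("  frames:", nrow(x$timeline), "\n")
  p <- x$populations
  cat("  top states:", paste(sprintf("%s=%.3f", names(p)[order(-p)][1:min(3, length(p))],
                                     sort(p, decreasing = TRUE)[1:min(3, length(p))]),
                             collapse = ", "), "\n")
  print(x$dg)
  if (!is.null(x$chi2)) print(x$chi2)
  invisible(x)
}
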