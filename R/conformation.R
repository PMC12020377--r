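#' Conformation container
#'
#' A conformation is one frame of a structure: a table of heavy atoms with
#' 1-based residue indices, residue names, atom names and Cartesian
#' coordinates in Angstrom. Atom names follow the PDB v3 dialect (`O2'`,
#' `OP1`, `OP2`); [read_structures()] normalizes older dialects on input.
#'
#' @param resid integer vector of 1-based residue indices.
#' @param resname character vector of residue names (e.g. `"G"`, `"U"`).
#' @param name character vector of atom names.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (A).
#' @param frame_time optional non-negative frame time (arbitrary units).
#' @return An object of class `conformation`: a data frame with columns
#'   `resid`, `resname`, `name`, `x`, `y`, `z`.
#' @export
conformation <- function(resid, resname, name, xyz, frame_time = NULL) {
  resid <- as.integer(resid)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(resid),
            length(resname) == length(resid), length(name) == length(resid))
  if (!all(is.finite(xyz)))
    stop("conformation: non-finite coordinates", call. = FALSE)
  key <- paste(resid, name)
  if (anyDuplicated(key))
    stop("conformation: duplicated (residue, atom) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (!is.null(frame_time))
    stopifnot(is.numeric(frame_time), frame_time >= 0)
  out <- data.frame(resid = resid, resname = as.character(resname),
                    name = as.character(name),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "frame_time") <- frame_time
  class(out) <- c("conformation", "data.frame")
  out
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x), " atoms, ",
      length(unique(x$resid)), " residues (",
      paste0(x$resname[!duplicated(x$resid)], unique(x$resid),
             collapse = " "), ")\n", sep = "")
  invisible(x)
}

## Coordinate matrix with "resid name" rownames for fast lookup.
conf_xyz <- function(conf) {
  m <- cbind(conf$x, conf$y, conf$z)
  rownames(m) <- paste(conf$resid, conf$name)
  m
}

#' Parse an atom reference
#'
#' Atom references are strings of the form `"G9:N1"` or `"9:N1"`: an
#' optional one-letter residue name, a 1-based residue index, a colon and an
#' atom name. `"pro-R_P"` and `"pro-S_P"` are accepted as aliases for the
#' prochiral phosphate oxygens `OP1` and `OP2`.
#'
#' @param ref atom-reference string.
#' @return list with elements `resid` (integer) and `name` (character).
#' @export
parse_atom_ref <- function(ref) {
  if (is.list(ref)) return(ref)
  stopifnot(is.character(ref), length(ref) == 1L)
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed atom reference: '", ref, "'", call. = FALSE)
  resid <- as.integer(sub("^[A-Za-z]*", "", parts[1]))
  if (is.na(resid))
    stop("malformed atom reference: '", ref, "'", call. = FALSE)
  nm <- parts[2]
  nm <- switch(nm, "pro-R_P" = "OP1", "pro-S_P" = "OP2", nm)
  list(resid = resid, name = nm)
}

## Coordinates of one referenced atom; errors name the missing reference.
atom_coords <- function(conf, ref) {
  r <- parse_atom_ref(ref)
  i <- which(conf$resid == r$resid & conf$name == r$name)
  if (length(i) != 1L)
    stop("atom lookup failed for reference '",
         if (is.character(ref)) ref else paste0(r$resid, ":", r$name),
         "'", call. = FALSE)
  c(conf$x[i], conf$y[i], conf$z[i])
}

#' Default atom map for the 14-mer UUCG hairpin
#'
#' Names every atom monitored by the state classifier: the hydrogen-bond
#' donor/acceptor heavy atoms of the native loop contacts, the four atoms of
#' the G9 glycosidic torsion, and the two RMSD selections (heavy atoms of
#' the U6-U7-C8-G9 loop; heavy atoms of all 14 residues). Residue numbering
#' follows the experimental structure (loop = residues 6-9).
#'
#' @param loop_resid residue indices of the tetraloop (default `6:9`).
#' @param all_resid residue indices of the full construct (default `1:14`).
#' @return list of atom references and residue selections, class `atom_map`.
#' @export
default_atom_map <- function(loop_resid = 6:9, all_resid = 1:14) {
  map <- list(
    U6_O2   = "U6:O2",  U6_O2p  = "U6:O2'", U6_proRP = "U6:OP1",
    U7_O2p  = "U7:O2'", C8_N4   = "C8:N4",
    G9_N1   = "G9:N1",  G9_N2   = "G9:N2",  G9_N7    = "G9:N7",
    G9_O6   = "G9:O6",  G9_O4p  = "G9:O4'", G9_C1p   = "G9:C1'",
    G9_N9   = "G9:N9",  G9_C4   = "G9:C4",
    loop_resid = loop_resid, all_resid = all_resid)
  class(map) <- "atom_map"
  map
}

## Heavy-atom selection (row indices) for a residue set.
heavy_selection <- function(conf, resid) {
  which(conf$resid %in% resid & !grepl("^H", conf$name))
}
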