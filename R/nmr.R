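#' Karplus relation for 3J scalar couplings
#'
#' J(theta) = A cos^2(theta + offset) + B cos(theta + offset) + C, with the
#' phase offset (degrees) applied to the structural torsion before
#' evaluation. Coefficient sets are configuration data (see
#' [default_karplus_sets()]), never hard-coded into the scorer.
#'
#' @param theta torsion angle(s) in degrees.
#' @param A,B,C Karplus coefficients in Hz.
#' @param offset phase offset in degrees (default 0).
#' @return coupling(s) in Hz.
#' @export
karplus_3j <- function(theta, A, B, C, offset = 0) {
  ct <- cos((theta + offset) * pi / 180)
  A * ct^2 + B * ct + C
}

#' Default Karplus coefficient sets
#'
#' Editable table of literature coefficient sets keyed by `set` id. The
#' shipped defaults are the classic H-C-C-H sugar parametrization
#' (A = 9.67, B = -2.03, C = 0.68 Hz) and the H-C-O-P backbone
#' parametrization (A = 15.3, B = -6.1, C = 1.6 Hz). Because the analysis
#' operates on heavy atoms only, the `offset` column carries the phase
#' shift standing in for the proton position on the heavy-atom torsion;
#' the synthetic data use the same convention, so any consistent offset is
#' self-consistent.
#'
#' @return data frame with columns `set`, `A`, `B`, `C`, `offset`.
#' @export
default_karplus_sets <- function() {
  data.frame(set = c("sugar_HCCH", "backbone_HCOP"),
             A = c(9.67, 15.3), B = c(-2.03, -6.1), C = c(0.68, 1.6),
             offset = c(-120, 0), stringsAsFactors = FALSE)
}

#' Effective NOE distance by r^-6 averaging
#'
#' r_eff = (weighted mean of r^-6)^(-1/6) over the ensemble frames. Lies
#' between min(r) and the arithmetic mean of r.
#'
#' @param r per-frame distances in Angstrom, all > 0.
#' @param weights per-frame weights (default 1).
#' @return effective distance in Angstrom.
#' @export
noe_effective <- function(r, weights = NULL) {
  if (any(r <= 0)) stop("domain error: non-positive NOE distance",
                        call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(r))
  (sum(weights * r^-6) / sum(weights))^(-1 / 6)
}

#' Effective ambiguous-NOE distance
#'
#' Ambiguous NOEs sum the r^-6 contributions of 2-4 nuclei pairs per frame
#' before the ensemble average: r_eff = (weighted frame-mean of
#' sum_pairs r^-6)^(-1/6). With a single pair this reduces to
#' [noe_effective()].
#'
#' @param r matrix of per-frame distances, frames in rows, pairs (1-4) in
#'   columns.
#' @param weights per-frame weights (default 1).
#' @return effective distance in Angstrom.
#' @export
ambnoe_effective <- function(r, weights = NULL) {
  r <- as.matrix(r)
  stopifnot(ncol(r) >= 1, ncol(r) <= 4)
  if (any(r <= 0)) stop("domain error: non-positive NOE distance",
                        call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(r))
  (sum(weights * rowSums(r^-6)) / sum(weights))^(-1 / 6)
}

#' Read / write an NMR observable table
#'
#' Tab-separated, one observable per row, columns `id`, `class` (one of
#' `backbone_3J`, `sugar_3J`, `NOE`, `ambNOE`), `atoms`
#' (semicolon-separated `residue:atom` tokens: 4 for a 3J torsion, 2 per
#' NOE pair, 4/6/8 for 2-4 ambiguous pairs), `exp_value` (Hz for 3J,
#' Angstrom for NOE classes), `exp_error` (> 0, same units) and
#' `karplus_set` (id into the Karplus table; empty for NOE rows).
#'
#' @param path file path.
#' @param table data frame with the columns above.
#' @return `read_observable_table()` returns the validated data frame.
#' @export
read_observable_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_observable_table(tab)
}

#' @rdname read_observable_table
#' @export
write_observable_table <- function(table, path) {
  utils::write.table(validate_observable_table(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_observable_table <- function(tab) {
  need <- c("id", "class", "atoms", "exp_value", "exp_error", "karplus_set")
  if (!all(need %in% names(tab)))
    stop("observable table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(tab$exp_error <= 0))
    stop("observable table: exp_error must be > 0", call. = FALSE)
  bad <- !tab$class %in% c("backbone_3J", "sugar_3J", "NOE", "ambNOE")
  if (any(bad))
    stop("unknown observable class: ", paste(unique(tab$class[bad]),
                                             collapse = ", "), call. = FALSE)
  ntok <- lengths(strsplit(tab$atoms, ";", fixed = TRUE))
  if (any(tab$class %in% c("backbone_3J", "sugar_3J") & ntok != 4))
    stop("3J rows need exactly 4 atom tokens", call. = FALSE)
  if (any(tab$class == "NOE" & ntok != 2))
    stop("NOE rows need exactly 2 atom tokens", call. = FALSE)
  if (any(tab$class == "ambNOE" & !(ntok %in% c(4, 6, 8))))
    stop("ambNOE rows need 2-4 atom pairs (4, 6 or 8 tokens)", call. = FALSE)
  tab
}

## Back-calculate one observable over the ensemble; NULL if atoms missing.
calc_observable <- function(row, frames, weights, ksets) {
  toks <- strsplit(row$atoms, ";", fixed = TRUE)[[1]]
  tryCatch({
    if (row$class %in% c("backbone_3J", "sugar_3J")) {
      k <- ksets[match(row$karplus_set, ksets$set), ]
      if (anyNA(k$A)) stop("unknown karplus set '", row$karplus_set, "'")
      th <- vapply(frames, function(cf)
        conf_dihedral(cf, toks[1], toks[2], toks[3], toks[4]), numeric(1))
      sum(weights * karplus_3j(th, k$A, k$B, k$C, k$offset)) / sum(weights)
    } else {
      npair <- length(toks) / 2
      D <- vapply(seq_len(npair), function(p) {
        vapply(frames, function(cf)
          conf_distance(cf, toks[2 * p - 1], toks[2 * p]), numeric(1))
      }, numeric(length(frames)))
      D <- matrix(D, nrow = length(frames))
      ambnoe_effective(D, weights)
    }
  }, error = function(e) NULL)
}

#' Total chi-square agreement with NMR observables
#'
#' Back-calculates every observable from the ensemble (per-frame Karplus
#' couplings averaged with the frame weights; NOE and ambiguous-NOE
#' effective distances by r^-6 averaging), forms sigma-normalized
#' residuals (calc - exp) / sigma, the per-class chi-square as the mean
#' squared residual within each class, and combines classes by a weighted
#' arithmetic mean with weights defaulting to the class observable counts
#' (so the default total equals the grand mean squared residual).
#'
#' @param table observable table (see [read_observable_table()]).
#' @param frames list of [conformation()] frames.
#' @param weights per-frame weights (default 1).
#' @param karplus_sets Karplus coefficient table (default
#'   [default_karplus_sets()]).
#' @param class_weights optional named per-class weights overriding the
#'   default observable-count weighting.
#' @return object of class `chi2_report`: list with `total_chi2`,
#'   `by_class` (data frame of class, n, chi2), `residuals` (per-observable
#'   data frame), `skipped` (ids of unresolvable observables) and
#'   `weighting` metadata.
#' @export
chi2_total <- function(table, frames, weights = NULL,
                       karplus_sets = default_karplus_sets(),
                       class_weights = NULL) {
  table <- validate_observable_table(table)
  if (is.null(weights)) weights <- rep(1, length(frames))
  calc <- vapply(seq_len(nrow(table)), function(i) {
    v <- calc_observable(table[i, ], frames, weights, karplus_sets)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  skipped <- table$id[is.na(calc)]
  if (length(skipped))
    warning("skipping observables with unresolvable atoms: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  ok <- !is.na(calc)
  resid <- (calc[ok] - table$exp_value[ok]) / table$exp_error[ok]
  cls <- table$class[ok]
  by_class <- do.call(rbind, lapply(unique(cls), function(cl) {
    data.frame(class = cl, n = sum(cls == cl),
               chi2 = mean(resid[cls == cl]^2))
  }))
  w <- if (is.null(class_weights)) by_class$n
       else as.numeric(class_weights[by_class$class])
  total <- sum(w * by_class$chi2) / sum(w)
  structure(list(
    total_chi2 = total, by_class = by_class,
    residuals = data.frame(id = table$id[ok], class = cls,
                           calc = calc[ok], exp = table$exp_value[ok],
                           sigma = table$exp_error[ok], residual = resid,
                           stringsAsFactors = FALSE),
    skipped = skipped,
    weighting = if (is.null(class_weights))
      "class weights = observable counts" else "user-supplied class weights"),
    class = "chi2_report")
}

#' @export
print.chi2_report <- function(x, ...) {
  cat("NMR agreement (weighted total chi-square)\n")
  df <- x$by_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-12s n = %3d   chi2 = %.3f\n",
                df$class[i], df$n[i], df$chi2[i]))
  cat(sprintf("  total chi2 = %.3f  (%s)\n", x$total_chi2, x$weighting))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
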