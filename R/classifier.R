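#' Conformational state labels of the UUCG tetraloop
#'
#' The eleven published states, in classifier precedence order (the
#' stem+loop override is evaluated first), plus the explicit `unclassified`
#' label for frames matching no rule.
#'
#' @return character vector of state labels.
#' @export
tl_states <- function() {
  c("native", "sugar_base_N7_lost", "bph7_lost", "both_sugar_base_lost",
    "C8_bulge_one_sugar_base_lost", "G9_bulge_syn", "G9_bulge_anti",
    "G9_back_in_pocket_anti", "U6U7C8_bulge", "loop_disrupted",
    "stem_loop_disrupted", "unclassified")
}

#' Classifier configuration
#'
#' Distance thresholds (Angstrom), RMSD cutoffs (Angstrom) and the
#' glycosidic syn window (degrees) of the published clustering criteria.
#' All printed `<` / `>` comparisons are applied strictly; equality falls
#' through to later rules.
#'
#' @param hb hydrogen-bond donor-acceptor cutoff (default 3.5).
#' @param bph_native native 7BPh (C8 N4 - U6 pro-R_P) cutoff (default 3.7).
#' @param n7_relaxed relaxed U7 O2'-G9 N7 cutoff in the 7BPh-lost rule
#'   (default 4.0).
#' @param bph_back 7BPh cutoff in the back-in-pocket rule (default 4.2).
#' @param far "contact clearly lost" cutoff (default 5.0).
#' @param n1_back G9 N1 - U6 O2 cutoff in the back-in-pocket rule
#'   (default 5.2).
#' @param rmsd_loop_cut loop heavy-atom RMSD cutoff (default 3.0).
#' @param rmsd_all_cut all heavy-atom RMSD cutoff of the stem+loop override
#'   (default 4.6).
#' @param syn window of the glycosidic torsion counted as syn
#'   (default \[-25, 115\] degrees, closed); anti is its exact complement.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(hb = 3.5, bph_native = 3.7, n7_relaxed = 4.0,
                              bph_back = 4.2, far = 5.0, n1_back = 5.2,
                              rmsd_loop_cut = 3.0, rmsd_all_cut = 4.6,
                              syn = syn_window()) {
  stopifnot(hb < bph_native, bph_native < n7_relaxed, n7_relaxed < bph_back,
            bph_back < far, far < n1_back, hb > 0,
            rmsd_loop_cut > 0, rmsd_all_cut > 0)
  structure(list(hb = hb, bph_native = bph_native, n7_relaxed = n7_relaxed,
                 bph_back = bph_back, far = far, n1_back = n1_back,
                 rmsd_loop_cut = rmsd_loop_cut, rmsd_all_cut = rmsd_all_cut,
                 syn = syn),
            class = "classifier_config")
}

#' Extract the classifier's geometric features from one frame
#'
#' Computes the five monitored donor-acceptor heavy-atom distances, the G9
#' glycosidic torsion chi (O4'-C1'-N9-C4) and the superposition RMSDs of
#' the loop heavy atoms and of all heavy atoms against the reference
#' (starting/native) structure.
#'
#' @param conf frame to analyze, a [conformation()].
#' @param map an [default_atom_map()]-style atom map.
#' @param reference reference conformation for the RMSD features.
#' @return named list of class `geometric_features` with elements
#'   `d_N1_O2`, `d_N2_O2`, `d_O2p6_O6`, `d_O2p7_N7`, `d_N4_proRP`,
#'   `chi_G9`, `rmsd_loop`, `rmsd_all`.
#' @export
extract_features <- function(conf, map = default_atom_map(),
                             reference = conf) {
  f <- list(
    d_N1_O2   = conf_distance(conf, map$G9_N1, map$U6_O2),
    d_N2_O2   = conf_distance(conf, map$G9_N2, map$U6_O2),
    d_O2p6_O6 = conf_distance(conf, map$U6_O2p, map$G9_O6),
    d_O2p7_N7 = conf_distance(conf, map$U7_O2p, map$G9_N7),
    d_N4_proRP = conf_distance(conf, map$C8_N4, map$U6_proRP),
    chi_G9 = conf_dihedral(conf, map$G9_O4p, map$G9_C1p, map$G9_N9,
                           map$G9_C4),
    rmsd_loop = superpose_rmsd(conf, reference, resid = map$loop_resid),
    rmsd_all = superpose_rmsd(conf, reference, resid = map$all_resid))
  class(f) <- "geometric_features"
  f
}

#' Classify one frame into a conformational state
#'
#' Applies the published clustering criteria in a fixed precedence order:
#' the stem+loop-disrupted override first (all-heavy-atom RMSD > 4.6 A
#' overrides every other definition), then the states from least to most
#' disrupted, then loop-disrupted (which by construction never captures a
#' frame matching the U6+U7+C8-bulge rule), and finally the explicit
#' `unclassified` label for the regions of feature space the printed
#' criteria do not cover.
#'
#' @param f features from [extract_features()] (any named list with the
#'   same fields works).
#' @param cfg a [classifier_config()].
#' @return a single state label (see [tl_states()]).
#' @export
classify_frame <- function(f, cfg = classifier_config()) {
  syn <- in_window(f$chi_G9, cfg$syn)
  n1 <- f$d_N1_O2 < cfg$hb
  n2 <- f$d_N2_O2 < cfg$hb
  o6 <- f$d_O2p6_O6
  n7 <- f$d_O2p7_N7
  bph <- f$d_N4_proRP

  if (f$rmsd_all > cfg$rmsd_all_cut) return("stem_loop_disrupted")
  if (n1 && o6 < cfg$hb && n7 < cfg$hb && bph < cfg$bph_native && syn)
    return("native")
  if ((n1 || n2) && o6 < cfg$hb && n7 > cfg$hb && bph < cfg$bph_native && syn)
    return("sugar_base_N7_lost")
  if ((n1 || n2) && o6 < cfg$hb && n7 < cfg$n7_relaxed &&
      bph > cfg$bph_native && syn)
    return("bph7_lost")
  if ((n1 || n2) && o6 > cfg$hb && n7 > cfg$hb && bph < cfg$bph_native && syn)
    return("both_sugar_base_lost")
  if ((n1 || n2) && (o6 > cfg$hb || n7 > cfg$hb) && bph > cfg$far && syn)
    return("C8_bulge_one_sugar_base_lost")
  if (f$d_N1_O2 > cfg$far && o6 > cfg$far && syn &&
      f$rmsd_loop < cfg$rmsd_loop_cut)
    return("G9_bulge_syn")
  if (f$d_N1_O2 > cfg$far && o6 > cfg$far && !syn &&
      f$rmsd_loop < cfg$rmsd_loop_cut)
    return("G9_bulge_anti")
  if (f$d_N1_O2 < cfg$n1_back && (o6 < cfg$bph_native || bph < cfg$bph_back) &&
      !syn && f$rmsd_loop < cfg$rmsd_loop_cut)
    return("G9_back_in_pocket_anti")
  if (f$d_N1_O2 > cfg$far && (o6 < cfg$n7_relaxed || n7 < cfg$n7_relaxed) &&
      bph > cfg$far && syn)
    return("U6U7C8_bulge")
  if (f$rmsd_loop > cfg$rmsd_loop_cut) return("loop_disrupted")
  "unclassified"
}

#' Classify every frame of a trajectory
#'
#' Runs [extract_features()] and [classify_frame()] over a list of frames
#' and aggregates weighted state populations.
#'
#' @param frames list of [conformation()] frames.
#' @param map atom map (see [default_atom_map()]).
#' @param reference reference conformation for RMSD features.
#' @param cfg a [classifier_config()].
#' @param weights optional per-frame weights > 0 (default 1; e.g.
#'   unbiasing factors of a biased ensemble).
#' @param times optional per-frame times.
#' @return object of class `state_timeline`: a data frame with columns
#'   `frame`, `time`, `state`, `weight` and the eight feature columns, with
#'   a `populations` attribute (named weighted fractions summing to 1).
#' @export
classify_trajectory <- function(frames, map = default_atom_map(),
                                reference = frames[[1]],
                                cfg = classifier_config(),
                                weights = NULL, times = NULL) {
  n <- length(frames)
  stopifnot(n >= 1)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(times)) times <- seq_len(n) - 1
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights > 0),
            length(times) == n)
  feats <- lapply(frames, extract_features, map = map, reference = reference)
  fm <- do.call(rbind, lapply(feats, function(f) as.data.frame(unclass(f))))
  states <- vapply(feats, classify_frame, character(1), cfg = cfg)
  out <- data.frame(frame = seq_len(n), time = times, state = states,
                    weight = weights, fm, stringsAsFactors = FALSE)
  class(out) <- c("state_timeline", "data.frame")
  attr(out, "populations") <- timeline_populations(out)
  attr(out, "config") <- cfg
  out
}

#' Weighted state populations of a timeline
#'
#' @param timeline a `state_timeline` (or any data frame with `state` and
#'   `weight` columns).
#' @return named numeric vector of weighted fractions over the observed
#'   states; sums to 1.
#' @export
timeline_populations <- function(timeline) {
  w <- tapply(timeline$weight, timeline$state, sum)
  p <- as.numeric(w) / sum(timeline$weight)
  names(p) <- names(w)
  p
}

#' Per-state loop-RMSD statistics
#'
#' Mean and population standard deviation (divisor n) of the loop RMSD for
#' every state observed in a timeline, the summary reported alongside the
#' state definitions.
#'
#' @param timeline a `state_timeline`.
#' @param rmsd optional numeric series overriding `timeline$rmsd_loop`.
#' @return data frame with columns `state`, `n`, `mean`, `sd`.
#' @export
state_rmsd_stats <- function(timeline, rmsd = timeline$rmsd_loop) {
  stopifnot(length(rmsd) == nrow(timeline))
  states <- unique(timeline$state)
  res <- lapply(states, function(s) {
    x <- rmsd[timeline$state == s]
    data.frame(state = s, n = length(x), mean = mean(x),
               sd = sqrt(mean((x - mean(x))^2)))
  })
  do.call(rbind, res)
}

#' @export
print.state_timeline <- function(x, ...) {
  cat("<state_timeline> ", nrow(x), " frames\n", sep = "")
  p <- attr(x, "populations")
  print(round(p[order(-p)], 4))
  invisible(x)
}

#' @export
summary.state_timeline <- function(object, ...) {
  list(n_frames = nrow(object),
       populations = attr(object, "populations"),
       rmsd_stats = state_rmsd_stats(object))
}

#' @export
plot.state_timeline <- function(x, ...) {
  lev <- tl_states()
  idx <- match(x$state, lev)
  graphics::plot(x$time, idx, pch = 16, cex = 0.4, yaxt = "n",
                 xlab = "time", ylab = "", ...)
  graphics::axis(2, at = seq_along(lev), labels = lev, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}
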