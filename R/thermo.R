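#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 0.0019872

#' Two-state folding free energy from a folded population
#'
#' dG_fold = -R T ln(p / (1 - p)) with R = 0.0019872 kcal/(mol K); negative
#' when the folded state is the majority. Antisymmetric about p = 0.5.
#'
#' @param p folded fraction, strictly between 0 and 1.
#' @param temperature temperature in Kelvin (default 298).
#' @return free energy in kcal/mol.
#' @export
population_to_dG <- function(p, temperature = 298) {
  if (any(p <= 0 | p >= 1))
    stop(errorCondition(
      "unbounded estimate: population at 0 or 1 gives infinite dG; only a bound can be reported",
      class = c("tetrafold_unbounded_estimate", "error", "condition")))
  -R_KCAL * temperature * log(p / (1 - p))
}

#' Folded population from a folding free energy
#'
#' Inverse of [population_to_dG()]: p = 1 / (1 + exp(dG / (R T))).
#'
#' @param dG free energy in kcal/mol.
#' @param temperature temperature in Kelvin (default 298).
#' @return fraction in (0, 1).
#' @export
dG_to_population <- function(dG, temperature = 298) {
  1 / (1 + exp(dG / (R_KCAL * temperature)))
}

## Contiguous block boundaries: n frames into n_blocks equal blocks,
## remainder frames going to the last block.
block_index <- function(n, n_blocks) {
  size <- n %/% n_blocks
  idx <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_blocks)
  idx
}

#' Folding free-energy estimate with block-bootstrap errors
#'
#' The central estimator of the package. The per-frame folded indicator
#' (optionally weighted, e.g. by unbiasing factors of a biased ensemble;
#' optionally split into independent runs that are concatenated) gives the
#' point estimate of the folded population; statistical errors come from a
#' circular-free block bootstrap: the concatenated series is cut into
#' `n_blocks` contiguous equal blocks, blocks are resampled with
#' replacement `n_resamples` times, and the 2.5/97.5 percentiles of the
#' resampled populations give the population bounds, mapped through the
#' two-state relation to a free-energy interval.
#'
#' @param indicator logical (or 0/1) vector: folded per frame.
#' @param weights per-frame weights > 0 (default 1).
#' @param runs optional run identifier per frame; runs are concatenated in
#'   order of first appearance before blocking.
#' @param n_blocks number of bootstrap blocks (default 16).
#' @param n_resamples bootstrap resamples (default 1000).
#' @param temperature Kelvin (default 298).
#' @param seed optional integer seed making the resampling reproducible.
#' @return object of class `dgfold` with elements `p_native`, `dG`,
#'   `p_lo`, `p_hi`, `p_se`, `dG_lo`, `dG_hi`, `dG_err`, `temperature`,
#'   `n_frames`, `n_blocks`, `n_resamples`, and `interval` metadata naming
#'   the percentile convention.
#' @seealso [population_to_dG()], [aggregate_runs()]
#' @export
dg_fold <- function(indicator, weights = NULL, runs = NULL, n_blocks = 16,
                    n_resamples = 1000, temperature = 298, seed = NULL) {
  ind <- as.logical(indicator)
  n <- length(ind)
  stopifnot(n >= n_blocks, !anyNA(ind))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(is.finite(weights)), all(weights > 0))
  if (!is.null(runs)) {
    ord <- order(match(runs, unique(runs)))
    ind <- ind[ord]; weights <- weights[ord]
  }
  p_hat <- sum(weights * ind) / sum(weights)

  blk <- block_index(n, n_blocks)
  fold_sum <- as.numeric(tapply(weights * ind, blk, sum))
  w_sum <- as.numeric(tapply(weights, blk, sum))
  p_boot <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      sum(fold_sum[pick]) / sum(w_sum[pick])
    }, numeric(1))
  })
  qs <- stats::quantile(p_boot, c(0.025, 0.975), names = FALSE, type = 7)

  safe_dG <- function(p) {
    if (p <= 0) Inf else if (p >= 1) -Inf
    else population_to_dG(p, temperature)
  }
  dG <- safe_dG(p_hat)
  dG_lo <- safe_dG(qs[2])   # high population -> low dG
  dG_hi <- safe_dG(qs[1])
  if (p_hat <= 0 || p_hat >= 1)
    warning("population at ", p_hat,
            ": dG unbounded, reporting the bound only", call. = FALSE)
  structure(list(
    p_native = p_hat, dG = dG,
    p_lo = qs[1], p_hi = qs[2], p_se = stats::sd(p_boot),
    dG_lo = dG_lo, dG_hi = dG_hi,
    dG_err = if (is.finite(dG_lo) && is.finite(dG_hi))
      (dG_hi - dG_lo) / 2 else Inf,
    temperature = temperature, n_frames = n, n_blocks = n_blocks,
    n_resamples = n_resamples,
    interval = "percentile 2.5/97.5 of block-bootstrap populations"),
    class = "dgfold")
}

#' @export
print.dgfold <- function(x, ...) {
  cat("Two-state folding free energy (block bootstrap)\n")
  cat(sprintf("  p_native = %.4f  [%.4f, %.4f]  (n = %d frames, %d blocks)\n",
              x$p_native, x$p_lo, x$p_hi, x$n_frames, x$n_blocks))
  cat(sprintf("  dG_fold  = %.2f kcal/mol  [%.2f, %.2f]  at T = %g K\n",
              x$dG, x$dG_lo, x$dG_hi, x$temperature))
  invisible(x)
}

#' @export
summary.dgfold <- function(object, ...) {
  c(p_native = object$p_native, p_lo = object$p_lo, p_hi = object$p_hi,
    p_se = object$p_se, dG = object$dG, dG_lo = object$dG_lo,
    dG_hi = object$dG_hi, dG_err = object$dG_err,
    temperature = object$temperature)
}

#' @export
coef.dgfold <- function(object, ...) {
  c(p_native = object$p_native, dG = object$dG)
}

#' @export
confint.dgfold <- function(object, parm = "dG", level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% percentile interval is computed", call. = FALSE)
  out <- rbind(p_native = c(object$p_lo, object$p_hi),
               dG = c(object$dG_lo, object$dG_hi))
  colnames(out) <- c("2.5 %", "97.5 %")
  out[parm, , drop = FALSE]
}

#' Average folding free energies over independent simulations
#'
#' Arithmetic mean and sample standard deviation of per-run dG values, the
#' convention used to combine the three independent runs of each force
#' field.
#'
#' @param per_run_dG numeric vector of at least two per-run values
#'   (kcal/mol).
#' @return list with `mean` and `sd` (kcal/mol).
#' @export
aggregate_runs <- function(per_run_dG) {
  stopifnot(is.numeric(per_run_dG), length(per_run_dG) >= 2)
  list(mean = mean(per_run_dG), sd = stats::sd(per_run_dG))
}

#' Count folding events
#'
#' Number of unfolded-to-folded (FALSE to TRUE) transitions along a
#' continuous (demultiplexed) replica.
#'
#' @param indicator logical vector, folded per frame.
#' @return integer count.
#' @export
count_folding_events <- function(indicator) {
  ind <- as.logical(indicator)
  n <- length(ind)
  stopifnot(n >= 1, !anyNA(ind))
  if (n == 1) return(0L)
  sum(ind[-1] & !ind[-n])
}
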