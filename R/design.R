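# Study designs: the sampling grids of the acute (bolus) and chronic
# (infusion) MPL rat studies, or user-specified variants.

# canonical sacrifice grids (hours).  Acute: 17 timepoints over 0-72 h, dense
# in the first 12 h where MPL PK is fast (drug clears in ~10 h); chronic: 11
# timepoints over ~7 days.
.acute_grid <- c(0, 0.25, 0.5, 0.75, 1, 2, 4, 5, 5.5, 7, 8, 12, 18, 24, 30, 48, 72)
.chronic_grid <- c(0, 6, 10, 13, 18, 24, 36, 48, 72, 96, 170)

#' Construct a study design (time grid + replicate structure)
#'
#' The defaults reproduce the two canonical rat sacrifice designs: acute
#' bolus dosing with 17 timepoints from 0 to 72 h (n = 2-4 animals per
#' timepoint) and chronic infusion with 11 timepoints over about 7 days.
#' Non-default grids are spaced quadratically (dense early), matching the
#' fast initial PK of an intravenous dose.
#'
#' @param regimen_label `"acute"` or `"chronic"`.
#' @param n_timepoints number of sacrifice timepoints (>= 3).
#' @param horizon_h study horizon in hours (> 0).
#' @param replicates replicate animals per timepoint: a single integer, a
#'   vector of length `n_timepoints`, or `NULL` to draw counts seeded by
#'   `seed` (2-4 for acute, 3-4 for chronic, as in the original studies).
#' @param seed integer seed used only when `replicates` is `NULL`.
#' @return an object of class `study_design`: list with `regimen_label`,
#'   `timepoints_h` (strictly increasing, first >= 0) and
#'   `replicates_per_timepoint`.
#' @export
#' @examples
#' make_design("acute", 17, 72, replicates = 3, seed = 1)
make_design <- function(regimen_label = c("acute", "chronic"),
                        n_timepoints = if (regimen_label[1] == "acute") 17L else 11L,
                        horizon_h = if (regimen_label[1] == "acute") 72 else 170,
                        replicates = NULL, seed = 1L) {
  regimen_label <- match.arg(regimen_label)
  if (!is.numeric(n_timepoints) || length(n_timepoints) != 1 || n_timepoints < 3)
    paldyn_stop("paldyn_invalid_design", "need at least 3 timepoints")
  if (!is.numeric(horizon_h) || length(horizon_h) != 1 || horizon_h <= 0)
    paldyn_stop("paldyn_invalid_design", "study horizon must be positive")
  n_timepoints <- as.integer(n_timepoints)

  tp <- if (regimen_label == "acute" && n_timepoints == 17L && horizon_h == 72) {
    .acute_grid
  } else if (regimen_label == "chronic" && n_timepoints == 11L && horizon_h == 170) {
    .chronic_grid
  } else {
    horizon_h * seq(0, 1, length.out = n_timepoints)^2
  }

  if (is.null(replicates)) {
    pool <- if (regimen_label == "acute") 2:4 else 3:4
    replicates <- with_seed(seed,
      sample(pool, n_timepoints, replace = TRUE))
  } else if (length(replicates) == 1) {
    replicates <- rep(as.integer(replicates), n_timepoints)
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != n_timepoints || any(replicates < 1))
    paldyn_stop("paldyn_invalid_design",
                "replicates must be length-", n_timepoints, " positive integers")
  stopifnot(all(diff(tp) > 0), tp[1] >= 0)

  structure(list(regimen_label = regimen_label,
                 timepoints_h = tp,
                 replicates_per_timepoint = replicates),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s: %d timepoints over [%g, %g] h, %d animals\n",
              x$regimen_label, length(x$timepoints_h),
              min(x$timepoints_h), max(x$timepoints_h),
              sum(x$replicates_per_timepoint)))
  invisible(x)
}
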