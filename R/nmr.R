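# PHBV copolymer composition from 1H-NMR methine peak integrals, and PHA
# mass content. Each monomer backbone carries exactly one methine proton,
# so the 3HV mole fraction equals the 3HV methine area over the total
# methine area.

#' Methine integration windows
#'
#' Chemical-shift windows (ppm) used to assign methine peaks. Defaults
#' follow the standard PHBV 1H-NMR assignments in CDCl3: the 3HB methine
#' multiplet near 5.25 ppm and the 3HV methine near 5.16 ppm. Windows are
#' half-open `[lo, hi)` and must not overlap.
#'
#' @param hb Numeric length-2 window for the 3HB methine
#'   (default `c(5.20, 5.30)`).
#' @param hv Numeric length-2 window for the 3HV methine
#'   (default `c(5.10, 5.20)`).
#' @return A named list of windows.
#' @export
methine_windows <- function(hb = c(5.20, 5.30), hv = c(5.10, 5.20)) {
  stopifnot(length(hb) == 2L, length(hv) == 2L, hb[1] < hb[2], hv[1] < hv[2])
  if (max(hb[1], hv[1]) < min(hb[2], hv[2])) {
    stop("methine windows overlap", call. = FALSE)
  }
  list(hb = as.numeric(hb), hv = as.numeric(hv))
}

#' Assign methine peaks
#'
#' Labels each peak by the window containing its chemical shift:
#' `3HB_methine`, `3HV_methine`, or `unassigned`. Multiple peaks inside a
#' window are summed by downstream composition calculations.
#'
#' @param peaks `data.frame` with columns `shift_ppm` and `integral`.
#' @param windows Windows from [methine_windows()].
#' @return `peaks` with an `assignment` column added.
#' @export
assign_methine_peaks <- function(peaks, windows = methine_windows()) {
  stopifnot(all(c("shift_ppm", "integral") %in% names(peaks)))
  if (any(peaks$integral < 0)) stop("negative peak integral", call. = FALSE)
  in_win <- function(x, w) x >= w[1] & x < w[2]
  peaks$assignment <- rep("unassigned", nrow(peaks))
  peaks$assignment[in_win(peaks$shift_ppm, windows$hb)] <- "3HB_methine"
  peaks$assignment[in_win(peaks$shift_ppm, windows$hv)] <- "3HV_methine"
  peaks
}

#' 3HV mole percent from methine integrals
#'
#' `%3HV = 100 * I_V / (I_B + I_V)` where `I_B` and `I_V` are the 3HB and
#' 3HV methine peak areas. Because each monomer contributes one methine
#' proton, this is a mole percent. `%3HB` is its complement, so the two
#' always sum to exactly 100.
#'
#' @param I_B 3HB methine integral (>= 0).
#' @param I_V 3HV methine integral (>= 0).
#' @return A list of class `composition_result`: `hv_mol_percent`,
#'   `hb_mol_percent`, `I_B`, `I_V`.
#' @export
hv_mol_percent <- function(I_B, I_V) {
  if (I_B < 0 || I_V < 0) stop("negative methine integral", call. = FALSE)
  if (I_B + I_V == 0) stop("no methine signal", call. = FALSE)
  hv <- 100 * I_V / (I_B + I_V)
  structure(list(hv_mol_percent = hv, hb_mol_percent = 100 - hv,
                 I_B = I_B, I_V = I_V),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("PHBV composition: %.1f%% 3HV / %.1f%% 3HB (I_V = %.3g, I_B = %.3g)\n",
              x$hv_mol_percent, x$hb_mol_percent, x$I_V, x$I_B))
  invisible(x)
}

#' Composition from a peak list
#'
#' Convenience wrapper: assigns peaks to methine windows, sums the
#' integrals per assignment, and computes the 3HV mole percent.
#'
#' @inheritParams assign_methine_peaks
#' @return A `composition_result`.
#' @export
composition_from_peaks <- function(peaks, windows = methine_windows()) {
  assigned <- assign_methine_peaks(peaks, windows)
  I_B <- sum(assigned$integral[assigned$assignment == "3HB_methine"])
  I_V <- sum(assigned$integral[assigned$assignment == "3HV_methine"])
  hv_mol_percent(I_B, I_V)
}

#' PHA content as percent of cell dry weight
#'
#' @param lyophilized_mass Cell dry weight (mg), > 0.
#' @param polymer_mass Extracted polymer mass (mg), in
#'   `[0, lyophilized_mass]`.
#' @return PHA content percent.
#' @export
pha_content_percent <- function(lyophilized_mass, polymer_mass) {
  if (lyophilized_mass <= 0) stop("lyophilized mass must be > 0",
                                  call. = FALSE)
  if (polymer_mass < 0 || polymer_mass > lyophilized_mass) {
    stop("polymer mass must lie in [0, lyophilized mass]", call. = FALSE)
  }
  100 * polymer_mass / lyophilized_mass
}
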