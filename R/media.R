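# Elemental C/N/P balances of defined cultivation media. A recipe lists
# each component's concentration (mM) and its assimilable carbon,
# nitrogen and phosphorus atom counts; the C/N/P ratio is the elemental
# sum normalized to phosphorus.

#' Atomic mass sets for C/N/P ratios
#'
#' Two conventions: `"iupac"` uses standard atomic masses (C 12.011,
#' N 14.007, P 30.974); `"p32"` references phosphorus at 32 g/mol, a
#' rounding convention under which the commonly printed mass ratios of
#' haloarchaeal defined media are reproduced to about 0.1.
#'
#' @param set `"iupac"` or `"p32"`.
#' @return Named numeric vector with elements `C`, `N`, `P`.
#' @export
cnp_mass_set <- function(set = c("iupac", "p32")) {
  set <- match.arg(set)
  switch(set,
         iupac = c(C = 12.011, N = 14.007, P = 30.974),
         p32 = c(C = 12.011, N = 14.007, P = 32.0))
}

#' Build a medium recipe table
#'
#' @param component Component names.
#' @param concentration_mM Concentrations in mM (>= 0). Use
#'   [gl_to_mM()] to convert g/l inputs.
#' @param C,N,P Assimilable atom counts per formula unit (non-negative).
#' @return A `data.frame` of class `medium_recipe`.
#' @export
medium_recipe <- function(component, concentration_mM, C = 0, N = 0, P = 0) {
  n <- length(component)
  rec <- data.frame(component = component,
                    concentration_mM = as.numeric(concentration_mM),
                    C = rep_len(C, n), N = rep_len(N, n), P = rep_len(P, n),
                    stringsAsFactors = FALSE)
  if (any(rec$concentration_mM < 0)) stop("negative concentration",
                                          call. = FALSE)
  if (any(rec$C < 0 | rec$N < 0 | rec$P < 0)) {
    stop("negative element count", call. = FALSE)
  }
  class(rec) <- c("medium_recipe", "data.frame")
  rec
}

#' Convert g/l to mM
#'
#' @param g_per_l Concentration in g/l.
#' @param molar_mass Molar mass in g/mol (required; an error otherwise).
#' @return Concentration in mM.
#' @export
gl_to_mM <- function(g_per_l, molar_mass) {
  if (missing(molar_mass) || is.null(molar_mass) || !is.finite(molar_mass)) {
    stop("g/l concentration requires a molar mass", call. = FALSE)
  }
  1000 * g_per_l / molar_mass
}

# Defined-medium base for Haloferax: salts, phosphate, ammonium and trace
# vitamins. Tris buffer and mineral salts carry zero assimilable C/N/P
# counts by convention (the buffer is not a carbon/nitrogen source);
# thiamine (C12N4) and biotin (C10N2) are included even though their
# contribution is < 0.1%.
haloferax_base_components <- function() {
  medium_recipe(
    component = c("Tris-HCl", "NaCl", "MgCl2", "MgSO4", "KCl", "NH4Cl",
                  "CaCl2", "K2HPO4", "KH2PO4", "MnCl2", "ZnSO4", "FeSO4",
                  "CuSO4", "thiamine", "biotin"),
    concentration_mM = c(15.9, 2600, 93.8, 90.3, 60, 5.3, 6.4, 0.6, 0.4,
                         0.0019, 0.0016, 0.0088, 0.0002, 0.0032, 0.0004),
    C = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 12, 10),
    N = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 4, 2),
    P = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
}

rbind_recipe <- function(...) {
  rec <- do.call(rbind, lapply(list(...), as.data.frame))
  class(rec) <- c("medium_recipe", "data.frame")
  rec
}

#' Hv-min defined medium
#'
#' Minimal medium with a mixed carbon source: 32.0 mM dl-lactate (C3),
#' 3.7 mM glycerol (C3) and 15.0 mM succinate (C4), on the Haloferax
#' salt/phosphate/vitamin base. Optionally supplemented with valeric acid
#' (C5, molar mass 102.13 g/mol).
#'
#' @param valeric_acid_g_l Valeric acid supplementation in g/l
#'   (default 0).
#' @return A `medium_recipe`.
#' @export
hv_min_medium <- function(valeric_acid_g_l = 0) {
  rec <- rbind_recipe(
    haloferax_base_components(),
    medium_recipe(c("sodium dl-lactate", "glycerol", "sodium succinate"),
                  c(32.0, 3.7, 15.0), C = c(3, 3, 4)))
  if (valeric_acid_g_l > 0) {
    rec <- rbind_recipe(
      rec,
      medium_recipe("valeric acid", gl_to_mM(valeric_acid_g_l, 102.13),
                    C = 5))
  }
  rec
}

#' Glycerol defined medium
#'
#' Same base as [hv_min_medium()] but with 74.2 mM glycerol as sole
#' carbon source.
#'
#' @return A `medium_recipe`.
#' @export
glycerol_medium <- function() {
  rbind_recipe(haloferax_base_components(),
               medium_recipe("glycerol", 74.2, C = 3))
}

#' Elemental C/N/P ratio of a medium
#'
#' Sums millimoles of carbon, nitrogen and phosphorus per litre from the
#' recipe (concentration times atom count per component). On the molar
#' basis the mole ratio is returned normalized to P = 1; on the mass
#' basis (the default, matching how such ratios are customarily printed)
#' each element is multiplied by its atomic mass first.
#'
#' @param recipe A `medium_recipe`.
#' @param basis `"mass"` (default) or `"molar"`.
#' @param masses Atomic masses from [cnp_mass_set()]; only used on the
#'   mass basis.
#' @return Named numeric vector `c(C =, N =, P = 1)`.
#' @export
cnp_ratio <- function(recipe, basis = c("mass", "molar"),
                      masses = cnp_mass_set("iupac")) {
  basis <- match.arg(basis)
  mmol <- c(C = sum(recipe$concentration_mM * recipe$C),
            N = sum(recipe$concentration_mM * recipe$N),
            P = sum(recipe$concentration_mM * recipe$P))
  if (mmol[["P"]] == 0) stop("recipe contains no phosphorus", call. = FALSE)
  amount <- if (basis == "mass") mmol * masses[c("C", "N", "P")] else mmol
  out <- amount / amount[["P"]]
  names(out) <- c("C", "N", "P")
  out
}

#' Total elemental millimoles of a recipe
#'
#' @param recipe A `medium_recipe`.
#' @return Named vector of mmol/l of `C`, `N`, `P`.
#' @export
cnp_mmol <- function(recipe) {
  c(C = sum(recipe$concentration_mM * recipe$C),
    N = sum(recipe$concentration_mM * recipe$N),
    P = sum(recipe$concentration_mM * recipe$P))
}
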