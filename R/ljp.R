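# Liquid junction potentials by the Henderson equation, with a recipe
# dissociation helper so solutions can be entered the way methods sections
# print them (salt millimolarities plus a pH-adjusting base).

#' Limiting relative ionic mobilities
#'
#' Mechanical mobilities of common electrophysiology ions relative to K+,
#' derived from limiting equivalent conductances at infinite dilution
#' (u_rel = lambda_eq / (|z| * lambda_eq(K+))), the convention used by
#' standard junction-potential calculators. Values for small inorganic ions
#' follow conductivity tables; large organic polyanions (EGTA, nucleotide
#' di-anions, phosphocreatine) are assigned class values typical of anions
#' of their size, which at the few-mM level where they occur shifts computed
#' junction potentials by well under 1 mV.
#'
#' @format Data frame with columns `species`, `z` (signed valence), and
#'   `mobility` (dimensionless, K+ = 1).
#' @export
ion_mobility_table <- function() {
  tab <- rbind(
    data.frame(species = "H",        z =  1, mobility = 4.757),
    data.frame(species = "Li",       z =  1, mobility = 0.526),
    data.frame(species = "Na",       z =  1, mobility = 0.682),
    data.frame(species = "K",        z =  1, mobility = 1.000),
    data.frame(species = "Rb",       z =  1, mobility = 1.059),
    data.frame(species = "Cs",       z =  1, mobility = 1.050),
    data.frame(species = "NH4",      z =  1, mobility = 1.000),
    data.frame(species = "TMA",      z =  1, mobility = 0.611),
    data.frame(species = "TEA",      z =  1, mobility = 0.444),
    data.frame(species = "Tris",     z =  1, mobility = 0.402),
    data.frame(species = "choline",  z =  1, mobility = 0.508),
    data.frame(species = "Mg",       z =  2, mobility = 0.361),
    data.frame(species = "Ca",       z =  2, mobility = 0.4048),
    data.frame(species = "Ba",       z =  2, mobility = 0.4329),
    data.frame(species = "Cd",       z =  2, mobility = 0.367),
    data.frame(species = "Zn",       z =  2, mobility = 0.359),
    data.frame(species = "Cl",       z = -1, mobility = 1.0388),
    data.frame(species = "Br",       z = -1, mobility = 1.0625),
    data.frame(species = "I",        z = -1, mobility = 1.0453),
    data.frame(species = "F",        z = -1, mobility = 0.7533),
    data.frame(species = "NO3",      z = -1, mobility = 0.9721),
    data.frame(species = "HCO3",     z = -1, mobility = 0.6054),
    data.frame(species = "H2PO4",    z = -1, mobility = 0.4490),
    data.frame(species = "HPO4",     z = -2, mobility = 0.3880),
    data.frame(species = "SO4",      z = -2, mobility = 0.5442),
    data.frame(species = "acetate",  z = -1, mobility = 0.5564),
    data.frame(species = "gluconate",z = -1, mobility = 0.3300),
    data.frame(species = "isethionate", z = -1, mobility = 0.5200),
    data.frame(species = "methanesulfonate", z = -1, mobility = 0.6600),
    data.frame(species = "HEPES",    z = -1, mobility = 0.3000),
    data.frame(species = "MES",      z = -1, mobility = 0.3700),
    data.frame(species = "EGTA",     z = -2, mobility = 0.2400),
    data.frame(species = "ATP",      z = -2, mobility = 0.2400),
    data.frame(species = "GTP",      z = -2, mobility = 0.2200),
    data.frame(species = "phosphocreatine", z = -2, mobility = 0.3000))
  rownames(tab) <- NULL
  tab
}

#' Construct an ionic solution composition
#'
#' @param species Character vector of ionic species names (must appear in
#'   [ion_mobility_table()]).
#' @param conc Concentrations (mM), same length, all >= 0.
#' @param check_balance Verify electroneutrality: net charge imbalance must
#'   be below 5% of total ionic strength (guards against recipes whose salts
#'   were dissociated incorrectly).
#' @return Object of class `solution_composition`: data frame with columns
#'   `species`, `z`, `conc`, `mobility`.
#' @export
solution_composition <- function(species, conc, check_balance = TRUE) {
  stopifnot(length(species) == length(conc))
  if (length(species) == 0) stop("solution_composition: empty solution")
  if (any(conc < 0)) stop("solution_composition: concentrations must be >= 0")
  tab <- ion_mobility_table()
  idx <- match(species, tab$species)
  if (anyNA(idx))
    stop("solution_composition: no tabulated mobility for species: ",
         paste(species[is.na(idx)], collapse = ", "))
  out <- data.frame(species = species, z = tab$z[idx], conc = conc,
                    mobility = tab$mobility[idx])
  # merge duplicate species
  agg <- stats::aggregate(conc ~ species + z + mobility, data = out, FUN = sum)
  out <- agg[, c("species", "z", "conc", "mobility")]
  if (check_balance) {
    imbalance <- abs(sum(out$z * out$conc))
    strength  <- 0.5 * sum(out$z^2 * out$conc)
    if (strength > 0 && imbalance > 0.05 * strength)
      stop(sprintf(paste0("solution_composition: net charge imbalance %.1f mM",
                          " exceeds 5%% of ionic strength %.1f mM; check the",
                          " salt dissociation"), imbalance, strength))
  }
  class(out) <- c("solution_composition", "data.frame")
  out
}

# salt -> ionic species stoichiometry; acids are neutralized by the recipe's
# pH base (fraction ionized set by pH for the buffer, full for strong
# chelator/nucleotide acids at physiological pH)
.salt_table <- list(
  "NaCl"  = list(c("Na", 1),  c("Cl", 1)),
  "KCl"   = list(c("K", 1),   c("Cl", 1)),
  "CsCl"  = list(c("Cs", 1),  c("Cl", 1)),
  "LiCl"  = list(c("Li", 1),  c("Cl", 1)),
  "CaCl2" = list(c("Ca", 1),  c("Cl", 2)),
  "MgCl2" = list(c("Mg", 1),  c("Cl", 2)),
  "BaCl2" = list(c("Ba", 1),  c("Cl", 2)),
  "CdCl2" = list(c("Cd", 1),  c("Cl", 2)),
  "TEA-Cl" = list(c("TEA", 1), c("Cl", 1)),
  "TEACl" = list(c("TEA", 1), c("Cl", 1)),
  "TEA"   = list(c("TEA", 1), c("Cl", 1)),   # bare TEA read as chloride salt
  "K-gluconate"  = list(c("K", 1),  c("gluconate", 1)),
  "Na-isethionate" = list(c("Na", 1), c("isethionate", 1)),
  "KH2PO4" = list(c("K", 1),  c("H2PO4", 1)),
  "NaH2PO4" = list(c("Na", 1), c("H2PO4", 1)),
  "NaHCO3" = list(c("Na", 1), c("HCO3", 1)),
  "Na2-phosphocreatine" = list(c("Na", 2), c("phosphocreatine", 1)),
  "Mg-ATP" = list(c("Mg", 1), c("ATP", 1)),
  "Na2-ATP" = list(c("Na", 2), c("ATP", 1)))

# weak acids: species, anionic charge equivalents per mole, ionized fraction
# at recording pH (NA = set from pH, HEPES pKa 7.55)
.acid_table <- list(
  "HEPES" = list(species = "HEPES", eq = 1, frac = NA),
  "EGTA"  = list(species = "EGTA", eq = 2, frac = 1),
  "GTP"   = list(species = "GTP", eq = 2, frac = 1),
  "phosphocreatine" = list(species = "phosphocreatine", eq = 2, frac = 1))

.neutral_species <- c("glucose", "D-glucose", "sucrose")

#' Dissociate a printed solution recipe into ionic species
#'
#' Turns a methods-section recipe (named salt millimolarities) into a
#' [solution_composition()]. Strong salts dissociate stoichiometrically;
#' neutral osmolytes (glucose, sucrose) are dropped; bare "TEA" is read as
#' the chloride salt; "EGTA:CsOH" is read as the di-caesium salt. Weak acids
#' contribute their predominant anion at the recording pH: HEPES its
#' mono-anion at the Henderson-Hasselbalch fraction (pKa 7.55), EGTA, GTP
#' and phosphocreatine their di-anions.
#'
#' Two titration conventions are offered. `"printed"` (default) enters each
#' printed component exactly once and does not model the unstated amount of
#' pH-adjusting base; the resulting composition is not charge balanced on
#' paper (the deficit is carried by the unmodeled base and protonated buffer
#' species), which mirrors how recipes are entered into instrument
#' junction-potential calculators and reproduces their output. The
#' `"counterion"` convention adds the base cation equivalents needed to
#' neutralize every acid, yielding a strictly electroneutral composition;
#' it shifts computed junction potentials by roughly +1.5 mV for a
#' K-gluconate internal because of the extra ~25 mM K+.
#'
#' @param recipe Named numeric vector of concentrations (mM), e.g.
#'   `c("K-gluconate" = 140, "NaCl" = 4)`.
#' @param ph_base Cation of the pH-adjusting base: "KOH", "CsOH" or "NaOH".
#' @param ph Recording pH (sets the ionized fraction of HEPES).
#' @param titration `"printed"` or `"counterion"` (see Details).
#' @return A [solution_composition()].
#' @examples
#' dissociate_recipe(c("KCl" = 140), ph_base = "KOH")
#' @export
dissociate_recipe <- function(recipe, ph_base = c("KOH", "CsOH", "NaOH"),
                              ph = 7.25,
                              titration = c("printed", "counterion")) {
  ph_base <- match.arg(ph_base)
  titration <- match.arg(titration)
  base_cation <- c(KOH = "K", CsOH = "Cs", NaOH = "Na")[[ph_base]]
  if (is.null(names(recipe)) || any(names(recipe) == ""))
    stop("dissociate_recipe: recipe must be a fully named numeric vector")
  species <- character(0); conc <- numeric(0)
  add <- function(s, c) {
    species <<- c(species, s); conc <<- c(conc, c)
  }
  for (salt in names(recipe)) {
    mM <- unname(recipe[[salt]])
    if (salt %in% .neutral_species) next
    if (salt == "EGTA:CsOH") {          # printed as the di-caesium salt
      add("EGTA", mM); add("Cs", 2 * mM)
    } else if (!is.null(.salt_table[[salt]])) {
      for (sp in .salt_table[[salt]]) add(sp[[1]], mM * as.numeric(sp[[2]]))
    } else if (!is.null(.acid_table[[salt]])) {
      ac <- .acid_table[[salt]]
      frac <- if (is.na(ac$frac)) 1 / (1 + 10^(7.55 - ph)) else ac$frac
      add(ac$species, mM * frac)
      if (titration == "counterion")
        add(base_cation, mM * frac * ac$eq)
    } else {
      stop("dissociate_recipe: unknown salt '", salt, "'")
    }
  }
  solution_composition(species, conc,
                       check_balance = (titration == "counterion"))
}

#' Liquid junction potential by the Henderson equation
#'
#' Computes the junction potential that develops between the pipette
#' (internal) solution and the bath (external) solution, using the Henderson
#' mixture approximation with limiting relative ionic mobilities. The value
#' returned is the potential of the bath relative to the pipette; with the
#' usual amplifier zeroing this is the amount by which recorded membrane
#' voltages overestimate true voltages, so corrected values are obtained by
#' subtracting it (see [apply_junction_correction()]).
#'
#' @param internal,external [solution_composition()] objects (or recipes
#'   already dissociated via [dissociate_recipe()]).
#' @param temperature Absolute temperature (K), default 295.
#' @return Junction potential in mV.
#' @examples
#' int <- dissociate_recipe(c("KCl" = 140), ph_base = "KOH")
#' ext <- dissociate_recipe(c("NaCl" = 140), ph_base = "NaOH")
#' henderson_ljp(int, ext)
#' @export
henderson_ljp <- function(internal, external, temperature = 295) {
  stopifnot(inherits(internal, "solution_composition"),
            inherits(external, "solution_composition"))
  if (temperature <= 0) stop("henderson_ljp: temperature must be > 0 K")
  sp <- union(internal$species, external$species)
  ca <- setNames(numeric(length(sp)), sp)  # pipette
  cb <- ca                                 # bath
  ca[internal$species] <- internal$conc
  cb[external$species] <- external$conc
  tab <- ion_mobility_table()
  z <- tab$z[match(sp, tab$species)]
  u <- tab$mobility[match(sp, tab$species)]
  s1 <- sum(z * u * (cb - ca))
  s2 <- sum(z^2 * u * (cb - ca))
  la <- sum(z^2 * u * ca)
  lb <- sum(z^2 * u * cb)
  if (la <= 0 || lb <= 0) stop("henderson_ljp: a solution has no ions")
  if (abs(s2) < 1e-12 * (la + lb)) return(0)  # identical ionic profiles
  1000 * .GAS_R * temperature / .FARADAY * (s1 / s2) * log(la / lb)
}

#' Printed solution recipes used by the bundled study configuration
#'
#' Recipes for the recording solutions the package's demo study emulates:
#' the K-gluconate current-clamp internal, the standard bicarbonate ACSF
#' bath, the CsCl-based sodium-channel internal, the reduced-sodium (30 mM
#' Na) external used for whole-cell sodium-current recording, and the
#' high-Cl CsCl internal used for sIPSC recording. Concentrations in mM.
#'
#' @return Named list of recipes, each a named numeric vector plus the pH
#'   base in `attr(, "ph_base")`.
#' @export
study_solution_recipes <- function() {
  r <- list(
    kgluconate_internal = structure(
      c("K-gluconate" = 140, "NaCl" = 4, "CaCl2" = 0.5, "HEPES" = 10,
        "EGTA" = 5, "phosphocreatine" = 5, "Mg-ATP" = 2, "GTP" = 0.4),
      ph_base = "KOH"),
    acsf = structure(
      c("NaCl" = 125, "KCl" = 2.5, "MgCl2" = 1, "KH2PO4" = 1.25,
        "NaHCO3" = 26, "CaCl2" = 2, "D-glucose" = 20),
      ph_base = "NaOH"),
    na_internal = structure(
      c("CsCl" = 115, "CaCl2" = 0.5, "EGTA:CsOH" = 5, "HEPES" = 10,
        "Na2-phosphocreatine" = 5, "TEA" = 20, "Mg-ATP" = 2, "GTP" = 0.4),
      ph_base = "CsOH"),
    na_external = structure(
      c("NaCl" = 30, "BaCl2" = 1, "MgCl2" = 2, "CsCl" = 45, "CdCl2" = 0.2,
        "CaCl2" = 1, "HEPES" = 10, "TEA-Cl" = 20, "D-glucose" = 100),
      ph_base = "CsOH"),
    sipsc_internal = structure(
      c("CsCl" = 135, "NaCl" = 4, "GTP" = 0.4, "Mg-ATP" = 2, "CaCl2" = 0.5,
        "EGTA" = 5, "HEPES" = 10),
      ph_base = "CsOH"))
  r
}

#' Junction potentials for the bundled study solutions
#'
#' Convenience wrapper: dissociates the printed recipes from
#' [study_solution_recipes()] and evaluates the Henderson equation for the
#' three pipette/bath pairings used in the demo study.
#'
#' @param temperature Absolute temperature (K), default 295.
#' @return Named numeric vector (mV): `current_clamp` (K-gluconate vs ACSF),
#'   `na_recording` (CsCl internal vs 30 mM Na external), and
#'   `nucleated_patch` (CsCl internal vs ACSF).
#' @export
study_junction_potentials <- function(temperature = 295) {
  rec <- study_solution_recipes()
  diss <- function(x) dissociate_recipe(x, ph_base = attr(x, "ph_base"))
  c(current_clamp  = henderson_ljp(diss(rec$kgluconate_internal),
                                   diss(rec$acsf), temperature),
    na_recording   = henderson_ljp(diss(rec$na_internal),
                                   diss(rec$na_external), temperature),
    nucleated_patch = henderson_ljp(diss(rec$na_internal),
                                    diss(rec$acsf), temperature))
}
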