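# Volume/mass bookkeeping: translating batch saccharification conditions
# (solution volume, substrate mass, enzyme concentration) into the number of
# enzymes surrounding one simulated sub-unit, and cocktail ratio arithmetic.

#' Monomer molar masses (kg/mol)
#'
#' Molar masses of glucose, xylose and the representative monolignol (mean of
#' coumaryl, coniferyl and sinapyl alcohol), rounded to three digits.
#'
#' @param m_glc,m_xyl,m_lign molar masses in kg/mol.
#' @export
monomer_masses <- function(m_glc = 0.180, m_xyl = 0.150, m_lign = 0.180) {
  m <- c(m_glc = m_glc, m_xyl = m_xyl, m_lign = m_lign)
  if (any(m <= 0)) stop("molar masses must be positive")
  m
}

#' Mass of one microfibril sub-unit
#'
#' `m_SU = sum(N_k * M_k / N_A)` over glucose, xylose and monolignol counts.
#'
#' @param counts monomer counts `c(N_glc, N_xyl, N_lign)` (as from
#'   [composition_summary()]).
#' @param masses molar masses from [monomer_masses()], kg/mol.
#' @return mass in grams.
#' @export
subunit_mass <- function(counts, masses = monomer_masses()) {
  if (any(counts < 0)) stop("counts must be >= 0")
  sum(counts * masses) / AVOGADRO * 1000
}

#' Number of sub-units in a batch
#'
#' @param m_substrate total substrate mass (g).
#' @param m_SU mass of one sub-unit (g).
#' @export
n_subunits <- function(m_substrate, m_SU) {
  if (m_SU <= 0) stop("m_SU must be positive")
  m_substrate / m_SU
}

#' Volume occupied by one sub-unit
#'
#' `V_SU = d_SU^2 * (N_bonds + 1) * d_glc`, a square prism of cross-section
#' `d_SU` (10 nm, wide enough to hold the shell layers) and one glucose
#' diameter `d_glc` per monomer along the axis.
#'
#' @param d_SU cross-section edge (nm).
#' @param N_bonds bonds per cellulose chain.
#' @param d_glc glucose diameter (nm).
#' @return volume in m^3.
#' @export
subunit_volume <- function(d_SU = 10, N_bonds = 200, d_glc = 1) {
  if (d_SU <= 0 || N_bonds < 0 || d_glc <= 0) stop("invalid sub-unit geometry")
  d_SU^2 * (N_bonds + 1) * d_glc * 1e-27
}

#' Solvent volume surrounding one sub-unit
#'
#' `V_surrounding = V_solution / N_SU - V_SU`.
#'
#' @param V_solution total solution volume (m^3); default 50 mL.
#' @param N_SU number of sub-units.
#' @param V_SU volume of one sub-unit (m^3).
#' @return volume in m^3 (error if non-positive).
#' @export
surrounding_volume <- function(V_solution = 50e-6, N_SU, V_SU = subunit_volume()) {
  if (N_SU <= 0) stop("N_SU must be positive")
  v <- V_solution / N_SU - V_SU
  if (v <= 0) {
    stop("surrounding volume is non-positive: substrate denser than solution")
  }
  v
}

#' Enzyme count from a molar concentration
#'
#' `N_enzyme = c_enzyme * V_surrounding * N_A`, rounded to the nearest
#' integer.
#'
#' @param c_enzyme concentration in mol/L.
#' @param V_surrounding volume in m^3.
#' @export
enzymes_from_concentration <- function(c_enzyme, V_surrounding) {
  if (c_enzyme < 0 || V_surrounding <= 0) stop("inputs must be positive")
  round(c_enzyme * 1000 * V_surrounding * AVOGADRO)
}

#' Cocktail ratios
#'
#' Literature cellulase cocktail percentages (EG/CBH/BGL; the raw percentages
#' do not sum to 100 and are only used as ratios) and the cellulase:xylanase
#' split of an optimized cellulase + xylanase blend.
#'
#' @param p_EG,p_CBH,p_BGL cellulase percentages.
#' @param cellulase_share,xylanase_share blend shares.
#' @export
cocktail_ratios <- function(p_EG = 15, p_CBH = 38.5, p_BGL = 11,
                            cellulase_share = 58.83, xylanase_share = 41.16) {
  r <- list(p_EG = p_EG, p_CBH = p_CBH, p_BGL = p_BGL,
            cellulase_share = cellulase_share,
            xylanase_share = xylanase_share)
  if (any(unlist(r) <= 0)) stop("ratios must be positive")
  structure(r, class = "cocktail_ratios")
}

#' Split a total enzyme count into the four classes
#'
#' The xylanase count is the xylanase share of the total; the remaining
#' cellulases are split by the normalized EG/CBH/BGL percentages.  All counts
#' are rounded to the nearest integer.
#'
#' @param N_total total enzyme count.
#' @param ratios a [cocktail_ratios()].
#' @return named integer vector `c(EG, CBH, BGL, XYL)`.
#' @export
cocktail_split <- function(N_total, ratios = cocktail_ratios()) {
  if (N_total < 0) stop("N_total must be >= 0")
  xs <- ratios$xylanase_share / (ratios$cellulase_share + ratios$xylanase_share)
  n_xyl <- round(N_total * xs)
  n_cel <- N_total - n_xyl
  p <- c(ratios$p_EG, ratios$p_CBH, ratios$p_BGL)
  p <- p / sum(p)
  counts <- c(round(n_cel * p[1]), round(n_cel * p[2]), round(n_cel * p[3]), n_xyl)
  names(counts) <- c("EG", "CBH", "BGL", "XYL")
  as.integer(counts) |> setNames(c("EG", "CBH", "BGL", "XYL"))
}

#' Full dosage table for a batch
#'
#' Convenience wrapper chaining the sub-unit mass, count and volume math with
#' the enzyme concentration and cocktail split.
#'
#' @param counts monomer counts of one sub-unit.
#' @param c_enzyme overall enzyme concentration (mol/L).
#' @param m_substrate substrate mass (g).
#' @param V_solution solution volume (m^3).
#' @param masses molar masses (kg/mol).
#' @param d_SU,N_bonds,d_glc sub-unit geometry (nm / bonds / nm).
#' @param ratios a [cocktail_ratios()].
#' @return a list with every intermediate quantity and the per-class counts.
#' @export
dose_table <- function(counts, c_enzyme = 5e-6, m_substrate = 4,
                       V_solution = 50e-6, masses = monomer_masses(),
                       d_SU = 10, N_bonds = 200, d_glc = 1,
                       ratios = cocktail_ratios()) {
  m_SU <- subunit_mass(counts, masses)
  N_SU <- n_subunits(m_substrate, m_SU)
  V_SU <- subunit_volume(d_SU, N_bonds, d_glc)
  V_surr <- surrounding_volume(V_solution, N_SU, V_SU)
  N_enzyme <- enzymes_from_concentration(c_enzyme, V_surr)
  list(
    m_SU_g = m_SU,
    N_SU = N_SU,
    V_SU_m3 = V_SU,
    V_surrounding_m3 = V_surr,
    l_cube_nm = V_surr^(1 / 3) * 1e9,
    N_enzyme = N_enzyme,
    counts = cocktail_split(N_enzyme, ratios)
  )
}
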