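# Amino-acid residue masses (Da): mass of the residue as incorporated in a
# peptide chain (monomer minus water).  One water is added per chain for the
# free termini.  Values follow standard proteomics mass tables.

.aa_mass_avg <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.aa_mass_mono <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

.water_avg <- 18.01524
.water_mono <- 18.010565

# Approximate average atomic masses for mass-weighted centres of geometry.
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                   ZN = 65.38, MG = 24.305, CA = 40.078)

residue_mass_table <- function(kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  if (kind == "average") list(aa = .aa_mass_avg, water = .water_avg)
  else list(aa = .aa_mass_mono, water = .water_mono)
}

# Mass of a one-letter protein sequence (one chain): residue masses + water.
sequence_mass <- function(seq, kind = c("average", "monoisotopic")) {
  tab <- residue_mass_table(match.arg(kind))
  aa <- strsplit(toupper(seq), "")[[1]]
  unknown <- setdiff(unique(aa), names(tab$aa))
  if (length(unknown) > 0)
    stop("unknown amino-acid code(s): ", paste(unknown, collapse = ", "))
  sum(tab$aa[aa]) + tab$water
}

element_mass <- function(elements) {
  m <- .element_mass[toupper(elements)]
  m[is.na(m)] <- 12.011  # treat unknown heavy atoms as carbon-like
  unname(m)
}
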