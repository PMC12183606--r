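# Element reference data used across parsing, perception and featurization.
# Values are standard tabulations: atomic masses (amu), single-bond covalent
# radii (Angstrom, Cordero-style), van der Waals radii (Angstrom, Bondi-style
# with common extensions).

.element_data <- local({
  # na.strings disabled: "NA" is sodium here
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE,
                    na.strings = character(), text = "
symbol number   mass  rcov  rvdw
H       1    1.008  0.31  1.20
B       5   10.811  0.84  1.92
C       6   12.011  0.76  1.70
N       7   14.007  0.71  1.55
O       8   15.999  0.66  1.52
F       9   18.998  0.57  1.47
NA     11   22.990  1.66  2.27
MG     12   24.305  1.41  1.73
P      15   30.974  1.07  1.80
S      16   32.066  1.05  1.80
CL     17   35.453  1.02  1.75
K      19   39.098  2.03  2.75
CA     20   40.078  1.76  2.31
MN     25   54.938  1.39  2.05
FE     26   55.845  1.32  2.04
CO     27   58.933  1.26  2.00
NI     28   58.693  1.24  1.97
CU     29   63.546  1.32  1.96
ZN     30   65.380  1.22  2.01
BR     35   79.904  1.20  1.85
I      53  126.904  1.39  1.98
AR     18   39.948  1.06  1.88
SE     34   78.971  1.20  1.90
")
  rownames(tab) <- tab$symbol
  tab
})

.metal_symbols <- c("NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN")

.hybridizations <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2",
                     "UNSPECIFIED", "OTHER")

.standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.water_residues <- c("HOH", "WAT", "DOD", "H2O")
.halogen_symbols <- c("F", "CL", "BR", "I")

# default formal charge carried by an isolated metal ion
.metal_formal_charge <- c(NA. = 1, MG = 2, K = 1, CA = 2, MN = 2, FE = 2,
                          CO = 2, NI = 2, CU = 2, ZN = 2)
names(.metal_formal_charge) <- c("NA", "MG", "K", "CA", "MN", "FE",
                                 "CO", "NI", "CU", "ZN")

.norm_element <- function(x) toupper(trimws(x))

.element_known <- function(x) .norm_element(x) %in% rownames(.element_data)

.element_field <- function(x, field, default = NA_real_) {
  x <- .norm_element(x)
  out <- .element_data[x, field]
  out[is.na(out)] <- default
  out
}

#' Atomic mass lookup
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu (NA for unknown symbols).
#' @keywords internal
element_mass <- function(element) .element_field(element, "mass")

#' Covalent radius lookup
#' @param element character vector of element symbols.
#' @return numeric vector of single-bond covalent radii in Angstrom.
#' @keywords internal
covalent_radius <- function(element) .element_field(element, "rcov")

element_number <- function(element) .element_field(element, "number")
vdw_radius <- function(element) .element_field(element, "rvdw", default = 1.7)
is_metal <- function(element) .norm_element(element) %in% .metal_symbols
is_halogen <- function(element) .norm_element(element) %in% .halogen_symbols
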