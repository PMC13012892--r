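#' Amino-acid property table
#'
#' Per-residue physicochemical descriptors used for node featurization:
#' Kyte-Doolittle hydropathy, Grantham polarity, side-chain volume (A^3),
#' isoelectric point, average residue mass (Da) and formal charge at
#' physiological pH (Asp/Glu -1, Lys/Arg +1, others 0).
#'
#' @return A data.frame with one row per standard amino acid, keyed by
#'   three-letter code (`aa3`).
#' @export
aa_properties <- function() {
  path <- system.file("extdata", "aa_properties.tsv", package = "tcrgraphs")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "aa_properties.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# cached copy, resolved once per session
.aa_env <- new.env(parent = emptyenv())

aa_table <- function() {
  if (is.null(.aa_env$tab)) {
    tab <- aa_properties()
    rownames(tab) <- tab$aa3
    .aa_env$tab <- tab
  }
  .aa_env$tab
}

#' Standard amino acids in canonical (alphabetical three-letter) order
#' @return Character vector of 20 three-letter codes.
#' @export
aa_order <- function() aa_table()$aa3

# common non-standard -> parent standard residue mappings
.nonstandard_map <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", OCS = "CYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS", KCX = "LYS",
  HYP = "PRO", PCA = "GLU", CGU = "GLU", FME = "MET", M3L = "LYS"
)

map_nonstandard_residue <- function(res_name) {
  out <- res_name
  hit <- res_name %in% names(.nonstandard_map)
  out[hit] <- .nonstandard_map[res_name[hit]]
  out
}

is_standard_aa <- function(res_name) res_name %in% aa_order()

# --- atom typing for interaction-type flags -------------------------------

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

# side-chain hydrogen-bond donor heavy atoms per residue
.sc_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG"
)

# side-chain acceptor heavy atoms per residue
.sc_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

.acidic_oxygens <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_nitrogens <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

atom_in_set <- function(res_name, atom_name, set) {
  ok <- logical(length(res_name))
  hit <- res_name %in% names(set)
  if (any(hit)) {
    ok[hit] <- mapply(function(r, a) a %in% set[[r]],
                      res_name[hit], atom_name[hit])
  }
  ok
}

is_hbond_donor <- function(res_name, atom_name) {
  atom_name == "N" | atom_in_set(res_name, atom_name, .sc_donors)
}

is_hbond_acceptor <- function(res_name, atom_name) {
  atom_name == "O" | atom_name == "OXT" |
    atom_in_set(res_name, atom_name, .sc_acceptors)
}

is_acidic_oxygen <- function(res_name, atom_name) {
  atom_in_set(res_name, atom_name, .acidic_oxygens)
}

is_basic_nitrogen <- function(res_name, atom_name) {
  atom_in_set(res_name, atom_name, .basic_nitrogens)
}

is_apolar_carbon <- function(res_name, atom_name, element) {
  element == "C" & !(atom_name %in% .backbone_atoms) &
    res_name %in% .apolar_residues
}
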