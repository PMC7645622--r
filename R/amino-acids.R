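# Amino-acid alphabets and shipped property tables.
#
# Property tables live as editable CSV under inst/extdata so alternative
# scales can be dropped in without touching code; the loaders below read and
# cache them.

#' The 20 standard amino acids (1-letter codes)
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 3-letter -> 1-letter lookup for PDB residue names
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Approximate background amino-acid frequencies (UniProt/Swiss-Prot scale),
# used by the synthetic sequence generator.
AA_BACKGROUND_FREQ <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
)

.vox_cache <- new.env(parent = emptyenv())

read_aa_csv <- function(file) {
  path <- system.file("extdata", file, package = "voxppi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Raw seven-property descriptor table for autocovariance encoding
#'
#' The seven physicochemical scales used by the autocovariance encoder:
#' hydrophobicity, hydrophilicity, side-chain volume, polarity,
#' polarizability, solvent-accessible surface area and net charge index.
#' Values are the widely used set from the classical autocovariance PPI
#' encoding literature; rows are the 20 standard amino acids.
#'
#' @return a 20 x 7 numeric matrix with amino-acid rownames
#' @export
#' @examples
#' dim(ac_descriptor_table())
ac_descriptor_table <- function() {
  if (is.null(.vox_cache$ac_raw)) {
    df <- read_aa_csv("ac_descriptors.csv")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$aa
    .vox_cache$ac_raw <- m[AA_ALPHABET, , drop = FALSE]
  }
  .vox_cache$ac_raw
}

#' Residue attribute tables for voxel channels
#'
#' Per-residue values painted onto the attribute voxel channels:
#' Kyte-Doolittle hydropathy index, isoelectric point, and side-chain
#' charge at pH 7.
#'
#' @return a named list of three named numeric vectors
#'   (`hydropathy`, `isoelectric`, `charge`), each over the 20 amino acids
#' @export
voxel_attribute_tables <- function() {
  if (is.null(.vox_cache$vox_attr)) {
    df <- read_aa_csv("voxel_attributes.csv")
    .vox_cache$vox_attr <- lapply(
      c(hydropathy = "hydropathy", isoelectric = "isoelectric",
        charge = "charge"),
      function(col) setNames(df[[col]], df$aa)
    )
  }
  .vox_cache$vox_attr
}

#' Conjoint-triad cluster assignment
#'
#' The standard seven-group clustering of the 20 amino acids by dipole and
#' side-chain volume used by the conjoint-triad encoder:
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.
#'
#' @return a named integer vector mapping each amino acid to a cluster in 1..7
#' @export
#' @examples
#' table(ct_clustering())
ct_clustering <- function() {
  if (is.null(.vox_cache$ct)) {
    df <- read_aa_csv("ct_clusters.csv")
    .vox_cache$ct <- setNames(as.integer(df$cluster), df$aa)[AA_ALPHABET]
  }
  .vox_cache$ct
}

validate_clustering <- function(clustering) {
  if (!all(AA_ALPHABET %in% names(clustering))) {
    vox_abort("config", "clustering must assign every standard amino acid")
  }
  cl <- clustering[AA_ALPHABET]
  if (any(!cl %in% 1:7) || length(unique(cl)) != 7L) {
    vox_abort("config",
              "clustering must use all 7 clusters, values in 1..7")
  }
  cl
}
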