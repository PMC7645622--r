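# PDB backbone reading and writing.
#
# Only fixed-column ATOM records are consumed: the pipeline needs nothing
# but backbone atom names, residue identity and coordinates, and the error
# contract (line-numbered parse failures, first-MODEL / first-altLoc
# policy) is part of the package surface. The synthetic-fixture writer is
# the exact inverse, so structures round-trip at the format's 3-decimal
# coordinate precision.

#' Read backbone atoms from a PDB file
#'
#' Parses fixed-column `ATOM` records and keeps only backbone atoms.
#' `HETATM` records are skipped, only the first `MODEL` of a multi-model
#' file is read, and for alternate locations the first listed conformer of
#' each atom is kept. Chains are concatenated in file order into a single
#' trace.
#'
#' @param path path to a PDB file
#' @param backbone_atoms character vector of PDB atom names to keep.
#'   The default `c("N", "CA", "C")` is the peptide backbone
#'   (amide nitrogen, alpha-carbon, carbonyl carbon).
#' @return a `backbone_trace`: a tibble with columns `atom_name`,
#'   `residue_name` (3-letter), `residue_1` (1-letter), `residue_index`,
#'   `chain_id`, `x`, `y`, `z`, in file order
#' @export
#' @examples
#' pdb <- synth_backbone(5, seed = 1)
#' tmp <- tempfile(fileext = ".pdb")
#' writeLines(pdb$pdb_text, tmp)
#' read_pdb_backbone(tmp)
read_pdb_backbone <- function(path, backbone_atoms = c("N", "CA", "C")) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)

  # restrict to the first MODEL when models are present
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 0) {
    endmdl <- which(trimws(rec) == "ENDMDL")
    last <- if (length(endmdl) > 0) endmdl[1] else length(lines)
    keep_range <- seq(model_starts[1], last)
    in_model <- seq_along(lines) %in% keep_range
  } else {
    in_model <- rep(TRUE, length(lines))
  }

  is_atom <- rec == "ATOM  " & in_model
  idx <- which(is_atom)
  if (length(idx) == 0) {
    vox_abort("empty_structure",
              sprintf("no ATOM records found in '%s'", path))
  }
  ln <- lines[idx]

  atom_name <- trimws(substr(ln, 13, 16))
  alt_loc <- substr(ln, 17, 17)
  residue_name <- trimws(substr(ln, 18, 20))
  chain_id <- substr(ln, 22, 22)
  residue_index <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  icode <- substr(ln, 27, 27)
  xyz <- lapply(list(c(31, 38), c(39, 46), c(47, 54)), function(cols) {
    suppressWarnings(as.numeric(substr(ln, cols[1], cols[2])))
  })
  bad <- which(!is.finite(xyz[[1]]) | !is.finite(xyz[[2]]) |
                 !is.finite(xyz[[3]]) | is.na(residue_index))
  if (length(bad) > 0) {
    vox_abort("parse",
              sprintf("malformed ATOM record at line %d of '%s'",
                      idx[bad[1]], path))
  }

  keep <- atom_name %in% backbone_atoms
  if (!any(keep)) {
    vox_abort("empty_structure",
              sprintf("no backbone atoms (%s) found in '%s'",
                      paste(backbone_atoms, collapse = ","), path))
  }

  tr <- tibble(
    atom_name = atom_name[keep],
    residue_name = residue_name[keep],
    residue_index = residue_index[keep],
    chain_id = chain_id[keep],
    icode = icode[keep],
    alt_loc = alt_loc[keep],
    x = xyz[[1]][keep], y = xyz[[2]][keep], z = xyz[[3]][keep]
  )

  # alternate locations: keep the first listed conformer of each atom
  key <- paste(tr$chain_id, tr$residue_index, tr$icode, tr$atom_name)
  tr <- tr[!duplicated(key), ]

  unknown <- setdiff(unique(tr$residue_name), names(AA_THREE_TO_ONE))
  if (length(unknown) > 0) {
    vox_abort("unknown_residue",
              sprintf("non-standard residue name(s) in '%s': %s",
                      path, paste(unknown, collapse = ", ")))
  }
  tr$residue_1 <- unname(AA_THREE_TO_ONE[tr$residue_name])
  tr$icode <- NULL
  tr$alt_loc <- NULL

  new_backbone_trace(tr)
}

new_backbone_trace <- function(tbl) {
  structure(as_tibble(tbl),
            class = c("backbone_trace", class(as_tibble(tbl))))
}

#' Write a backbone trace as PDB ATOM records
#'
#' The inverse of [read_pdb_backbone()]; coordinates are written in the
#' format's fixed `%8.3f` columns.
#'
#' @param trace a `backbone_trace` tibble
#' @param path output path; when `NULL` the text is returned invisibly only
#' @return (invisibly) the character vector of PDB lines
#' @export
write_pdb_backbone <- function(trace, path = NULL) {
  element <- substr(trace$atom_name, 1, 1)
  name_fmt <- ifelse(nchar(trace$atom_name) < 4,
                     sprintf(" %-3s", trace$atom_name),
                     trace$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(trace)), name_fmt, trace$residue_name,
    trace$chain_id, trace$residue_index,
    trace$x, trace$y, trace$z, 1, 0, element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
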