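# FASTA sequences and labeled pair tables.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20-letter standard
#' amino-acid alphabet. Records containing ambiguity or non-standard codes
#' (U, X, B, Z, ...) are rejected, mirroring the usual cleaning of PPI
#' benchmark sets.
#'
#' @param path path to a FASTA file
#' @return a tibble with columns `id` and `seq`, in file order
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKVL", ">p2", "ACDE"), tmp)
#' read_fasta(tmp)
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    vox_abort("parse", sprintf("no FASTA records in '%s'", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0) {
      vox_abort("validation",
                sprintf(
                  "sequence '%s' contains non-standard symbol(s): %s",
                  ids[i], paste(bad, collapse = ", ")))
    }
    if (nchar(seqs[i]) < 1) {
      vox_abort("validation", sprintf("sequence '%s' is empty", ids[i]))
    }
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs tibble with columns `id` and `seq`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  out <- as.vector(rbind(paste0(">", seqs$id), seqs$seq))
  writeLines(out, path)
  invisible(path)
}

#' Read a labeled protein-pair table
#'
#' Expects three tab- or comma-delimited columns: protein A id, protein B
#' id, and a 0/1 interaction label. A header row is detected and skipped.
#'
#' @param path path to the pairs file
#' @return a tibble with columns `id_a`, `id_b`, `label` (integer 0/1),
#'   in file order; an empty file yields an empty tibble
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble(id_a = character(), id_b = character(),
                  label = integer())
  if (length(lines) == 0) return(empty)

  delim <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad_ncol <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad_ncol) > 0) {
    vox_abort("parse",
              sprintf("line %d of '%s' does not have 3 fields",
                      bad_ncol[1], path))
  }
  m <- do.call(rbind, parts)
  m <- apply(m, 2, trimws)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)

  # header row: third field is non-numeric (a numeric non-0/1 value is a
  # label error, not a header)
  if (!m[1, 3] %in% c("0", "1") &&
      is.na(suppressWarnings(as.numeric(m[1, 3])))) {
    m <- m[-1, , drop = FALSE]
    if (nrow(m) == 0) return(empty)
  }
  if (!all(m[, 3] %in% c("0", "1"))) {
    first_bad <- which(!m[, 3] %in% c("0", "1"))[1]
    vox_abort("validation",
              sprintf("label '%s' in '%s' is not 0 or 1",
                      m[first_bad, 3], path))
  }
  tibble(id_a = m[, 1], id_b = m[, 2], label = as.integer(m[, 3]))
}

#' Write a labeled pair table
#'
#' @param pairs tibble with columns `id_a`, `id_b`, `label`
#' @param path output path (tab-delimited, no header)
#' @return `path`, invisibly
#' @export
write_pairs <- function(pairs, path) {
  writeLines(sprintf("%s\t%s\t%d", pairs$id_a, pairs$id_b,
                     as.integer(pairs$label)), path)
  invisible(path)
}
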