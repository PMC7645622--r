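# Feature store: a plain-text, self-describing container for per-protein
# fixed-length feature vectors.
#
# A feature table is the package's tabular currency for encoded proteins:
# a tibble with columns `id` (character), `tag` (one of "AC", "CT",
# "structural", "fused") and `vec` (list-column of equal-length numeric
# vectors). The on-disk store is TSV with two metadata header lines
# recording the tag and vector length, and values written at full double
# precision (%.17g) so a write/read round trip is bit-exact.

FEATURE_TAGS <- c("AC", "CT", "structural", "fused")

#' Construct a feature table
#'
#' @param id character vector of protein ids
#' @param vectors list of equal-length numeric vectors (or a numeric matrix
#'   with one row per id)
#' @param tag provenance tag, one of `"AC"`, `"CT"`, `"structural"`, `"fused"`
#' @return a feature table tibble with columns `id`, `tag`, `vec`
#' @export
feature_table <- function(id, vectors, tag) {
  tag <- match.arg(tag, FEATURE_TAGS)
  if (is.matrix(vectors)) {
    vectors <- lapply(seq_len(nrow(vectors)), function(i) vectors[i, ])
  }
  lens <- vapply(vectors, length, 1L)
  if (length(vectors) > 0 && length(unique(lens)) > 1) {
    vox_abort("validation", "all feature vectors must have equal length")
  }
  tibble(id = as.character(id), tag = tag,
         vec = lapply(vectors, as.numeric))
}

# stack a feature table's vectors into an id-rownamed matrix
feature_matrix <- function(tbl) {
  m <- do.call(rbind, tbl$vec)
  if (is.null(m)) m <- matrix(numeric(), nrow = 0, ncol = 0)
  rownames(m) <- tbl$id
  m
}

#' Write a feature table to a plain-text store
#'
#' @param tbl a feature table (see [feature_table()]); all rows must share
#'   one provenance tag
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_store <- function(tbl, path) {
  tags <- unique(tbl$tag)
  if (length(tags) > 1) {
    vox_abort("validation",
              sprintf("feature store requires a single tag, found: %s",
                      paste(tags, collapse = ", ")))
  }
  tag <- if (length(tags) == 0) "fused" else tags
  dim <- if (nrow(tbl) == 0) 0L else length(tbl$vec[[1]])
  header <- c(sprintf("#voxppi-features\ttag=%s\tdim=%d", tag, dim))
  body <- vapply(seq_len(nrow(tbl)), function(i) {
    paste(c(tbl$id[i], sprintf("%.17g", tbl$vec[[i]])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature table from a plain-text store
#'
#' @param path path written by [write_feature_store()]
#' @return a feature table tibble
#' @export
read_feature_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "#voxppi-features")) {
    vox_abort("parse", sprintf("'%s' is not a voxppi feature store", path))
  }
  meta <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tag <- meta[["tag"]]
  dim <- as.integer(meta[["dim"]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(feature_table(character(), list(), tag))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  vecs <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (length(v) != dim || anyNA(v)) {
      vox_abort("integrity",
                sprintf(
                  "record %d of '%s' does not match declared dim %d",
                  i, path, dim))
    }
    v
  })
  feature_table(vapply(parts, `[`, "", 1), vecs, tag)
}
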