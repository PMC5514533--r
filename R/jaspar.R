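#' Read a motif in JASPAR PFM text format
#'
#' Accepts both the bracketed 4-row dialect
#' (`>MA0001.1 NAME` then `A [ 1 2 3 ]` ...) and the raw 4-row matrix
#' dialect (4 whitespace-separated numeric rows in A, C, G, T order).
#'
#' @param path file path (or character vector of lines).
#' @return a `pfm`; counts if the values look like counts, frequencies if
#'   every column sums to 1. The motif name, if present, is kept as
#'   attribute `"name"`.
#' @export
read_jaspar <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else
    path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4) stop("JASPAR input needs 4 matrix rows")
  lines <- lines[1:4]
  rows <- lapply(seq_len(4), function(i) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^([ACGT])\\s*\\[(.*)\\]", ln))[[1]]
    if (length(m) == 3) {
      if (m[2] != DNA_BASES[i]) {
        stop("JASPAR rows must be in A, C, G, T order; found ", m[2])
      }
      ln <- m[3]
    }
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln),
                                              "[[:space:]]+")[[1]]))
    if (anyNA(v)) stop("non-numeric value in JASPAR row: ", lines[i])
    v
  })
  if (length(unique(lengths(rows))) != 1) {
    stop("JASPAR rows have unequal lengths")
  }
  m <- do.call(rbind, rows)
  kind <- if (all(abs(colSums(m) - 1) < 1e-6)) "frequencies" else "counts"
  pfm <- new_pfm(m, kind = kind)
  attr(pfm, "name") <- name
  pfm
}

#' Write a motif in JASPAR PFM text format
#'
#' @param pfm a `pfm`.
#' @param path file path.
#' @param name motif header written after `>`.
#' @export
write_jaspar <- function(pfm, path, name = "pentascan_motif") {
  m <- unclass(pfm)
  fmt <- if (attr(pfm, "kind") == "counts") "%g" else "%.6f"
  lines <- c(paste0(">", name),
             vapply(seq_len(4), function(i) {
               sprintf("%s [ %s ]", DNA_BASES[i],
                       paste(sprintf(fmt, m[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
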