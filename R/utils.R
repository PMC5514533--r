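#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
DNA_RESNAMES <- c(A = "DA", C = "DC", G = "DG", T = "DT")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AROMATIC_AA <- c("PHE", "TYR", "TRP", "HIS")

#' Complement of a base string
#'
#' @param x character vector of sequences over A/C/G/T.
#' @param reverse if `TRUE` return the reverse complement.
#' @return character vector of the same length.
#' @export
complement_sequence <- function(x, reverse = FALSE) {
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(b %in% DNA_BASES)) {
      stop("sequence contains characters outside {A,C,G,T}: ", s)
    }
    comp <- unname(BASE_COMPLEMENT[b])
    if (reverse) comp <- rev(comp)
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all k-mers over the DNA alphabet
#'
#' Returns all `4^k` sequences over `{A, C, G, T}` in lexicographic order.
#' The order is the canonical indexing used throughout the package: the
#' first position is the most significant base-4 digit (A = 0 ... T = 3).
#'
#' @param k k-mer length, between 1 and 15.
#' @return character vector of length `4^k`.
#' @examples
#' enumerate_kmers(1)
#' length(enumerate_kmers(5)) # 1024
#' @export
enumerate_kmers <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > 15) {
    stop("k must be a single integer in 1..15")
  }
  index_to_kmer(seq_len(4^k) - 1, k)
}

#' Convert between k-mer strings and lexicographic indices
#'
#' `kmer_index` maps sequences to their 0-based lexicographic index (first
#' position most significant, A = 0 ... T = 3); `index_to_kmer` is the
#' inverse. This indexing orders every score table in the package.
#'
#' @param seqs character vector of equal-length sequences.
#' @return `kmer_index`: numeric vector of 0-based indices.
#' @export
kmer_index <- function(seqs) {
  k <- nchar(seqs[1])
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES) - 1,
              nrow = k)
  if (anyNA(m)) stop("sequence contains characters outside {A,C,G,T}")
  as.numeric(4^((k - 1):0) %*% m)
}

#' @rdname kmer_index
#' @param idx numeric vector of 0-based indices.
#' @param k k-mer length.
#' @return `index_to_kmer`: character vector of sequences.
#' @export
index_to_kmer <- function(idx, k) {
  digits <- matrix(0L, nrow = length(idx), ncol = k)
  rem <- as.numeric(idx)
  for (j in k:1) {
    digits[, j] <- as.integer(rem %% 4)
    rem <- rem %/% 4
  }
  m <- matrix(DNA_BASES[digits + 1L], nrow = length(idx), ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Extract, for every full-length 0-based index over 4^L, the 0-based index of
# the k-mer starting at position `pos` (1-based). Pure integer arithmetic so
# Kmer-Sum never materialises the sequence strings.
subkmer_index <- function(idx, L, pos, k = 5) {
  (idx %/% 4^(L - k - (pos - 1))) %% 4^k
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# element symbol from a PDB atom name when the element column is absent
guess_element <- function(name) {
  s <- gsub("[0-9']", "", name)
  ifelse(substr(s, 1, 1) == "H" | grepl("^[0-9]H", name), "H",
         substr(s, 1, 1))
}
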