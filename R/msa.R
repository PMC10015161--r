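#' @useDynLib topotest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## 20-letter amino-acid alphabet in the classical order used by empirical
## rate matrices (A R N D C Q E G H I L K M F P S T W Y V).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid alignment with site-pattern compression
#'
#' Builds the package's alignment container from a character matrix
#' (rows = sequences, columns = aligned sites). Identical columns are
#' collapsed into site patterns with integer multiplicities; the full
#' matrix is retained so alignments round-trip through FASTA unchanged.
#'
#' Gaps (`-`) and ambiguity codes (`X`, `?`, `*`, `.`) are coded as fully
#' ambiguous states and contribute a partial-likelihood vector of ones
#' during inference.
#'
#' @param x character matrix of single residues, with row names giving the
#'   sequence labels; lower-case letters are accepted.
#' @return an object of class `aa_msa` with elements `labels`, `seq` (the
#'   residue matrix), `patterns` (pattern x taxon integer codes, 0 =
#'   ambiguous), `weights` (pattern multiplicities), `pattern_index`
#'   (site -> pattern map) and `n_sites`.
#' @export
aa_msa <- function(x) {
  if (!is.matrix(x) || !is.character(x))
    stop("'x' must be a character matrix of residues")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("'x' must have unique row names (sequence labels)")
  if (ncol(x) < 1L) stop("alignment has zero columns")
  x <- toupper(x)
  codes <- match(x, AA_ALPHABET)           # NA for gap/ambiguity
  bad <- is.na(codes) & !(x %in% c("-", "X", "?", "*", "."))
  if (any(bad))
    stop("unknown residue(s): ", paste(unique(x[bad]), collapse = " "))
  codes[is.na(codes)] <- 0L
  m <- matrix(as.integer(codes), nrow = nrow(x))   # taxa x sites
  key <- apply(m, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pid <- match(key, key[first])
  patterns <- t(m[, first, drop = FALSE])          # patterns x taxa
  structure(list(
    labels = rownames(x),
    seq = x,
    patterns = patterns,
    weights = as.numeric(tabulate(pid, sum(first))),
    pattern_index = pid,
    n_sites = ncol(x)
  ), class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences, %d sites (%d patterns)\n",
              length(x$labels), x$n_sites, nrow(x$patterns)))
  invisible(x)
}

#' @export
as.matrix.aa_msa <- function(x, ...) x$seq

#' Read an aligned FASTA file of protein sequences
#'
#' @param path path to an aligned FASTA file.
#' @return an [aa_msa] object.
#' @export
read_msa_fasta <- function(path) {
  seqs <- ape::read.FASTA(path, type = "AA")
  chr <- as.character(seqs)
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: unequal lengths in ", path)
  m <- do.call(rbind, chr)
  rownames(m) <- names(seqs)
  aa_msa(m)
}

#' Write an alignment as FASTA
#'
#' @param msa an [aa_msa] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "aa_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$labels)) {
    writeLines(paste0(">", msa$labels[i]), con)
    writeLines(paste(msa$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}
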