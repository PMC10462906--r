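# Internal sequence helpers shared across modules.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate DNA to amino acids
#'
#' Translates an in-frame DNA string (standard code) into a one-letter
#' amino-acid string; stop codons become `*`. Trailing partial codons are
#' dropped.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of amino-acid sequences.
#' @export
#' @examples
#' translate_dna("TGTGCGAGATGG")
translate_dna <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return("")
    paste(seqinr::translate(strsplit(substr(s, 1L, n), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split sequences of equal length into a character matrix (rows = sequences).
.seq_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1L)
  matrix(unlist(strsplit(x, ""), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

# Pairwise Hamming distance (as fraction of length) between equal-length
# strings, computed via per-base indicator cross-products.
.hamming_frac_matrix <- function(x) {
  n <- length(x)
  L <- nchar(x[1])
  m <- .seq_matrix(x)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- m == b
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  d <- (L - matches) / L
  diag(d) <- 0
  dimnames(d) <- list(x, x)
  d
}

# Hamming distance (count) between two equal-length strings.
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 0-based frame-0 codon indices of stop codons in a DNA string.
.stop_codon_indices <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(integer(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  cods <- substring(seq, starts, starts + 2L)
  which(cods %in% .STOP_CODONS) - 1L
}

# Strip the allele suffix from an IMGT-style gene call ("IGHV1-2*02" ->
# "IGHV1-2"); multiple comma-separated calls keep only the first.
gene_of <- function(call) {
  sub("\\*.*$", "", sub(",.*$", "", call))
}

# V subgroup ("IGHV1-2*02" -> "IGHV1").
subgroup_of <- function(call) {
  sub("[-/].*$", "", gene_of(call))
}

# Position-wise majority consensus of equal-length strings, optionally
# weighted; ties broken by alphabetical base order.
.consensus <- function(x, w = NULL) {
  if (length(x) == 1L) return(x)
  m <- .seq_matrix(x)
  if (is.null(w)) w <- rep(1, length(x))
  cons <- vapply(seq_len(ncol(m)), function(j) {
    tab <- sort(tapply(w, m[, j], sum), decreasing = TRUE)
    best <- tab[tab == tab[1]]
    sort(names(best))[1]
  }, character(1))
  paste(cons, collapse = "")
}
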