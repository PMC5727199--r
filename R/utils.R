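is_dna <- function(x, len = NULL) {
  ok <- is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGT]+$", x)
  if (ok && !is.null(len)) ok <- nchar(x) == len
  ok
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon, call. = FALSE)
  aa
}

# Run `expr` under a fixed RNG seed when `seed` is given, untouched otherwise.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Character matrix (reads x positions) from equal-length strings.
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), 0, 0))
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L)
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), ncol = len, byrow = TRUE)
}

# Hamming distances from each row of char matrix `mat` to string `center`.
hamming_to <- function(mat, center) {
  cc <- strsplit(center, "")[[1]]
  stopifnot(ncol(mat) == length(cc))
  rowSums(mat != matrix(cc, nrow(mat), ncol(mat), byrow = TRUE))
}

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
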