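# Sequence encodings shared by the alignment kernels.
#
# Proteins are encoded as 0-based indices into the BLOSUM62 row order
# (Biostrings convention, alphabet "ARNDCQEGHILKMFPSTWYVBZX*"); DNA as
# 0=A, 1=C, 2=G, 3=T, 4=N.

aa_alphabet <- function() {
  rownames(substitution_matrix("BLOSUM62"))
}

#' Retrieve a protein substitution matrix by name
#'
#' Only matrices shipped with Biostrings are supported (e.g. `"BLOSUM62"`,
#' `"BLOSUM50"`). The matrix includes the `*` (stop) row/column, which is how
#' residues aligned against in-frame stop codons are scored.
#'
#' @param name matrix identifier.
#' @return integer matrix with residue dimnames.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.fishor_env[[key]])) return(.fishor_env[[key]])
  ok <- tryCatch({
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    storage.mode(m) <- "integer"
    m
  }, warning = function(w) NULL, error = function(e) NULL)
  if (is.null(ok)) stop("unknown substitution matrix: ", name)
  .fishor_env[[key]] <- ok
  ok
}

encode_protein <- function(x, alphabet = aa_alphabet()) {
  if (length(x) != 1L || !nzchar(x)) stop("protein sequence must be a non-empty string")
  idx <- match(strsplit(toupper(x), "")[[1]], alphabet)
  if (anyNA(idx)) stop("protein sequence contains characters outside the matrix alphabet")
  as.integer(idx - 1L)
}

encode_dna <- function(x) {
  if (length(x) != 1L) stop("dna sequence must be a single string")
  v <- utf8ToInt(toupper(x))
  code <- integer(128)
  code[] <- NA_integer_
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[utf8ToInt("N")] <- 4L
  if (any(v > 127L)) stop("invalid characters in DNA sequence")
  out <- code[v]
  if (anyNA(out)) stop("invalid characters in DNA sequence (allowed: A, C, G, T, N)")
  out
}

decode_dna <- function(v) {
  paste(c("A", "C", "G", "T", "N")[v + 1L], collapse = "")
}

revcomp_int <- function(v) {
  out <- rev(v)
  ifelse(out < 4L, 3L - out, 4L)
}

revcomp <- function(x) decode_dna(revcomp_int(encode_dna(x)))

# codon index (16 a + 4 b + c over ACGT) -> 0-based BLOSUM row of residue
codon_aa_table <- function(alphabet = aa_alphabet()) {
  if (!is.null(.fishor_env$codon_aa)) return(.fishor_env$codon_aa)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- integer(64)
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
    codon <- paste0(bases[a + 1], bases[b + 1], bases[cc + 1])
    tab[16 * a + 4 * b + cc + 1] <- match(unname(gc[codon]), alphabet) - 1L
  }
  .fishor_env$codon_aa <- tab
  tab
}

translate_int <- function(dna_int, alphabet = aa_alphabet()) {
  n <- length(dna_int) %/% 3L
  if (n == 0L) return("")
  tab <- codon_aa_table(alphabet)
  x_row <- match("X", alphabet) - 1L
  i <- seq_len(n) * 3L - 2L
  a <- dna_int[i]; b <- dna_int[i + 1L]; cc <- dna_int[i + 2L]
  row <- ifelse(a > 3L | b > 3L | cc > 3L, x_row, tab[16L * a + 4L * b + cc + 1L])
  paste(alphabet[row + 1L], collapse = "")
}
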