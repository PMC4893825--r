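`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement on plain character strings; faster than DNAString
# round-trips in per-variant hot paths, N maps to N.
revcompStr <- function(s) {
  if (!nzchar(s)) return(s)
  x <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

complementStr <- function(s) chartr("ACGTNacgtn", "TGCANtgcan", s)

normChrom <- function(x) sub("^chr", "", x)
chromEqual <- function(a, b) normChrom(a) == normChrom(b)

# Codon tables as named codon -> amino-acid vectors.
geneticCodeTable <- function(table = c("standard", "mito")) {
  table <- match.arg(table)
  if (table == "standard") Biostrings::GENETIC_CODE
  else Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation against the standard or vertebrate mitochondrial
#' code. Selenocysteine positions (codon indices supplied via annotation)
#' render internal TGA as \code{U}. A trailing incomplete codon is dropped and
#' flagged via the \code{incomplete} attribute, which drives
#' \code{incomplete_terminal_codon_variant}.
#'
#' @param cds coding sequence (A/C/G/T/N string), length >= 3.
#' @param table \code{"standard"} or \code{"mito"}.
#' @param seleno integer codon indices annotated as selenocysteine.
#' @return amino-acid string ('*' for stop); attribute \code{incomplete} is
#'   TRUE when a trailing partial codon was dropped.
#' @export
translateCds <- function(cds, table = "standard", seleno = integer(0)) {
  stopifnot(nchar(cds) >= 3L)
  if (grepl("[^ACGTNacgtn]", cds)) stop("non-ACGTN character in CDS")
  cds <- toupper(cds)
  code <- geneticCodeTable(table)
  n <- nchar(cds)
  nc <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (length(seleno)) {
    sec <- intersect(seleno, which(codons == "TGA"))
    aa[sec] <- "U"
  }
  out <- paste(aa, collapse = "")
  attr(out, "incomplete") <- (n %% 3L) != 0L
  out
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", U = "Sec", X = "Xaa", `*` = "Ter")

aaThree <- function(aa) {
  if (!nzchar(aa)) return("")
  paste(AA3[strsplit(aa, "", fixed = TRUE)[[1L]]], collapse = "")
}

# Maximal 3' shift of a deletion within sequence `seq`: segment of length
# `len` starting at `pos` moves right while the base entering the deleted
# window equals the base leaving it.
shift3Deletion <- function(seq, pos, len) {
  n <- nchar(seq)
  while (pos + len <= n &&
         substr(seq, pos, pos) == substr(seq, pos + len, pos + len)) {
    pos <- pos + 1L
  }
  pos
}

# Maximal 3' shift of an insertion placed after position `after` (0 = before
# first base). The inserted string rotates as it shifts.
shift3Insertion <- function(seq, after, allele) {
  n <- nchar(seq)
  while (after + 1L <= n &&
         substr(allele, 1L, 1L) == substr(seq, after + 1L, after + 1L)) {
    allele <- paste0(substr(allele, 2L, nchar(allele)), substr(allele, 1L, 1L))
    after <- after + 1L
  }
  list(after = after, allele = allele)
}

# After maximal shifting, an insertion is a duplication when it equals the
# immediately 5' adjacent sequence.
isDuplication <- function(seq, after, allele) {
  L <- nchar(allele)
  after >= L && substr(seq, after - L + 1L, after) == allele
}

# "i/n" style exon / intron numbering strings
fracLabel <- function(i, n) {
  if (length(i) == 0L) return("")
  if (length(i) == 1L) sprintf("%d/%d", i, n)
  else sprintf("%d-%d/%d", min(i), max(i), n)
}

writeLinesUtf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}
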