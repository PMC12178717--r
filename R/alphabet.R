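# Symbol tables for the 11-letter diploid consensus alphabet.
#
# A consensus call is one of: A,C,G,T (homozygous), R,Y,S,W,K,M (the six
# two-base IUPAC ambiguity codes, heterozygous), or N (missing / masked).
# Everything is handled at the raw-byte level so that whole contigs stored
# as single strings can be classified and rewritten without ever expanding
# to per-character vectors of R strings.

HOM_BASES <- c("A", "C", "G", "T")
HET_CODES <- c("R", "Y", "S", "W", "K", "M")
MISSING_CALL <- "N"
CALL_ALPHABET <- c(HOM_BASES, HET_CODES, MISSING_CALL)

# IUPAC two-base codes and their allele pairs
IUPAC_PAIRS <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

.byte <- function(ch) as.integer(charToRaw(ch))

# Normalization table: maps every possible input byte to its normalized
# call. Uppercase calls in the alphabet survive; everything else --
# lowercase letters (soft-masked), 'n'/'N', three/four-base ambiguity
# codes (B,D,H,V), gaps, stray symbols -- becomes MISSING. Soft-masked
# a/c/g/t are deliberately treated as missing so that repeat-derived bases
# drop out of all counts, mirroring hard-masked references.
.make_normalize_table <- function() {
  tab <- rep(charToRaw(MISSING_CALL), 256L)
  for (ch in CALL_ALPHABET) tab[.byte(ch) + 1L] <- charToRaw(ch)
  tab
}
NORMALIZE_TABLE <- .make_normalize_table()

# Site class codes: 0 = HOM, 1 = HET, 2 = MISSING, 3 = not a normalized call
CLASS_HOM <- 0L
CLASS_HET <- 1L
CLASS_MISSING <- 2L
.make_class_table <- function() {
  tab <- rep(3L, 256L)
  for (ch in HOM_BASES) tab[.byte(ch) + 1L] <- CLASS_HOM
  for (ch in HET_CODES) tab[.byte(ch) + 1L] <- CLASS_HET
  tab[.byte(MISSING_CALL) + 1L] <- CLASS_MISSING
  tab
}
CLASS_TABLE <- .make_class_table()

# Haploid allele tables: for a het byte, its two alleles; for hom, itself.
.make_allele_tables <- function() {
  a1 <- rep(charToRaw(MISSING_CALL), 256L)
  a2 <- rep(charToRaw(MISSING_CALL), 256L)
  for (ch in HOM_BASES) {
    a1[.byte(ch) + 1L] <- charToRaw(ch)
    a2[.byte(ch) + 1L] <- charToRaw(ch)
  }
  for (ch in HET_CODES) {
    pair <- IUPAC_PAIRS[[ch]]
    a1[.byte(ch) + 1L] <- charToRaw(pair[1L])
    a2[.byte(ch) + 1L] <- charToRaw(pair[2L])
  }
  list(a1 = a1, a2 = a2)
}
ALLELE_TABLES <- .make_allele_tables()

# Pairing table: 256*b1 + b2 -> diploid call byte (A+G -> R, A+A -> A, ...)
.make_pair_table <- function() {
  tab <- rep(charToRaw(MISSING_CALL), 256L * 256L)
  idx <- function(x, y) .byte(x) * 256L + .byte(y) + 1L
  for (b in HOM_BASES) tab[idx(b, b)] <- charToRaw(b)
  for (ch in HET_CODES) {
    pair <- IUPAC_PAIRS[[ch]]
    tab[idx(pair[1L], pair[2L])] <- charToRaw(ch)
    tab[idx(pair[2L], pair[1L])] <- charToRaw(ch)
  }
  tab
}
PAIR_TABLE <- .make_pair_table()

# Raw-level helpers -------------------------------------------------------

normalize_raw <- function(r) NORMALIZE_TABLE[as.integer(r) + 1L]

classify_raw <- function(r) CLASS_TABLE[as.integer(r) + 1L]

contig_raw <- function(s) charToRaw(s)

raw_contig <- function(r) rawToChar(r)
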