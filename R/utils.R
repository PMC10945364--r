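# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom methods is
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    .stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  if (integer && x != round(x))
    .stopf("'%s' must be a whole number, got %s", name, x)
  invisible(x)
}

# RNA <-> DNA, always uppercase.  Sequences are handled internally as DNA
# (Biostrings IUPAC matching operates on the DNA alphabet); user-facing motif
# output uses the RNA alphabet.
.as_dna_chr <- function(x) chartr("Uu", "Tt", toupper(as.character(x)))
.as_rna_chr <- function(x) chartr("Tt", "Uu", toupper(as.character(x)))

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(.as_dna_chr(x))))
}

.IUPAC_OK <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# Comma-joined integer list <-> integer vector (tabular alignment dialect).
.join_offsets <- function(offsets) {
  vapply(offsets, function(o) paste(o, collapse = ","), character(1))
}

.split_offsets <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}

# Minimum mismatch offset per record; Inf when the record has none.
.min_offset <- function(offset_strings) {
  vapply(.split_offsets(offset_strings), function(o) {
    if (length(o)) min(o) else Inf
  }, numeric(1))
}

.seqlengths_of <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    .stopf("expected a named DNAStringSet or a named length vector")
  }
}
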