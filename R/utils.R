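# Internal helpers shared across modules. All genomic intervals are 0-based
# half-open; conversion to/from 1-based formats happens only in junctools I/O
# and at the SAM boundary.

#' @import data.table
#' @importFrom methods is
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  a = "t", c = "g", g = "c", t = "a", n = "n"
)

# reverse complement of a character vector of sequences
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    comp <- COMPLEMENT[chars]
    comp[is.na(comp)] <- "N"
    paste0(comp, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Load a genome into a named character vector of uppercase sequences.
# Accepts a FASTA path, a named character vector (passed through), or a
# DNAStringSet.
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    seqs <- toupper(as.character(ss))
    # FASTA headers may carry descriptions; key on the first word
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  if (is(genome, "DNAStringSet")) {
    seqs <- toupper(as.character(genome))
    names(seqs) <- sub("\\s.*$", "", names(genome))
    return(seqs)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stop("`genome` must be a FASTA path, a named character vector, ",
       "or a DNAStringSet")
}

# substring in 0-based half-open coordinates, with bounds check
seq0 <- function(seqs, contig, start, end) {
  if (!contig %in% names(seqs)) {
    stop("contig '", contig, "' not present in genome")
  }
  len <- nchar(seqs[[contig]])
  if (any(start < 0L) || any(end > len) || any(start > end)) {
    stop("interval [", start, ",", end, ") out of bounds for contig '",
         contig, "' (length ", len, ")")
  }
  substr(seqs[[contig]], start + 1L, end)
}

# hamming distance between two equal-length strings
hamming_string <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# stable numeric-to-string conversion used by all text writers: integers print
# without a decimal part, everything else with 17 significant digits so that
# write -> read -> write is byte-identical
num2str <- function(x) {
  out <- character(length(x))
  nas <- is.na(x)
  out[nas] <- "NA"
  ints <- !nas & is.finite(x) & x == round(x) & abs(x) < 1e15
  out[ints] <- sprintf("%.0f", x[ints])
  rest <- !nas & !ints
  out[rest] <- sprintf("%.17g", x[rest])
  out
}

locus_key <- function(contig, start, end) {
  paste(contig, start, end, sep = ":")
}
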