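#' @import methods
#' @importFrom stats rbeta rbinom runif density fisher.test phyper pnorm setNames
#' @importFrom utils head read.table write.table
NULL

# DNA/RNA letter conversion: sequences are held as DNA internally, motifs and
# k-mer tables are reported in the RNA alphabet.
.to_dna <- function(x) chartr("Uu", "Tt", as.character(x))
.to_rna <- function(x) chartr("Tt", "Uu", as.character(x))

.check_strand <- function(s, what = "record") {
  s <- as.character(s)
  if (!all(s %in% c("+", "-"))) {
    stop(what, " strand must be '+' or '-' (iCLIP signal is strand-specific)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Round a ratio to a percentage
#'
#' Computes `100 * part / whole` rounded half-up to a fixed number of decimal
#' places, the convention used for all percentage summaries in the package.
#'
#' @param part Numerator count (`part <= whole`).
#' @param whole Denominator count (strictly positive).
#' @param decimals Number of decimal places (default 1).
#' @return A numeric percentage.
#' @examples
#' percentage(162, 381)      # 42.5
#' percentage(43, 160, 0)    # 27
#' @export
percentage <- function(part, whole, decimals = 1) {
  if (any(whole == 0)) stop("'whole' must be > 0", call. = FALSE)
  if (any(part > whole)) stop("'part' must not exceed 'whole'", call. = FALSE)
  if (any(part < 0)) stop("'part' must be non-negative", call. = FALSE)
  f <- 10^decimals
  floor(100 * part / whole * f + 0.5) / f
}

# Strand-aware sequence extraction from an in-memory genome (DNAStringSet).
.get_seq <- function(genome, chrom, start, end, strand) {
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  n <- length(start)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(genome)) {
      stop("unknown chromosome: ", chrom[i], call. = FALSE)
    }
    s <- Biostrings::subseq(genome[[chrom[i]]], start = start[i], end = end[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  Biostrings::DNAStringSet(out)
}

.get_seq_gr <- function(genome, gr) {
  .get_seq(genome, GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr),
           BiocGenerics::end(gr), BiocGenerics::strand(gr))
}

# seqlengths as a plain named integer vector from a DNAStringSet genome
.genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
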