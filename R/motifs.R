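#' Count k-mers in a set of sequences
#'
#' Counts all length-`k` windows of all sequences (a 9-nt sequence yields 4
#' hexamer windows); windows containing ambiguous bases are skipped. Counts
#' are reported over the full RNA k-mer space (U for T).
#'
#' @param seqs character vector or XStringSet (DNA or RNA letters accepted).
#' @param k k-mer length (default 6).
#' @param per_site Count each sequence at most once per k-mer (presence
#'   rather than multiplicity).
#' @return Named integer vector over all 4^k RNA k-mers.
#' @export
countKmers <- function(seqs, k = 6L, per_site = FALSE) {
  k <- as.integer(k)
  seqs <- Biostrings::DNAStringSet(.to_dna(seqs))
  if (!length(seqs)) {
    return(setNames(integer(0), character(0)))
  }
  if (k > min(Biostrings::width(seqs))) {
    stop("k exceeds the length of the shortest sequence", call. = FALSE)
  }
  m <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  counts <- if (per_site) colSums(m > 0L) else colSums(m)
  setNames(as.integer(counts), .to_rna(names(counts)))
}

# index of every valid 9-nt sampling window over a set of transcripts:
# returns list(seq = character vector of transcript sequences,
#              tx = transcript index per window, start = local start)
.window_index <- function(tx_seqs, w) {
  tx_chr <- as.character(tx_seqs)
  len <- nchar(tx_chr)
  keep <- len >= w
  if (!any(keep)) {
    stop("all transcripts are shorter than the sampling window", call. = FALSE)
  }
  tx_chr <- tx_chr[keep]
  len <- len[keep]
  n_win <- len - w + 1L
  list(seq = tx_chr,
       tx = rep.int(seq_along(tx_chr), n_win),
       start = unlist(lapply(n_win, seq_len), use.names = FALSE))
}

#' Sample background windows from target transcripts
#'
#' Draws `n` windows of width `w` uniformly over all valid start positions of
#' the supplied transcript sequences (with replacement) — the background
#' model used by [hexamerZscores()]. Transcripts shorter than `w` are
#' excluded.
#'
#' @param tx_seqs DNAStringSet (or character) of transcript sequences.
#' @param n Number of windows.
#' @param w Window width (default 9).
#' @param seed Integer seed.
#' @return Character vector of `n` window sequences.
#' @export
sampleBackgroundWindows <- function(tx_seqs, n, w = 9L, seed = NULL) {
  idx <- .window_index(Biostrings::DNAStringSet(.to_dna(tx_seqs)), w)
  draw <- function() {
    j <- sample.int(length(idx$tx), n, replace = TRUE)
    substring(idx$seq[idx$tx[j]], idx$start[j], idx$start[j] + w - 1L)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Hexamer enrichment z-scores against a resampled background
#'
#' Observed hexamer counts in the binding-site sequences are compared with
#' counts from `n_samples` background sets, each drawing the same number of
#' same-width windows uniformly from the target transcript sequences. For
#' each hexamer, `z = (observed - bg_mean) / bg_sd`; hexamers never seen in
#' the background (`bg_sd = 0`) are flagged and their z is reported missing.
#'
#' @param site_seqs Binding-site sequences (equal width, typically 9 nt).
#' @param tx_seqs Target transcript sequences (spliced, sense strand).
#' @param k k-mer length (default 6).
#' @param n_samples Number of background resamples (default 1000).
#' @param seed Integer seed.
#' @param per_site Presence/absence counting, see [countKmers()].
#' @return data.frame with columns `hexamer` (RNA alphabet), `observed`,
#'   `bg_mean`, `bg_sd`, `z`, `degenerate`, sorted by decreasing z (missing z
#'   last).
#' @export
hexamerZscores <- function(site_seqs, tx_seqs, k = 6L, n_samples = 1000L,
                           seed = 1L, per_site = FALSE) {
  site_seqs <- Biostrings::DNAStringSet(.to_dna(site_seqs))
  if (!length(site_seqs)) stop("no site sequences supplied", call. = FALSE)
  w <- unique(Biostrings::width(site_seqs))
  if (length(w) != 1L) stop("site sequences must have equal width")
  observed <- countKmers(site_seqs, k, per_site = per_site)
  n <- length(site_seqs)

  idx <- .window_index(Biostrings::DNAStringSet(.to_dna(tx_seqs)), w)
  n_win <- length(idx$tx)
  kmer_names <- names(observed)
  bg <- matrix(0, nrow = n_samples, ncol = length(kmer_names))
  withr::with_seed(seed, {
    for (s in seq_len(n_samples)) {
      j <- sample.int(n_win, n, replace = TRUE)
      wins <- Biostrings::DNAStringSet(
        substring(idx$seq[idx$tx[j]], idx$start[j], idx$start[j] + w - 1L))
      bg[s, ] <- if (per_site) {
        colSums(Biostrings::oligonucleotideFrequency(wins, width = k) > 0L)
      } else {
        Biostrings::oligonucleotideFrequency(wins, width = k,
                                             simplify.as = "collapsed")
      }
    }
  })
  bg_mean <- colMeans(bg)
  bg_sd <- sqrt(colSums(sweep(bg, 2, bg_mean)^2) / (n_samples - 1L))
  z <- ifelse(bg_sd > 0, (observed - bg_mean) / bg_sd, NA_real_)
  out <- data.frame(
    hexamer = kmer_names,
    observed = as.integer(observed),
    bg_mean = bg_mean,
    bg_sd = bg_sd,
    z = z,
    degenerate = bg_sd == 0,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$z, out$hexamer, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Scan sequences for exact motif matches
#'
#' Reports every exact occurrence (overlapping matches included) of `motif`
#' on the sense strand of the supplied sequences. U and T are equivalent.
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param motif Motif string over A/C/G/U(T), non-empty.
#' @return data.frame with `seq` (sequence name), `start` (1-based), `end`.
#' @export
scanMotif <- function(seqs, motif = "CAGA") {
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  nms <- names(seqs)
  seqs <- Biostrings::DNAStringSet(.to_dna(seqs))
  names(seqs) <- if (is.null(nms)) as.character(seq_along(seqs)) else nms
  pat <- Biostrings::DNAString(.to_dna(motif))
  hits <- Biostrings::vmatchPattern(pat, seqs)
  n_per <- S4Vectors::elementNROWS(hits)
  ir <- unlist(hits, use.names = FALSE)
  data.frame(
    seq = rep(names(seqs), n_per),
    start = BiocGenerics::start(ir),
    end = BiocGenerics::end(ir),
    stringsAsFactors = FALSE
  )
}

#' Scan a genome for motif matches on gene sense strands
#'
#' Scans chromosome sequences for exact matches of `motif` on the plus strand
#' and of its reverse complement on the minus strand, returning
#' strand-annotated genomic hits; downstream pairing restricts hits to the
#' host gene's strand.
#'
#' @param genome Named DNAStringSet.
#' @param motif Motif string (A/C/G/U or T).
#' @return GRanges of hits (width = motif length) with strand.
#' @export
scanMotifGenome <- function(genome, motif = "CAGA") {
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  pat <- Biostrings::DNAString(.to_dna(motif))
  rc <- Biostrings::reverseComplement(pat)
  out <- list()
  si <- GenomeInfoDb::Seqinfo(names(genome),
                              seqlengths = unname(Biostrings::width(genome)))
  for (ch in names(genome)) {
    fw <- Biostrings::matchPattern(pat, genome[[ch]])
    if (length(fw)) {
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(BiocGenerics::start(fw), BiocGenerics::end(fw)),
        strand = "+", seqinfo = si)
    }
    rv <- Biostrings::matchPattern(rc, genome[[ch]])
    if (length(rv)) {
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(BiocGenerics::start(rv), BiocGenerics::end(rv)),
        strand = "-", seqinfo = si)
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  BiocGenerics::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Binding-site peak distance to the nearest motif occurrence
#'
#' Pairs each binding-site peak with the nearest same-strand motif hit within
#' its host gene and reports the signed offset of the peak relative to the
#' motif's first base, in transcript orientation. Internally the offset is 0
#' when the peak sits exactly on the first motif base; the reported
#' `position` column shifts this by one so that the first motif base is
#' position 1 (e.g. the C of CAGA), the convention used for display.
#'
#' @param sites A [BindingSiteSet-class].
#' @param hits GRanges of motif hits, e.g. from [scanMotifGenome()].
#' @param ann A [GenomeAnnotation-class] (defines host genes).
#' @param window Offsets beyond +/- `window` are excluded from the histogram
#'   (default 50).
#' @return list with `offsets` (data.frame `site`, `gene_id`, `offset`,
#'   `position`), `histogram` (data.frame `position`, `count`) and `dropped`
#'   (sites whose host gene has no hit, or without a host gene).
#' @export
motifDistanceProfile <- function(sites, hits, ann, window = 50L) {
  peaks <- sitePeaks(sites)
  gene <- .host_gene(peaks, ann)
  gr <- .gene_ranges(ann)
  gh <- GenomicRanges::findOverlaps(hits, gr)
  hit_gene <- split(S4Vectors::queryHits(gh),
                    S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(gh)])
  # same-strand requirement: findOverlaps is strand-aware, hit strand must
  # match the gene strand to land in hit_gene
  off <- rep(NA_integer_, length(peaks))
  for (i in seq_along(peaks)) {
    g <- gene[i]
    if (is.na(g) || is.null(hit_gene[[g]])) next
    h <- hits[hit_gene[[g]]]
    st <- as.character(BiocGenerics::strand(peaks))[i]
    p <- BiocGenerics::start(peaks)[i]
    first_base <- if (st == "+") BiocGenerics::start(h) else
      BiocGenerics::end(h)
    dd <- if (st == "+") p - first_base else first_base - p
    off[i] <- as.integer(dd[order(abs(dd), dd)][1])
  }
  keep <- !is.na(off)
  offsets <- data.frame(
    site = S4Vectors::mcols(peaks)$name[keep],
    gene_id = gene[keep],
    offset = off[keep],
    position = off[keep] + 1L,
    stringsAsFactors = FALSE
  )
  inwin <- offsets$offset[abs(offsets$offset) <= window]
  histogram <- data.frame(
    position = (-window:window) + 1L,
    count = tabulate(inwin + window + 1L, nbins = 2L * window + 1L)
  )
  list(offsets = offsets, histogram = histogram, dropped = sum(!keep))
}

#' Fraction of binding sites matching motif patterns
#'
#' Counts, for each pattern, the binding sites containing at least one match
#' (a site counts once per pattern regardless of multiplicity). Literal
#' patterns are matched exactly (U/T equivalent); the special pattern
#' `"CU-rich"` matches sites with at least `min_pyrimidines` C/U bases.
#'
#' @param site_seqs Site sequences (character or XStringSet).
#' @param patterns Character vector of patterns.
#' @param min_pyrimidines Pyrimidine threshold for `"CU-rich"` (default 5, a
#'   pyrimidine majority of a 9-nt site).
#' @return data.frame with `pattern`, `n_sites`, `pct` (one decimal).
#' @export
motifSiteFraction <- function(site_seqs, patterns,
                              min_pyrimidines = 5L) {
  seqs <- Biostrings::DNAStringSet(.to_dna(site_seqs))
  n <- length(seqs)
  if (!n) stop("no site sequences supplied", call. = FALSE)
  counts <- vapply(patterns, function(p) {
    if (identical(toupper(p), "CU-RICH")) {
      pyr <- Biostrings::letterFrequency(seqs, letters = "CT")
      sum(pyr >= min_pyrimidines)
    } else {
      pat <- Biostrings::DNAString(.to_dna(p))
      sum(Biostrings::vcountPattern(pat, seqs) > 0L)
    }
  }, numeric(1))
  data.frame(
    pattern = patterns,
    n_sites = as.integer(counts),
    pct = percentage(as.integer(counts), n),
    stringsAsFactors = FALSE
  )
}
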