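#' Remove PCR duplicates from iCLIP reads
#'
#' Reads with identical mapping start position (per chromosome and strand)
#' and identical random barcode are collapsed to a single read; the first
#' occurrence survives, preserving relative order.
#'
#' @param reads data.frame with columns `chrom`, `start`, `strand`, `barcode`.
#' @return data.frame of surviving reads.
#' @export
dedupReads <- function(reads) {
  if (!nrow(reads)) return(reads)
  need <- c("chrom", "start", "strand", "barcode")
  stopifnot(all(need %in% names(reads)))
  if (any(!nzchar(reads$barcode))) stop("barcodes must be non-empty")
  key <- paste(reads$chrom, reads$strand, reads$start, reads$barcode,
               sep = "\r")
  reads[!duplicated(key), , drop = FALSE]
}

#' Merge immediately adjacent crosslink peaks
#'
#' Peaks at directly adjacent nucleotides (same chromosome and strand,
#' positions i, i+1, i+2, ...) are grouped into maximal runs and only the
#' peak with the highest score in each run is kept. A gap of two or more
#' nucleotides breaks a run. Equal-score ties keep the 5'-most peak in
#' transcript orientation.
#'
#' @param peaks Width-1 GRanges with a finite `score` column.
#' @return GRanges of retained peaks, sorted by (chrom, strand, position).
#' @export
mergeAdjacentPeaks <- function(peaks) {
  if (!length(peaks)) return(peaks)
  .check_strand(BiocGenerics::strand(peaks), "peak")
  key <- paste(GenomeInfoDb::seqnames(peaks), BiocGenerics::strand(peaks),
               BiocGenerics::start(peaks))
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, strand, position) peak entries", call. = FALSE)
  }
  p <- .sort_peaks(peaks)
  ch <- as.character(GenomeInfoDb::seqnames(p))
  st <- as.character(BiocGenerics::strand(p))
  pos <- BiocGenerics::start(p)
  n <- length(p)
  new_run <- c(TRUE, !(ch[-1] == ch[-n] & st[-1] == st[-n] &
                         pos[-1] == pos[-n] + 1L))
  run <- cumsum(new_run)
  sc <- S4Vectors::mcols(p)$score
  sel <- vapply(split(seq_len(n), run), function(ix) {
    best <- ix[sc[ix] == max(sc[ix])]
    # 5'-most in transcript orientation: genomic min on '+', max on '-'
    if (st[ix[1]] == "-") max(best) else min(best)
  }, integer(1))
  p[sort(unname(sel))]
}

#' Define 9-nt binding sites from merged peaks
#'
#' Each retained peak is extended by `flank` nucleotides upstream and
#' downstream (default 4 nt, giving 9-nt sites); the centre of the window is
#' the binding-site peak. Windows that would cross a chromosome boundary are
#' dropped (with a message) to preserve the fixed site width.
#'
#' @param peaks Width-1 GRanges of merged peaks with `score`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param flank Extension on each side (default 4).
#' @return A [BindingSiteSet-class].
#' @export
defineBindingSites <- function(peaks, chrom_lengths, flank = 4L) {
  flank <- as.integer(flank)
  ch <- as.character(GenomeInfoDb::seqnames(peaks))
  unknown <- setdiff(unique(ch), names(chrom_lengths))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pos <- BiocGenerics::start(peaks)
  len <- unname(chrom_lengths[ch])
  keep <- pos - flank >= 1L & pos + flank <= len
  if (any(!keep)) {
    message(sum(!keep), " peak(s) dropped: site window crosses a ",
            "chromosome boundary")
  }
  p <- peaks[keep]
  pos <- pos[keep]
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(p),
    IRanges::IRanges(pos - flank, pos + flank),
    strand = BiocGenerics::strand(p),
    name = sprintf("site_%05d", seq_along(p)),
    score = S4Vectors::mcols(p)$score,
    peak = pos
  )
  methods::new("BindingSiteSet", sites = gr,
               params = list(flank = flank))
}

#' Subtract control-proximal binding sites
#'
#' A protein binding site is removed when a same-strand control site lies
#' within `max_dist` nucleotides (inclusive). The distance anchor is
#' centre-to-centre between binding-site peaks by default
#' (`anchor = "peak"`); `anchor = "interval"` measures the gap between the
#' 9-nt windows instead. Kept and removed sites partition the input.
#'
#' @param sites Protein [BindingSiteSet-class].
#' @param control_sites Control [BindingSiteSet-class].
#' @param max_dist Inclusive distance threshold in nt (default 9).
#' @param anchor `"peak"` (default) or `"interval"`.
#' @return list with `kept` (BindingSiteSet), `removed` (BindingSiteSet) and
#'   `removed_count`.
#' @export
subtractControlSites <- function(sites, control_sites, max_dist = 9L,
                                 anchor = c("peak", "interval")) {
  anchor <- match.arg(anchor)
  p <- siteRanges(sites)
  ctl <- siteRanges(control_sites)
  if (!length(p) || !length(ctl)) {
    return(list(kept = sites,
                removed = methods::new("BindingSiteSet",
                                       sites = p[integer(0)],
                                       params = sites@params),
                removed_count = 0L))
  }
  if (anchor == "peak") {
    q <- sitePeaks(sites)
    s <- sitePeaks(control_sites)
    # width-1 points: |peak_p - peak_c| <= max_dist  <=>  gap <= max_dist - 1
    hits <- GenomicRanges::findOverlaps(q, s, maxgap = max_dist - 1L)
  } else {
    hits <- GenomicRanges::findOverlaps(p, ctl, maxgap = max_dist)
  }
  rm_idx <- unique(S4Vectors::queryHits(hits))
  keep <- setdiff(seq_along(p), rm_idx)
  list(
    kept = methods::new("BindingSiteSet", sites = p[keep],
                        params = sites@params),
    removed = methods::new("BindingSiteSet", sites = p[sort(rm_idx)],
                           params = sites@params),
    removed_count = length(rm_idx)
  )
}

#' Full site-calling pipeline
#'
#' Merges adjacent peaks, extends to 9-nt sites and subtracts
#' control-proximal sites for a protein/control peak pair.
#'
#' @param protein_peaks,control_peaks Width-1 GRanges with `score`.
#' @param chrom_lengths Named chromosome lengths.
#' @param config A [clipConfig()] bundle.
#' @param anchor Subtraction anchor, see [subtractControlSites()].
#' @return list with `sites` (kept BindingSiteSet), `removed_count`,
#'   `candidate_count` (protein sites before subtraction) and
#'   `control_count`.
#' @export
callBindingSites <- function(protein_peaks, control_peaks, chrom_lengths,
                             config = clipConfig(), anchor = "peak") {
  th <- config$thresholds
  pm <- mergeAdjacentPeaks(protein_peaks)
  cm <- mergeAdjacentPeaks(control_peaks)
  ps <- defineBindingSites(pm, chrom_lengths, flank = th$flank)
  cs <- defineBindingSites(cm, chrom_lengths, flank = th$flank)
  sub <- subtractControlSites(ps, cs, max_dist = th$subtract_dist,
                              anchor = anchor)
  list(sites = sub$kept, removed_count = sub$removed_count,
       candidate_count = length(ps), control_count = length(cs))
}
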