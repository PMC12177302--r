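#' @noRd
.gene_ranges <- function(ann) {
  g <- genes(ann)
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}

# host gene per peak: same-strand gene whose span contains the peak;
# ties between overlapping genes resolved by lexicographic gene id
.host_gene <- function(peaks, ann) {
  gr <- .gene_ranges(ann)
  hits <- GenomicRanges::findOverlaps(peaks, gr)
  host <- rep(NA_character_, length(peaks))
  if (length(hits)) {
    gid <- S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)]
    q <- S4Vectors::queryHits(hits)
    o <- order(q, gid)
    first <- !duplicated(q[o])
    host[q[o][first]] <- gid[o][first]
  }
  host
}

#' Assign binding sites to transcript features
#'
#' Each site is assigned to a feature (5' UTR, CDS, intron, 3' UTR) of the
#' representative transcript of its host gene, or to `intergenic`. A site
#' overlapping a feature by at least one nucleotide of its window qualifies;
#' when the window spans a feature boundary the assignment follows the
#' binding-site peak (centre) position.
#'
#' @param sites A [BindingSiteSet-class].
#' @param ann A [GenomeAnnotation-class].
#' @param min_exon_len Minimum exon length for the 5' splice-site distance
#'   annotation (default 50 nt).
#' @param tss_window Window for the TSS distance annotation (default 250 nt).
#' @return list with
#'   `site_annotation` (data.frame: `site`, `gene_id`, `feature`,
#'   `dist_to_tss`, `dist_to_5ss`), `gene_summary` (one row per gene with at
#'   least one site; logical columns per feature) and `feature_percentages`
#'   (per-feature gene counts and percentages over the site-bearing genes;
#'   these may sum to more than 100 because a gene can carry sites in several
#'   features).
#' @export
assignFeatures <- function(sites, ann, min_exon_len = 50L,
                           tss_window = 250L) {
  peaks <- sitePeaks(sites)
  win <- siteRanges(sites)
  featR <- featureRanges(ann)

  feature <- rep("intergenic", length(peaks))
  gene <- rep(NA_character_, length(peaks))

  # primary: feature containing the peak
  hits <- GenomicRanges::findOverlaps(peaks, featR)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    gid <- S4Vectors::mcols(featR)$gene_id[s]
    o <- order(q, gid)
    first <- !duplicated(q[o])
    feature[q[o][first]] <- S4Vectors::mcols(featR)$feature[s][o][first]
    gene[q[o][first]] <- gid[o][first]
  }

  # fallback: window overlap by >= 1 nt, largest overlap wins
  unassigned <- which(is.na(gene))
  if (length(unassigned)) {
    hits2 <- GenomicRanges::findOverlaps(win[unassigned], featR)
    if (length(hits2)) {
      q <- S4Vectors::queryHits(hits2)
      s <- S4Vectors::subjectHits(hits2)
      ovw <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(win[unassigned])[q], IRanges::ranges(featR)[s]))
      o <- order(q, -ovw, S4Vectors::mcols(featR)$gene_id[s])
      first <- !duplicated(q[o])
      feature[unassigned[q[o][first]]] <-
        S4Vectors::mcols(featR)$feature[s][o][first]
      gene[unassigned[q[o][first]]] <-
        S4Vectors::mcols(featR)$gene_id[s][o][first]
    }
  }
  n_intergenic <- sum(is.na(gene))
  if (n_intergenic) {
    message(n_intergenic, " site(s) outside annotated transcripts ",
            "(assigned intergenic)")
  }

  tssd <- .tss_distances(peaks, gene, ann, tss_window)
  ssd <- .donor_distances(peaks, gene, ann, min_exon_len)

  site_annotation <- data.frame(
    site = S4Vectors::mcols(peaks)$name,
    gene_id = gene,
    feature = feature,
    dist_to_tss = tssd,
    dist_to_5ss = ssd,
    stringsAsFactors = FALSE
  )

  with_gene <- !is.na(gene)
  feats <- c("5UTR", "CDS", "intron", "3UTR")
  target_genes <- sort(unique(gene[with_gene]))
  gene_summary <- data.frame(gene_id = target_genes, stringsAsFactors = FALSE)
  for (f in feats) {
    gene_summary[[f]] <- target_genes %in% gene[with_gene & feature == f]
  }
  n_target <- length(target_genes)
  feature_percentages <- data.frame(
    feature = feats,
    n_genes = vapply(feats, function(f) sum(gene_summary[[f]]), integer(1)),
    stringsAsFactors = FALSE
  )
  feature_percentages$pct <- if (n_target) {
    percentage(feature_percentages$n_genes, n_target)
  } else NA_real_
  rownames(feature_percentages) <- NULL

  list(site_annotation = site_annotation, gene_summary = gene_summary,
       feature_percentages = feature_percentages, n_target_genes = n_target)
}

# gene TSS: 5' end of the representative transcript (or a supplied table)
.gene_tss <- function(ann, tss = NULL) {
  if (!is.null(tss)) return(tss)
  tx <- transcripts(ann)
  rep <- tx[tx$representative, ]
  setNames(ifelse(rep$strand == "+", rep$start, rep$end), rep$gene_id)
}

.tss_distances <- function(peaks, gene, ann, window, tss = NULL) {
  tss_pos <- .gene_tss(ann, tss)
  g <- genes(ann)
  strand_of <- setNames(g$strand, g$gene_id)
  d <- rep(NA_integer_, length(peaks))
  ok <- !is.na(gene) & gene %in% names(tss_pos)
  if (any(ok)) {
    p <- BiocGenerics::start(peaks)[ok]
    t0 <- unname(tss_pos[gene[ok]])
    st <- unname(strand_of[gene[ok]])
    dd <- ifelse(st == "+", p - t0, t0 - p)
    dd[dd < 0 | dd > window] <- NA_integer_
    d[ok] <- as.integer(dd)
  }
  d
}

# qualifying donor 5' splice sites: exon >= min_exon_len followed by an
# intron, representative transcripts only
.donor_sites <- function(ann, min_exon_len = 50L) {
  ex <- exons(ann)
  rep_tx <- representativeTx(ann)
  keep <- as.character(S4Vectors::mcols(ex)$transcript_id) %in% rep_tx
  ex <- ex[keep]
  tx_id <- as.character(S4Vectors::mcols(ex)$transcript_id)
  rank <- S4Vectors::mcols(ex)$exon_rank
  n_ex <- stats::ave(rank, tx_id, FUN = max)
  donors <- ex[rank < n_ex & BiocGenerics::width(ex) >= min_exon_len]
  if (!length(donors)) {
    return(GenomicRanges::GRanges(gene_id = character(0)))
  }
  st <- as.character(BiocGenerics::strand(donors))
  pos <- ifelse(st == "+", BiocGenerics::end(donors),
                BiocGenerics::start(donors))
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(donors),
                         IRanges::IRanges(pos, width = 1L), strand = st,
                         gene_id = S4Vectors::mcols(donors)$gene_id)
}

# signed distance (transcript orientation) from each peak to the nearest
# qualifying donor of its host gene; negative = upstream/exonic side
.donor_distances <- function(peaks, gene, ann, min_exon_len = 50L) {
  donors <- .donor_sites(ann, min_exon_len)
  d_out <- rep(NA_integer_, length(peaks))
  if (!length(donors)) return(d_out)
  dg <- split(seq_along(donors), S4Vectors::mcols(donors)$gene_id)
  dpos <- BiocGenerics::start(donors)
  for (i in seq_along(peaks)) {
    g <- gene[i]
    if (is.na(g) || is.null(dg[[g]])) next
    st <- as.character(BiocGenerics::strand(peaks))[i]
    p <- BiocGenerics::start(peaks)[i]
    dd <- if (st == "+") p - dpos[dg[[g]]] else dpos[dg[[g]]] - p
    best <- dd[order(abs(dd), dd)][1]   # tie prefers the upstream (negative)
    d_out[i] <- as.integer(best)
  }
  d_out
}

#' Binding-site peak distance to the transcription start site
#'
#' Histogram of binding-site peaks falling up to `window` nt downstream of
#' the gene TSS (the 5' end of the representative transcript, or a supplied
#' per-gene TSS table), strand-aware. Sites upstream of the TSS or beyond the
#' window are excluded.
#'
#' @param sites A [BindingSiteSet-class].
#' @param ann A [GenomeAnnotation-class].
#' @param window Window size in nt (default 250).
#' @param tss Optional named vector of TSS positions (gene_id -> 1-based
#'   genomic position), e.g. from an external TSS catalogue.
#' @return list with `distances` (data.frame `site`, `gene_id`, `dist`) and
#'   `histogram` (data.frame `dist` 0..window, `count`).
#' @export
tssProfile <- function(sites, ann, window = 250L, tss = NULL) {
  peaks <- sitePeaks(sites)
  gene <- .host_gene(peaks, ann)
  d <- .tss_distances(peaks, gene, ann, window, tss)
  keep <- !is.na(d)
  distances <- data.frame(site = S4Vectors::mcols(peaks)$name[keep],
                          gene_id = gene[keep], dist = d[keep],
                          stringsAsFactors = FALSE)
  histogram <- data.frame(dist = 0:window,
                          count = tabulate(d[keep] + 1L, nbins = window + 1L))
  list(distances = distances, histogram = histogram)
}

#' Binding-site peak distance to the 5' splice site
#'
#' For each site, the signed distance (transcript orientation) from the peak
#' to the nearest qualifying donor splice site of its host gene. Only exons
#' of at least `min_exon_len` nt that are followed by an intron provide
#' donors; negative distances are upstream of the donor (exonic side).
#'
#' @inheritParams tssProfile
#' @param min_exon_len Minimum exon length (default 50 nt).
#' @param window Half-width of the reported histogram (default 100 nt).
#' @return list with `distances` (data.frame), `histogram` (data.frame over
#'   -window..window) and `density` (a [stats::density] fit, or NULL for
#'   fewer than 2 observations).
#' @export
donorProfile <- function(sites, ann, min_exon_len = 50L, window = 100L) {
  peaks <- sitePeaks(sites)
  gene <- .host_gene(peaks, ann)
  d <- .donor_distances(peaks, gene, ann, min_exon_len)
  keep <- !is.na(d)
  distances <- data.frame(site = S4Vectors::mcols(peaks)$name[keep],
                          gene_id = gene[keep], dist = d[keep],
                          stringsAsFactors = FALSE)
  inwin <- distances$dist[abs(distances$dist) <= window]
  histogram <- data.frame(
    dist = -window:window,
    count = tabulate(inwin + window + 1L, nbins = 2L * window + 1L)
  )
  dens <- if (length(inwin) >= 2) stats::density(inwin) else NULL
  list(distances = distances, histogram = histogram, density = dens)
}

#' Sequences around peaks upstream of 5' splice sites
#'
#' Extracts fixed-width windows (default 21 nt) centred on binding-site peaks
#' whose distance to the nearest qualifying 5' splice site falls in `zone`
#' (default 25 to 30 nt upstream). Windows are stacked at the peak anchor (no
#' multiple alignment is needed for fixed-width, peak-centred windows) into a
#' position frequency matrix; minus-strand windows are reverse-complemented.
#'
#' @inheritParams donorProfile
#' @param genome Named DNAStringSet.
#' @param zone Length-2 signed distance zone, default `c(-30, -25)`.
#' @param window Window width (odd, default 21).
#' @return list with `sequences` (DNAStringSet), `pfm` (4 x window base count
#'   matrix; column sums equal the number of sequences),
#'   `pyrimidine_fraction` (per-column C+T fraction) and `n`.
#' @export
upstreamWindows <- function(sites, ann, genome, zone = c(-30L, -25L),
                            window = 21L, min_exon_len = 50L) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  prof <- donorProfile(sites, ann, min_exon_len = min_exon_len)
  dd <- prof$distances
  sel <- dd[dd$dist >= zone[1] & dd$dist <= zone[2], , drop = FALSE]
  peaks <- sitePeaks(sites)
  idx <- match(sel$site, S4Vectors::mcols(peaks)$name)
  p <- BiocGenerics::start(peaks)[idx]
  ch <- as.character(GenomeInfoDb::seqnames(peaks))[idx]
  st <- as.character(BiocGenerics::strand(peaks))[idx]
  glen <- .genome_lengths(genome)
  ok <- p - half >= 1L & p + half <= unname(glen[ch])
  if (any(!ok)) {
    message(sum(!ok), " window(s) dropped: crossing a contig end")
  }
  seqs <- if (any(ok)) {
    .get_seq(genome, ch[ok], p[ok] - half, p[ok] + half, st[ok])
  } else Biostrings::DNAStringSet()
  if (length(seqs)) names(seqs) <- sel$site[ok]
  pfm <- if (length(seqs)) {
    Biostrings::consensusMatrix(seqs)[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    matrix(0L, 4, window, dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  pyr <- if (length(seqs)) {
    colSums(pfm[c("C", "T"), , drop = FALSE]) / colSums(pfm)
  } else rep(NA_real_, window)
  list(sequences = seqs, pfm = pfm, pyrimidine_fraction = pyr,
       n = length(seqs))
}
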