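#' Pipeline configuration
#'
#' Bundles the seed and the analysis thresholds with their standard defaults:
#' peak extension `flank = 4` nt (9-nt sites), control subtraction distance
#' `subtract_dist = 9` nt, minimum exon length for 5' splice-site profiles
#' `min_exon_len = 50` nt, TSS profile window `tss_window = 250` nt, k-mer
#' size `kmer_k = 6`, background resamples `n_background = 1000`, DAS gates
#' `min_prob = 0.9` and `min_dpsi = 0.1`, strong-shift cut `strong_dpsi = 0.3`,
#' differential-expression gates `l2fc_cut = 1` and `adjp_cut = 0.05`, and the
#' expression filter `cpm_cut = 1` in at least `cpm_min_samples = 3` samples.
#'
#' @param seed Integer seed used by every stochastic operation.
#' @param ... Named threshold overrides.
#' @return A list with elements `seed` and `thresholds`
#'   (class `clip_config`).
#' @export
clipConfig <- function(seed = 1L, ...) {
  thresholds <- list(
    flank = 4L, subtract_dist = 9L, min_exon_len = 50L, tss_window = 250L,
    kmer_k = 6L, n_background = 1000L, min_prob = 0.9, min_dpsi = 0.1,
    strong_dpsi = 0.3, l2fc_cut = 1, adjp_cut = 0.05, cpm_cut = 1,
    cpm_min_samples = 3L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(thresholds))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  thresholds[names(dots)] <- dots
  structure(list(seed = as.integer(seed), thresholds = thresholds),
            class = "clip_config")
}

#' @rdname clipConfig
#' @param path JSON file path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname clipConfig
#' @param config A `clip_config` object.
#' @export
readConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(clipConfig, c(list(seed = raw$seed), raw$thresholds))
}

#' Read a transcript annotation (GTF or GFF3)
#'
#' Parses annotation into a [GenomeAnnotation-class]. GTF attributes
#' `gene_id`/`transcript_id` are used directly; GFF3 `ID`/`Parent` chains are
#' resolved (gene <- mRNA <- exon/CDS). A transcript attribute
#' `representative "TRUE"` marks the representative model; otherwise the
#' longest-CDS rule applies (see [GenomeAnnotation()]). Transcript records
#' without exons are dropped with a warning.
#'
#' @param path GTF or GFF3 file.
#' @param seqlens Optional named chromosome lengths.
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(path, seqlens = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if (!"gene_id" %in% names(mc) && "Parent" %in% names(mc)) {
    gr <- .resolve_gff3(gr)
    mc <- S4Vectors::mcols(gr)
    type <- as.character(mc$type)
  }
  ex <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  if (!length(ex)) stop("annotation contains no exon records")

  tx_rows <- gr[type %in% c("transcript", "mRNA")]
  if (length(tx_rows)) {
    no_exon <- setdiff(as.character(S4Vectors::mcols(tx_rows)$transcript_id),
                       as.character(S4Vectors::mcols(ex)$transcript_id))
    if (length(no_exon)) {
      warning("dropping transcript record(s) without exons: ",
              paste(no_exon, collapse = ", "))
    }
  }

  representative <- NULL
  if ("representative" %in% names(S4Vectors::mcols(tx_rows))) {
    flag <- toupper(as.character(S4Vectors::mcols(tx_rows)$representative))
    representative <-
      as.character(S4Vectors::mcols(tx_rows)$transcript_id)[flag %in%
                                                            c("TRUE", "1")]
    if (!length(representative)) representative <- NULL
  }

  keep <- c("transcript_id", "gene_id")
  exo <- GenomicRanges::granges(ex)
  S4Vectors::mcols(exo) <- S4Vectors::mcols(ex)[, keep]
  cdso <- GenomicRanges::granges(cds)
  if (length(cds)) S4Vectors::mcols(cdso) <- S4Vectors::mcols(cds)[, keep]
  GenomeAnnotation(exo, cdso, representative = representative,
                   seqlens = seqlens)
}

# map GFF3 ID/Parent attributes onto gene_id/transcript_id columns
.resolve_gff3 <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- vapply(mc$Parent, function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  is_tx <- type %in% c("mRNA", "transcript")
  gene_of_tx <- setNames(parent[is_tx], id[is_tx])
  tx_id <- ifelse(is_tx, id, parent)
  gene_id <- ifelse(type == "gene", id,
                    ifelse(is_tx, parent, unname(gene_of_tx[parent])))
  S4Vectors::mcols(gr)$transcript_id <- tx_id
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$type <- ifelse(is_tx, "transcript", type)
  gr
}

#' Write a GenomeAnnotation as GTF
#'
#' Emits gene, transcript, exon and CDS records (1-based closed coordinates).
#' Representative transcripts carry the attribute `representative "TRUE"`, so
#' a write/read round trip preserves the representative flag.
#'
#' @param ann A [GenomeAnnotation-class].
#' @param path Output path.
#' @export
writeAnnotationGTF <- function(ann, path) {
  gt <- genes(ann)
  tx <- transcripts(ann)
  ex <- exons(ann)
  cds <- cdsParts(ann)
  att <- function(g, t = NULL, rep = NULL) {
    a <- sprintf('gene_id "%s";', g)
    if (!is.null(t)) a <- paste(a, sprintf('transcript_id "%s";', t))
    if (!is.null(rep)) {
      a <- paste(a, sprintf('representative "%s";', ifelse(rep, "TRUE",
                                                           "FALSE")))
    }
    a
  }
  lines <- c(
    sprintf("%s\tclipsplice\tgene\t%d\t%d\t.\t%s\t.\t%s",
            gt$chrom, gt$start, gt$end, gt$strand, att(gt$gene_id)),
    sprintf("%s\tclipsplice\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, tx$start, tx$end, tx$strand,
            att(tx$gene_id, tx$transcript_id, tx$representative)),
    sprintf("%s\tclipsplice\texon\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomeInfoDb::seqnames(ex)),
            BiocGenerics::start(ex), BiocGenerics::end(ex),
            as.character(BiocGenerics::strand(ex)),
            att(S4Vectors::mcols(ex)$gene_id,
                S4Vectors::mcols(ex)$transcript_id))
  )
  if (length(cds)) {
    lines <- c(lines,
      sprintf("%s\tclipsplice\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              as.character(GenomeInfoDb::seqnames(cds)),
              BiocGenerics::start(cds), BiocGenerics::end(cds),
              as.character(BiocGenerics::strand(cds)),
              att(S4Vectors::mcols(cds)$gene_id,
                  S4Vectors::mcols(cds)$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-nucleotide crosslink peaks (BED6)
#'
#' Each record must be a single-nucleotide interval (`end = start + 1` in BED
#' coordinates) with a finite numeric score and an explicit strand. Peaks are
#' returned sorted by (chrom, strand, position).
#'
#' @param path BED6 file; an empty file yields an empty result.
#' @return GRanges of width-1 peaks with `name` and `score`.
#' @export
readPeaks <- function(path) {
  if (file.info(path)$size == 0) {
    gr0 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr0) <- S4Vectors::DataFrame(name = character(0),
                                                  score = numeric(0))
    return(gr0)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(BiocGenerics::width(gr) == 1L)) {
    stop("crosslink peaks must be single-nucleotide intervals ",
         "(BED end = start + 1)", call. = FALSE)
  }
  .check_strand(BiocGenerics::strand(gr), "peak")
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc) || !all(is.finite(sc))) {
    stop("peak scores must be finite numbers", call. = FALSE)
  }
  .sort_peaks(gr)
}

.sort_peaks <- function(gr) {
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             as.character(BiocGenerics::strand(gr)),
             BiocGenerics::start(gr))
  gr[o]
}

#' @rdname readPeaks
#' @param peaks Width-1 GRanges with `score` (and optionally `name`).
#' @export
writePeaks <- function(peaks, path) {
  if (is.null(S4Vectors::mcols(peaks)$name)) {
    S4Vectors::mcols(peaks)$name <- sprintf("peak_%05d", seq_along(peaks))
  }
  .write_bed6(
    as.character(GenomeInfoDb::seqnames(peaks)),
    BiocGenerics::start(peaks) - 1L, BiocGenerics::end(peaks),
    S4Vectors::mcols(peaks)$name, S4Vectors::mcols(peaks)$score,
    as.character(BiocGenerics::strand(peaks)), path
  )
}

.write_bed6 <- function(chrom, start0, end, name, score, strand, path) {
  if (!length(chrom)) {
    file.create(path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, start0, end, name,
                     format(score, trim = TRUE, scientific = FALSE),
                     strand), path)
  invisible(path)
}

#' Write and read binding sites (BED6)
#'
#' Sites are written 0-based half-open; a site whose peak sits at 0-based
#' genomic position 100 is emitted as `start 96, end 105`. The score column
#' carries the retained peak score, and a write/read round trip returns an
#' identical site set.
#'
#' @param sites A [BindingSiteSet-class] (all widths 9).
#' @param path Output BED path.
#' @export
writeSites <- function(sites, path) {
  methods::validObject(sites)
  gr <- siteRanges(sites)
  .write_bed6(
    as.character(GenomeInfoDb::seqnames(gr)),
    BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
    S4Vectors::mcols(gr)$name, S4Vectors::mcols(gr)$score,
    as.character(BiocGenerics::strand(gr)), path
  )
}

#' @rdname writeSites
#' @param flank Half-width of the site window (default 4, i.e. 9-nt sites).
#' @export
readSites <- function(path, flank = 4L) {
  w <- 2L * flank + 1L
  if (file.info(path)$size == 0) {
    gr0 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr0) <- S4Vectors::DataFrame(
      name = character(0), score = numeric(0), peak = integer(0))
    return(methods::new("BindingSiteSet", sites = gr0,
                        params = list(flank = flank)))
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (!all(BiocGenerics::width(gr) == w)) {
    stop("binding sites must have width ", w, call. = FALSE)
  }
  .check_strand(BiocGenerics::strand(gr), "site")
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(gr)$name,
    score = S4Vectors::mcols(gr)$score,
    peak = BiocGenerics::start(gr) + flank
  )
  methods::new("BindingSiteSet", sites = out, params = list(flank = flank))
}

#' Genome FASTA I/O
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that keep only the first word of each
#' FASTA header as the chromosome name.
#'
#' @param path FASTA file.
#' @return Named DNAStringSet.
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname readGenomeFasta
#' @param genome Named DNAStringSet.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and duplicates are dropped.
#'
#' @param path Text file.
#' @return Character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Junction/intron count table I/O
#'
#' The count contract is a TSV with header and columns `event_id`,
#' `sample_id`, `condition`, `replicate`, `inclusion`, `exclusion`.
#'
#' @param path TSV file.
#' @return data.frame of counts.
#' @export
readCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("event_id", "sample_id", "condition", "replicate", "inclusion",
            "exclusion")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$inclusion < 0 | df$exclusion < 0)) {
    stop("counts must be non-negative")
  }
  df
}

#' @rdname readCounts
#' @param counts data.frame of counts.
#' @export
writeCounts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
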