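#' @rdname GenomeAnnotation-class
#' @param x A `GenomeAnnotation` or `BindingSiteSet` object.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("cdsParts", function(x) standardGeneric("cdsParts"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("representativeTx", function(x) standardGeneric("representativeTx"))

#' @rdname BindingSiteSet-class
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname BindingSiteSet-class
#' @export
setGeneric("sitePeaks", function(x) standardGeneric("sitePeaks"))

#' @rdname BindingSiteSet-class
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @describeIn GenomeAnnotation-class Exons (GRanges, ranked 5' to 3').
#' @export
setMethod("exons", "GenomeAnnotation", function(x) x@exons)

#' @describeIn GenomeAnnotation-class Per-exon CDS segments (GRanges).
#' @export
setMethod("cdsParts", "GenomeAnnotation", function(x) x@cds)

#' @describeIn GenomeAnnotation-class Transcript table (data.frame).
#' @export
setMethod("transcripts", "GenomeAnnotation", function(x) x@transcripts)

#' @describeIn GenomeAnnotation-class Gene table (data.frame).
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation-class Named character vector mapping
#'   `gene_id` to the representative `transcript_id`.
#' @export
setMethod("representativeTx", "GenomeAnnotation", function(x) {
  tx <- x@transcripts
  setNames(tx$transcript_id[tx$representative], tx$gene_id[tx$representative])
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", nrow(object@genes), "genes,",
      nrow(object@transcripts), "transcripts,",
      length(object@exons), "exons,",
      length(object@cds), "CDS segments\n")
})

#' @describeIn BindingSiteSet-class Site windows (GRanges).
#' @export
setMethod("siteRanges", "BindingSiteSet", function(x) x@sites)

#' @describeIn BindingSiteSet-class Width-1 GRanges of the binding-site peaks
#'   (centre nucleotides), carrying the site names and scores.
#' @export
setMethod("sitePeaks", "BindingSiteSet", function(x) {
  gr <- x@sites
  pk <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr),
    IRanges::IRanges(S4Vectors::mcols(gr)$peak, width = 1L),
    strand = BiocGenerics::strand(gr),
    name = S4Vectors::mcols(gr)$name,
    score = S4Vectors::mcols(gr)$score,
    seqinfo = GenomeInfoDb::seqinfo(gr)
  )
  pk
})

#' @describeIn BindingSiteSet-class Retained peak scores.
#' @export
setMethod("siteScores", "BindingSiteSet", function(x) {
  S4Vectors::mcols(x@sites)$score
})

#' @describeIn BindingSiteSet-class Number of sites.
#' @export
setMethod("length", "BindingSiteSet", function(x) length(x@sites))

setMethod("show", "BindingSiteSet", function(object) {
  cat("BindingSiteSet with", length(object@sites), "sites of width",
      if (length(object@sites)) unique(BiocGenerics::width(object@sites)) else
        2L * (object@params$flank %||% 4L) + 1L, "\n")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult\n")
  cat(sprintf("  sets: n1 = %d, n2 = %d, universe N = %d\n",
              object@n1, object@n2, object@N))
  cat(sprintf("  overlap: observed = %d, expected = %.3f\n",
              object@observed, object@expected))
  cat(sprintf("  representation factor = %.3f\n",
              object@representation_factor))
  cat(sprintf("  P(X >= observed) = %.4g  [%s]\n",
              object@p_value, object@method))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
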