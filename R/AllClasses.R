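#' GenomeAnnotation: genes, transcripts and exon models
#'
#' Container for a transcript annotation: ordered exons and CDS segments per
#' transcript, a transcript table and a gene table, with exactly one
#' representative transcript flagged per gene. Coordinates follow the
#' Bioconductor convention (1-based, closed intervals, held in
#' [GenomicRanges::GRanges]); GTF input/output is therefore a direct copy and
#' BED input/output converts on the boundary.
#'
#' @slot exons GRanges with metadata columns `transcript_id`, `gene_id` and
#'   `exon_rank` (1 = most 5' exon in transcript orientation).
#' @slot cds GRanges of per-exon CDS segments with `transcript_id`, `gene_id`.
#' @slot transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `cds_length`, `representative`.
#' @slot genes data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @export
setClass("GenomeAnnotation",
  slots = c(
    exons = "GRanges",
    cds = "GRanges",
    transcripts = "data.frame",
    genes = "data.frame"
  )
)

setValidity("GenomeAnnotation", function(object) {
  ex <- object@exons
  msgs <- character(0)
  need <- c("transcript_id", "gene_id", "exon_rank")
  if (!all(need %in% names(S4Vectors::mcols(ex)))) {
    return(paste("exons must carry metadata columns:",
                 paste(need, collapse = ", ")))
  }
  tx <- S4Vectors::mcols(ex)$transcript_id
  ch <- as.character(GenomeInfoDb::seqnames(ex))
  st <- as.character(BiocGenerics::strand(ex))
  if (any(st == "*")) msgs <- c(msgs, "exon strand must be '+' or '-'")
  if (length(ex)) {
    one <- vapply(split(paste(ch, st), tx),
                  function(z) length(unique(z)) == 1L, logical(1))
    if (!all(one)) {
      msgs <- c(msgs, "all exons of a transcript must share chrom and strand")
    }
  }
  rep_by_gene <- tapply(object@transcripts$representative,
                        object@transcripts$gene_id, sum)
  if (length(rep_by_gene) && !all(rep_by_gene == 1L)) {
    msgs <- c(msgs, "each gene must have exactly one representative transcript")
  }
  if (length(msgs)) msgs else TRUE
})

#' BindingSiteSet: 9-nt iCLIP binding sites
#'
#' A set of fixed-width binding sites, each a 9-nt window whose centre
#' nucleotide is the binding-site peak (the crosslink position retained after
#' merging adjacent peaks). The retained peak score is carried along.
#'
#' @slot sites GRanges of width `2 * flank + 1` (9 by default) with metadata
#'   columns `name`, `score` and `peak` (1-based genomic position of the
#'   centre nucleotide).
#' @slot params list of provenance parameters (e.g. `flank`, `seed`).
#' @export
setClass("BindingSiteSet",
  slots = c(sites = "GRanges", params = "list")
)

setValidity("BindingSiteSet", function(object) {
  gr <- object@sites
  msgs <- character(0)
  flank <- if (!is.null(object@params$flank)) object@params$flank else 4L
  w <- 2L * flank + 1L
  if (length(gr)) {
    if (!all(BiocGenerics::width(gr) == w)) {
      msgs <- c(msgs, sprintf("all sites must have width %d", w))
    }
    mc <- S4Vectors::mcols(gr)
    if (!all(c("name", "score", "peak") %in% names(mc))) {
      msgs <- c(msgs, "sites must carry metadata columns name, score, peak")
    } else {
      if (!all(mc$peak == BiocGenerics::start(gr) + flank)) {
        msgs <- c(msgs, "peak must be the centre nucleotide (start + flank)")
      }
      if (!all(is.finite(mc$score))) msgs <- c(msgs, "scores must be finite")
    }
    st <- as.character(BiocGenerics::strand(gr))
    if (!all(st %in% c("+", "-"))) {
      msgs <- c(msgs, "site strand must be '+' or '-'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' OverlapResult: gene-set overlap statistics
#'
#' @slot n1,n2 Sizes of the two gene sets.
#' @slot N Universe size.
#' @slot observed Observed intersection size.
#' @slot expected Expected intersection size under independence, `n1 * n2 / N`.
#' @slot representation_factor `observed / expected`.
#' @slot p_value One-sided enrichment p-value, `P(X >= observed)` for
#'   hypergeometric `X`.
#' @slot method `"exact"` or `"normal_approx"`.
#' @export
setClass("OverlapResult",
  slots = c(
    n1 = "integer", n2 = "integer", N = "integer", observed = "integer",
    expected = "numeric", representation_factor = "numeric",
    p_value = "numeric", method = "character"
  )
)

setValidity("OverlapResult", function(object) {
  msgs <- character(0)
  if (object@observed > min(object@n1, object@n2)) {
    msgs <- c(msgs, "observed overlap exceeds the smaller set")
  }
  if (object@p_value <= 0 || object@p_value > 1) {
    msgs <- c(msgs, "p_value must lie in (0, 1]")
  }
  if (!is.na(object@representation_factor) &&
      object@representation_factor < 0) {
    msgs <- c(msgs, "representation factor must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})
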