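suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

make_peaks <- function(chrom, pos, strand, score,
                       name = sprintf("p%03d", seq_along(pos))) {
  GRanges(chrom, IRanges::IRanges(pos, width = 1L), strand = strand,
          name = name, score = score)
}

# two-gene toy annotation with known feature structure:
#  gene A on '+': 3 exons, CDS 151..520, 60-nt introns, plus an AA isoform
#  gene B on '-': 2 exons, CDS pieces 1151..1200 and 1261..1340
toy_annotation <- function() {
  ex <- rbind(
    data.frame(chrom = "Chr1", start = c(101, 261, 461), end = c(200, 400, 600),
               strand = "+", transcript_id = "A.1", gene_id = "A"),
    data.frame(chrom = "Chr1", start = c(101, 273, 461), end = c(200, 400, 600),
               strand = "+", transcript_id = "A.2", gene_id = "A"),
    data.frame(chrom = "Chr1", start = c(1101, 1261), end = c(1200, 1400),
               strand = "-", transcript_id = "B.1", gene_id = "B")
  )
  cds <- rbind(
    data.frame(chrom = "Chr1", start = c(151, 261, 461), end = c(200, 400, 520),
               strand = "+", transcript_id = "A.1", gene_id = "A"),
    data.frame(chrom = "Chr1", start = c(151, 273, 461), end = c(200, 400, 520),
               strand = "+", transcript_id = "A.2", gene_id = "A"),
    data.frame(chrom = "Chr1", start = c(1151, 1261), end = c(1200, 1340),
               strand = "-", transcript_id = "B.1", gene_id = "B")
  )
  GenomeAnnotation(
    GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
            transcript_id = ex$transcript_id, gene_id = ex$gene_id),
    GRanges(cds$chrom, IRanges::IRanges(cds$start, cds$end),
            strand = cds$strand, transcript_id = cds$transcript_id,
            gene_id = cds$gene_id),
    representative = c("A.1", "B.1"),
    seqlens = c(Chr1 = 2000L)
  )
}

# annotation from plain data.frames (chrom,start,end,strand,transcript_id,
# gene_id), convenience for DAS toys
df_annotation <- function(exdf, cdsdf = NULL, representative = NULL,
                          seqlens = NULL) {
  ex <- GRanges(exdf$chrom, IRanges::IRanges(exdf$start, exdf$end),
                strand = exdf$strand, transcript_id = exdf$transcript_id,
                gene_id = exdf$gene_id)
  cds <- if (is.null(cdsdf)) GRanges() else
    GRanges(cdsdf$chrom, IRanges::IRanges(cdsdf$start, cdsdf$end),
            strand = cdsdf$strand, transcript_id = cdsdf$transcript_id,
            gene_id = cdsdf$gene_id)
  GenomeAnnotation(ex, cds, representative = representative,
                   seqlens = seqlens)
}

# independent brute-force oracles ------------------------------------------

oracle_merge_runs <- function(df) {
  # df: chrom, pos, strand, score; explicit run decomposition
  out <- list()
  for (ch in unique(df$chrom)) for (st in c("+", "-")) {
    d <- df[df$chrom == ch & df$strand == st, , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$pos), , drop = FALSE]
    run_start <- 1L
    for (i in seq_len(nrow(d))) {
      last <- i == nrow(d) || d$pos[i + 1L] != d$pos[i] + 1L
      if (last) {
        run <- d[run_start:i, , drop = FALSE]
        best <- which(run$score == max(run$score))
        pick <- if (st == "-") max(best) else min(best)
        out[[length(out) + 1L]] <- run[pick, , drop = FALSE]
        run_start <- i + 1L
      }
    }
  }
  d <- do.call(rbind, out)
  d[order(d$chrom, d$strand, d$pos), , drop = FALSE]
}

oracle_subtract <- function(p, ctl, max_dist = 9) {
  # all-pairs distance scan on peak positions
  removed <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(ctl))) {
      if (p$chrom[i] == ctl$chrom[j] && p$strand[i] == ctl$strand[j] &&
          abs(p$pos[i] - ctl$pos[j]) <= max_dist) {
        removed[i] <- TRUE
        break
      }
    }
  }
  removed
}

oracle_kmers <- function(seqs, k) {
  counts <- list()
  for (s in seqs) {
    s <- chartr("U", "T", toupper(s))
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      counts[[w]] <- (counts[[w]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_scan <- function(s, motif) {
  s <- chartr("U", "T", toupper(s))
  motif <- chartr("U", "T", toupper(motif))
  hits <- integer(0)
  if (nchar(s) >= nchar(motif)) {
    for (i in seq_len(nchar(s) - nchar(motif) + 1L)) {
      if (substr(s, i, i + nchar(motif) - 1L) == motif) hits <- c(hits, i)
    }
  }
  hits
}

# exact hypergeometric tail by full enumeration with choose()
oracle_hyper_tail <- function(N, n1, n2, obs) {
  ks <- obs:min(n1, n2)
  sum(choose(n1, ks) * choose(N - n1, n2 - ks)) / choose(N, n2)
}

# two-sided Fisher p for a 2x2 table by enumeration over the support
oracle_fisher2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- probs[support == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}
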