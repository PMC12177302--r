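# intron table with donor/acceptor keys in transcript orientation
.intron_table <- function(ann, representative_only = FALSE) {
  intr <- intronsByTranscript(ann, representative_only)
  if (!length(intr)) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      donor = integer(0), acceptor = integer(0)))
  }
  st <- as.character(BiocGenerics::strand(intr))
  s <- BiocGenerics::start(intr)
  e <- BiocGenerics::end(intr)
  data.frame(
    gene_id = as.character(S4Vectors::mcols(intr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(intr)$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(intr)),
    strand = st,
    start = s, end = e,
    donor = ifelse(st == "+", s, e),
    acceptor = ifelse(st == "+", e, s),
    stringsAsFactors = FALSE
  )
}

.event_row <- function(gene, type, chrom, strand, start, end,
                       incl_junction, excl_junction, frame = NA_integer_) {
  frame <- rep(as.integer(frame), length.out = length(gene))
  data.frame(
    event_id = sprintf("%s|%s|%d-%d", gene, type, start, end),
    gene_id = gene, type = type, chrom = chrom, strand = strand,
    start = start, end = end,
    incl_junction = incl_junction, excl_junction = excl_junction,
    frame = frame, stringsAsFactors = FALSE
  )
}

#' Detect exitrons in an annotation
#'
#' An intron of transcript T is an exitron when both of its boundaries lie
#' strictly inside a single CDS exon of a sibling transcript of the same gene
#' (at least 1 nt margin on both sides); an intron sharing a boundary with
#' the host CDS exon, or coinciding with a sibling's intron boundary set, is
#' an ordinary intron. The reading-frame effect (`length mod 3`) is recorded.
#'
#' @param ann A [GenomeAnnotation-class] with CDS records.
#' @return data.frame of `EI` event skeletons (one per distinct exitron) with
#'   columns `event_id`, `gene_id`, `type`, `chrom`, `strand`, `start`,
#'   `end`, `incl_junction`, `excl_junction`, `frame`.
#' @export
detectExitrons <- function(ann) {
  intr <- intronsByTranscript(ann)
  cds <- cdsParts(ann)
  empty <- .event_row(character(0), character(0), character(0), character(0),
                      integer(0), integer(0), character(0), character(0),
                      integer(0))
  if (!length(intr) || !length(cds)) return(empty)
  hits <- GenomicRanges::findOverlaps(intr, cds, type = "within")
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  same_gene <- as.character(S4Vectors::mcols(intr)$gene_id)[q] ==
    as.character(S4Vectors::mcols(cds)$gene_id)[s]
  sibling <- as.character(S4Vectors::mcols(intr)$transcript_id)[q] !=
    as.character(S4Vectors::mcols(cds)$transcript_id)[s]
  strict <- BiocGenerics::start(intr)[q] > BiocGenerics::start(cds)[s] &
    BiocGenerics::end(intr)[q] < BiocGenerics::end(cds)[s]
  keep <- which(same_gene & sibling & strict)
  if (!length(keep)) return(empty)
  qi <- unique(q[keep])
  ei <- intr[qi]
  out <- .event_row(
    gene = as.character(S4Vectors::mcols(ei)$gene_id),
    type = "EI",
    chrom = as.character(GenomeInfoDb::seqnames(ei)),
    strand = as.character(BiocGenerics::strand(ei)),
    start = BiocGenerics::start(ei),
    end = BiocGenerics::end(ei),
    incl_junction = NA_character_,
    excl_junction = sprintf("%s:%d-%d",
                            as.character(GenomeInfoDb::seqnames(ei)),
                            BiocGenerics::start(ei), BiocGenerics::end(ei)),
    frame = BiocGenerics::width(ei) %% 3L
  )
  out <- out[!duplicated(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate alternative-splicing events from annotation
#'
#' Pairwise comparison of the transcripts of each gene yields:
#' alternative acceptor (`AA`: two introns sharing a donor with different
#' acceptors), alternative donor (`AD`: shared acceptor, different donors),
#' cassette exon (`CE`: an internal exon whose two flanking junctions are
#' bridged by a single skipping junction in a sibling transcript), retained
#' intron (`RI`: every distinct annotated intron, quantified against the
#' gene-span pre-mRNA) and exitron (`EI`, see [detectExitrons()]). Duplicate
#' events are collapsed by coordinates.
#'
#' @param ann A [GenomeAnnotation-class].
#' @return data.frame of event skeletons (columns as in [detectExitrons()]).
#' @export
enumerateEvents <- function(ann) {
  it <- .intron_table(ann)
  out <- list()

  if (nrow(it)) {
    uintr <- it[!duplicated(it[c("gene_id", "start", "end")]), , drop = FALSE]

    # AA: same gene + donor, different acceptor -> one event per acceptor pair
    out$AA <- .alt_boundary_events(uintr, shared = "donor", type = "AA")
    # AD: same gene + acceptor, different donor
    out$AD <- .alt_boundary_events(uintr, shared = "acceptor", type = "AD")
    out$CE <- .cassette_events(ann, it, uintr)

    out$RI <- .event_row(
      gene = uintr$gene_id, type = "RI", chrom = uintr$chrom,
      strand = uintr$strand, start = uintr$start, end = uintr$end,
      incl_junction = NA_character_,
      excl_junction = sprintf("%s:%d-%d", uintr$chrom, uintr$start,
                              uintr$end)
    )
  }
  out$EI <- detectExitrons(ann)

  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev) || !nrow(ev)) {
    return(.event_row(character(0), character(0), character(0), character(0),
                      integer(0), integer(0), character(0), character(0)))
  }
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  ev <- ev[order(ev$gene_id, ev$type, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.alt_boundary_events <- function(uintr, shared, type) {
  alt <- if (shared == "donor") "acceptor" else "donor"
  key <- paste(uintr$gene_id, uintr[[shared]])
  grp <- split(seq_len(nrow(uintr)), key)
  rows <- list()
  for (ix in grp) {
    if (length(ix) < 2L) next
    ix <- ix[order(uintr[[alt]][ix])]
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in seq((a + 1L), length(ix))) {
        i <- ix[a]; j <- ix[b]
        # the alternative region spans the two competing boundaries
        lo <- min(uintr[[alt]][i], uintr[[alt]][j])
        hi <- max(uintr[[alt]][i], uintr[[alt]][j])
        row <- .event_row(
          gene = uintr$gene_id[i], type = type, chrom = uintr$chrom[i],
          strand = uintr$strand[i], start = lo, end = hi,
          incl_junction = sprintf("%s:%d-%d", uintr$chrom[i],
                                  uintr$start[i], uintr$end[i]),
          excl_junction = sprintf("%s:%d-%d", uintr$chrom[j],
                                  uintr$start[j], uintr$end[j])
        )
        # the shared boundary disambiguates events with equal alt regions
        row$event_id <- paste0(row$event_id, "|", shared,
                               uintr[[shared]][i])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.cassette_events <- function(ann, it, uintr) {
  ex <- exons(ann)
  tx_id <- as.character(S4Vectors::mcols(ex)$transcript_id)
  rows <- list()
  skip_key <- paste(uintr$gene_id, uintr$start, uintr$end)
  for (t in unique(tx_id)) {
    i <- which(tx_id == t)
    if (length(i) < 3L) next
    i <- i[order(BiocGenerics::start(ex)[i])]
    gene <- as.character(S4Vectors::mcols(ex)$gene_id)[i][1]
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[i][1]
    strand <- as.character(BiocGenerics::strand(ex))[i][1]
    s <- BiocGenerics::start(ex)[i]
    e <- BiocGenerics::end(ex)[i]
    for (j in 2:(length(i) - 1L)) {
      up <- c(e[j - 1L] + 1L, s[j] - 1L)     # upstream flanking intron
      dn <- c(e[j] + 1L, s[j + 1L] - 1L)     # downstream flanking intron
      skip <- paste(gene, up[1], dn[2])
      hit <- which(skip_key == skip)
      if (!length(hit)) next
      # the skipping intron must come from a different transcript
      others <- it$transcript_id[it$gene_id == gene & it$start == up[1] &
                                   it$end == dn[2]]
      if (!any(others != t)) next
      rows[[length(rows) + 1L]] <- .event_row(
        gene = gene, type = "CE", chrom = chrom, strand = strand,
        start = s[j], end = e[j],
        incl_junction = sprintf("%s:%d-%d;%s:%d-%d", chrom, up[1], up[2],
                                chrom, dn[1], dn[2]),
        excl_junction = sprintf("%s:%d-%d", chrom, up[1], dn[2])
      )
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Percent spliced-in
#'
#' `PSI = inclusion / (inclusion + exclusion)`; `NA` when both counts are
#' zero. For retained introns and exitrons, inclusion is intron/region
#' support and exclusion is the spliced-junction count; for AA/AD/CE the
#' counts are junction reads.
#'
#' @param inclusion,exclusion Non-negative count vectors.
#' @return Numeric PSI values in `[0, 1]` (or `NA`).
#' @export
computePSI <- function(inclusion, exclusion) {
  if (any(inclusion < 0 | exclusion < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- inclusion + exclusion
  ifelse(tot > 0, inclusion / tot, NA_real_)
}

#' Delta-PSI with a Beta posterior on pooled counts
#'
#' Counts are pooled within each condition and given a Jeffreys Beta(1/2,
#' 1/2) prior, so the per-condition PSI posterior is
#' `Beta(1/2 + inclusion, 1/2 + exclusion)`. `dpsi` is the difference of
#' posterior means (test minus control) and `probability` is the Monte Carlo
#' estimate of the posterior mass on the estimated sign of the change
#' (about 0.5 when the conditions are identical, near 1 for a clear change).
#' Events with fewer than `min_reps` replicates with defined PSI in either
#' condition are excluded.
#'
#' @param ctrl_incl,ctrl_excl,test_incl,test_excl Per-replicate counts.
#' @param n_draws Posterior draws (default 2000).
#' @param seed Integer seed.
#' @param min_reps Minimum replicates with defined PSI per condition
#'   (default 3).
#' @return list with `dpsi`, `probability`, `included` (FALSE when the
#'   min-replicates rule fails, with `dpsi`/`probability` NA).
#' @export
deltaPSI <- function(ctrl_incl, ctrl_excl, test_incl, test_excl,
                     n_draws = 2000L, seed = 1L, min_reps = 3L) {
  def_c <- sum(ctrl_incl + ctrl_excl > 0)
  def_t <- sum(test_incl + test_excl > 0)
  if (def_c < min_reps || def_t < min_reps) {
    return(list(dpsi = NA_real_, probability = NA_real_, included = FALSE))
  }
  a_c <- 0.5 + sum(ctrl_incl); b_c <- 0.5 + sum(ctrl_excl)
  a_t <- 0.5 + sum(test_incl); b_t <- 0.5 + sum(test_excl)
  dpsi <- a_t / (a_t + b_t) - a_c / (a_c + b_c)
  d <- withr::with_seed(seed, {
    rbeta(n_draws, a_t, b_t) - rbeta(n_draws, a_c, b_c)
  })
  probability <- if (dpsi >= 0) mean(d > 0) else mean(d < 0)
  list(dpsi = dpsi, probability = probability, included = TRUE)
}

#' Quantify and test events against a count table
#'
#' Joins event skeletons with a per-sample count table (see [readCounts()]
#' for the contract), computes per-sample PSI, the pooled-posterior delta-PSI
#' and sign probability per event (seeded per event from `config$seed`), and
#' applies the significance filters of [filterSignificant()].
#'
#' @param events data.frame from [enumerateEvents()] (or any frame with
#'   `event_id` and `type`).
#' @param counts data.frame with `event_id`, `sample_id`, `condition`,
#'   `replicate`, `inclusion`, `exclusion`.
#' @param control,test Condition labels in `counts`.
#' @param config A [clipConfig()] bundle (seed, `min_prob`, `min_dpsi`,
#'   `strong_dpsi`).
#' @param n_draws Posterior draws per event.
#' @return data.frame, one row per event, with count summaries, `dpsi`,
#'   `probability` and logical flags `included`, `junctions_detected`,
#'   `read_support`, `significant`, `strong`.
#' @export
dasAnalysis <- function(events, counts, control, test,
                        config = clipConfig(), n_draws = 2000L) {
  th <- config$thresholds
  keep <- counts$condition %in% c(control, test)
  counts <- counts[keep, , drop = FALSE]
  if (is.null(events$gene_id)) events$gene_id <- NA_character_
  cs <- split(counts, counts$event_id)
  res <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    cc <- cs[[ev$event_id]]
    if (is.null(cc)) {
      return(data.frame(
        event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
        incl_total = 0L, excl_total = 0L,
        ctrl_incl_all_pos = FALSE, test_incl_all_pos = FALSE,
        dpsi = NA_real_, probability = NA_real_, included = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    ctl <- cc[cc$condition == control, ]
    tst <- cc[cc$condition == test, ]
    ctl <- ctl[order(ctl$replicate), ]
    tst <- tst[order(tst$replicate), ]
    dp <- deltaPSI(ctl$inclusion, ctl$exclusion, tst$inclusion,
                   tst$exclusion, n_draws = n_draws,
                   seed = config$seed + i)
    data.frame(
      event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
      incl_total = sum(cc$inclusion), excl_total = sum(cc$exclusion),
      ctrl_incl_all_pos = nrow(ctl) > 0 && all(ctl$inclusion >= 1),
      test_incl_all_pos = nrow(tst) > 0 && all(tst$inclusion >= 1),
      dpsi = dp$dpsi, probability = dp$probability, included = dp$included,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  filterSignificant(res, th)
}

#' Apply the DAS significance filters
#'
#' AA and AD events are kept only when both alternative junctions were
#' detected (at least one read for the inclusion junction and one for the
#' exclusion junction, totalled over all samples). Retained-intron events
#' require intron read support in every control sample or in every test
#' sample. An event is `significant` when it passes its filters, has at
#' least `min_prob` posterior sign probability and `|dpsi| >= min_dpsi`;
#' `strong` additionally requires `|dpsi| >= strong_dpsi`.
#'
#' @param res data.frame with columns `type`, `dpsi`, `probability`,
#'   `included`, `incl_total`, `excl_total`, `ctrl_incl_all_pos`,
#'   `test_incl_all_pos` (as produced by [dasAnalysis()]).
#' @param thresholds list with `min_prob`, `min_dpsi`, `strong_dpsi`
#'   (defaults 0.9, 0.1, 0.3).
#' @return `res` with flags `junctions_detected`, `read_support`,
#'   `significant`, `strong` appended.
#' @export
filterSignificant <- function(res, thresholds = clipConfig()$thresholds) {
  th <- thresholds
  jd <- ifelse(res$type %in% c("AA", "AD"),
               res$incl_total >= 1L & res$excl_total >= 1L, TRUE)
  rs <- ifelse(res$type == "RI",
               res$ctrl_incl_all_pos | res$test_incl_all_pos, TRUE)
  sig <- res$included & jd & rs &
    !is.na(res$probability) & res$probability >= th$min_prob &
    !is.na(res$dpsi) & abs(res$dpsi) >= th$min_dpsi
  res$junctions_detected <- jd
  res$read_support <- rs
  res$significant <- sig
  res$strong <- sig & abs(res$dpsi) >= th$strong_dpsi
  res
}

#' Event-type composition of a DAS set
#'
#' @param das data.frame of (significant) events with `type` and `dpsi`.
#' @return list with `summary` (data.frame `type`, `n`, `pct`) and
#'   `aa_ad_ratio` (`NA` when there are no AD events).
#' @export
eventTypeSummary <- function(das) {
  if (!nrow(das)) {
    return(list(summary = data.frame(type = character(0), n = integer(0),
                                     pct = numeric(0)), aa_ad_ratio = NA_real_))
  }
  tab <- table(das$type)
  summary <- data.frame(type = names(tab), n = as.integer(tab),
                        pct = percentage(as.integer(tab), nrow(das)),
                        stringsAsFactors = FALSE)
  n_aa <- sum(das$type == "AA")
  n_ad <- sum(das$type == "AD")
  list(summary = summary,
       aa_ad_ratio = if (n_ad > 0) n_aa / n_ad else NA_real_)
}

#' Direction and magnitude of splicing shifts, by event type
#'
#' For each event type: the fractions of events with positive and negative
#' delta-PSI and the fractions with strong shifts (`|dpsi| >= strong_cut` in
#' either direction). The direction split of retained introns vs exitrons is
#' tested with a two-sided Fisher's exact test on the 2x2 (RI, EI) x
#' (positive, negative) table.
#'
#' @param das data.frame of events with `type` and `dpsi`.
#' @param strong_cut Strong-shift threshold (default 0.3).
#' @return list with `by_type` (data.frame) and `ri_ei_fisher_p` (`NA` when
#'   either type is absent).
#' @export
directionSummary <- function(das, strong_cut = 0.3) {
  types <- unique(das$type)
  by_type <- do.call(rbind, lapply(types, function(tp) {
    d <- das$dpsi[das$type == tp]
    n <- length(d)
    data.frame(
      type = tp, n = n,
      pct_up = percentage(sum(d > 0), n),
      pct_down = percentage(sum(d < 0), n),
      pct_strong_up = percentage(sum(d >= strong_cut), n),
      pct_strong_down = percentage(sum(d <= -strong_cut), n),
      stringsAsFactors = FALSE
    )
  }))
  p <- NA_real_
  if (all(c("RI", "EI") %in% types)) {
    m <- matrix(c(
      sum(das$type == "RI" & das$dpsi > 0),
      sum(das$type == "RI" & das$dpsi < 0),
      sum(das$type == "EI" & das$dpsi > 0),
      sum(das$type == "EI" & das$dpsi < 0)
    ), nrow = 2, byrow = TRUE,
    dimnames = list(c("RI", "EI"), c("up", "down")))
    if (all(rowSums(m) > 0)) p <- fisher.test(m)$p.value
  }
  list(by_type = by_type, ri_ei_fisher_p = p)
}

#' Splicing index from isoform signal intensities
#'
#' The splicing index of a gene is the signal of its longest isoform divided
#' by the total signal of all isoforms (e.g. RT-PCR band intensities).
#'
#' @param intensities Numeric per-isoform intensities.
#' @param lengths Annotated isoform lengths (same order).
#' @return Splicing index in `[0, 1]`; `NA` when the total signal is zero.
#' @export
splicingIndex <- function(intensities, lengths) {
  stopifnot(length(intensities) == length(lengths))
  tot <- sum(intensities)
  if (tot <= 0) return(NA_real_)
  unname(intensities[which.max(lengths)] / tot)
}

#' Classify differential gene expression
#'
#' A gene is upregulated when `l2fc >= l2fc_cut` and `adj_p < adjp_cut`
#' (inclusive fold-change bound), downregulated when `l2fc <= -l2fc_cut` and
#' `adj_p < adjp_cut`; everything else, including genes with missing
#' statistics, is unchanged.
#'
#' @param stats data.frame with `gene_id`, `l2fc`, `adj_p`.
#' @param l2fc_cut Absolute log2 fold-change threshold (default 1).
#' @param adjp_cut Adjusted p-value threshold (default 0.05).
#' @return list with `class` (character vector aligned to `stats`), and
#'   counts `up`, `down`, `unchanged`, `total_de`.
#' @export
classifyDE <- function(stats, l2fc_cut = 1, adjp_cut = 0.05) {
  miss <- is.na(stats$l2fc) | is.na(stats$adj_p)
  if (any(miss)) {
    message(sum(miss), " gene(s) with missing statistics left unchanged")
  }
  cls <- rep("unchanged", nrow(stats))
  up <- !miss & stats$l2fc >= l2fc_cut & stats$adj_p < adjp_cut
  dn <- !miss & stats$l2fc <= -l2fc_cut & stats$adj_p < adjp_cut
  cls[up] <- "up"
  cls[dn] <- "down"
  list(class = cls, up = sum(up), down = sum(dn),
       unchanged = sum(cls == "unchanged"), total_de = sum(up) + sum(dn))
}

#' Expression filter on a CPM matrix
#'
#' Keeps genes (rows) with `cpm >= cpm_cut` in at least `min_samples`
#' samples, the standard low-expression filter applied before differential
#' testing.
#'
#' @param cpm Numeric matrix, genes x samples.
#' @param cpm_cut CPM threshold (default 1).
#' @param min_samples Minimum qualifying samples (default 3).
#' @return Logical vector over rows.
#' @export
filterExpressed <- function(cpm, cpm_cut = 1, min_samples = 3L) {
  rowSums(cpm >= cpm_cut) >= min_samples
}
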