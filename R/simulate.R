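#' Simulate a genome and transcript annotation with known ground truth
#'
#' Generates a compact genome (uniform base composition by default,
#' configurable GC) and a multi-transcript annotation. Every gene carries a
#' representative transcript with a 5' UTR, 2-4 CDS exons and a 3' UTR;
#' introns are at least 60 nt and all intron boundaries (including planted
#' exitrons) carry GT...AG in the genomic sense strand. A configurable
#' fraction of genes (default 25%) carries an exitron-bearing isoform pair:
#' one transcript splices out a region that lies strictly inside a CDS exon
#' of its sibling. Additional transcripts plant alternative-acceptor,
#' alternative-donor and cassette-exon events.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed; the generator is fully deterministic under it.
#' @param gc GC content of the background sequence (default 0.5, i.e.
#'   uniform 25% per base).
#' @param exitron_frac Fraction of genes given an exitron isoform pair
#'   (default 0.25).
#' @param alt_frac Fraction of genes given one extra AA/AD/CE transcript
#'   (default 0.6).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @return list with `genome` (DNAStringSet), `annotation`
#'   ([GenomeAnnotation-class]) and `truth` (planted exitrons and alternative
#'   events, generator parameters, seed).
#' @export
simulateAnnotation <- function(n_genes, seed = 1L, gc = 0.5,
                               exitron_frac = 0.25, alt_frac = 0.6,
                               n_chroms = 2L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  withr::with_seed(seed, {
    .simulate_annotation_impl(n_genes, gc, exitron_frac, alt_frac, n_chroms,
                              seed)
  })
}

.rand_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.simulate_annotation_impl <- function(n_genes, gc, exitron_frac, alt_frac,
                                      n_chroms, seed) {
  n_chroms <- min(n_chroms, n_genes)
  ei_genes <- seq_len(ceiling(exitron_frac * n_genes))
  cursor <- rep(0L, n_chroms)
  chrom_seq <- vector("list", n_chroms)
  for (i in seq_len(n_chroms)) chrom_seq[[i]] <- character(0)

  exon_rows <- list()
  cds_rows <- list()
  rep_tx <- character(0)
  truth_ei <- list()
  truth_alt <- list()

  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%04d", g)
    is_ei <- g %in% ei_genes
    k <- sample(2:4, 1)
    utr5 <- sample(80:250, 1)
    utr3 <- sample(80:200, 1)
    cds_lens <- sample(90:240, k, replace = TRUE)
    ei_len <- NA_integer_
    host <- NA_integer_
    if (is_ei) {
      ei_len <- sample(60:102, 1)
      host <- if (k >= 3) 2L else 1L
      cds_lens[host] <- ei_len + sample(60:100, 1)
    }
    # total CDS a multiple of 3
    r <- sum(cds_lens) %% 3L
    if (r) cds_lens[k] <- cds_lens[k] + (3L - r)
    intron_lens <- sample(60:200, k - 1L, replace = TRUE)

    ex_lens <- cds_lens
    ex_lens[1] <- ex_lens[1] + utr5
    ex_lens[k] <- ex_lens[k] + utr3
    ex_start <- integer(k); ex_end <- integer(k)
    pos <- 1L
    for (j in seq_len(k)) {
      ex_start[j] <- pos
      ex_end[j] <- pos + ex_lens[j] - 1L
      pos <- ex_end[j] + 1L
      if (j < k) pos <- pos + intron_lens[j]
    }
    L <- ex_end[k]
    cds_lo <- utr5 + 1L
    cds_hi <- ex_end[k] - utr3

    # transcripts as local exon tables -----------------------------------
    tx_local <- list()
    tx_local[[paste0(gid, ".1")]] <- cbind(ex_start, ex_end)

    if (is_ei) {
      # CDS chunk of the host exon, in local coordinates
      lo <- max(ex_start[host], cds_lo)
      hi <- min(ex_end[host], cds_hi)
      margin <- (hi - lo + 1L - ei_len) %/% 2L
      xs <- lo + margin
      xe <- xs + ei_len - 1L
      m <- tx_local[[1]]
      split_ex <- rbind(c(m[host, 1], xs - 1L), c(xe + 1L, m[host, 2]))
      m2 <- rbind(if (host > 1) m[seq_len(host - 1L), , drop = FALSE],
                  split_ex,
                  if (host < k) m[seq(host + 1L, k), , drop = FALSE])
      tx_local[[paste0(gid, ".2")]] <- m2
      truth_ei[[length(truth_ei) + 1L]] <-
        list(gene_id = gid, local = c(xs, xe), len = ei_len)
    }

    if (stats::runif(1) < alt_frac) {
      kind <- if (k >= 3) sample(c("AA", "AD", "CE"), 1) else
        sample(c("AA", "AD"), 1)
      m <- tx_local[[1]]
      alt <- switch(kind,
        AA = {
          i <- sample(k - 1L, 1)
          d <- sample(6:18, 1)
          m[i + 1L, 1] <- m[i + 1L, 1] + d   # acceptor shifts into next exon
          m
        },
        AD = {
          i <- sample(k - 1L, 1)
          d <- sample(6:18, 1)
          m[i, 2] <- m[i, 2] - d             # donor shifts into this exon
          m
        },
        CE = {
          inner <- seq(2L, k - 1L)
          j <- if (length(inner) == 1L) inner else sample(inner, 1)
          m[-j, , drop = FALSE]
        })
      nm <- paste0(gid, ".", length(tx_local) + 1L)
      tx_local[[nm]] <- alt
      truth_alt[[length(truth_alt) + 1L]] <- list(gene_id = gid, type = kind)
    }

    # genome sequence for this gene (sense strand), GT...AG at all introns
    seqv <- .rand_bases(L, gc)
    for (m in tx_local) {
      if (nrow(m) < 2L) next
      for (j in seq_len(nrow(m) - 1L)) {
        is_ <- m[j, 2] + 1L
        ie_ <- m[j + 1L, 1] - 1L
        seqv[is_] <- "G"; seqv[is_ + 1L] <- "T"
        seqv[ie_ - 1L] <- "A"; seqv[ie_] <- "G"
      }
    }

    # placement -----------------------------------------------------------
    ci <- 1L + (g - 1L) %% n_chroms
    gap <- sample(200:400, 1)
    g_start <- cursor[ci] + gap + 1L
    g_end <- g_start + L - 1L
    strand <- sample(c("+", "-"), 1)
    chrom <- sprintf("Chr%d", ci)
    gene_seq <- paste(seqv, collapse = "")
    if (strand == "-") {
      gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
    }
    chrom_seq[[ci]] <- c(chrom_seq[[ci]],
                         paste(.rand_bases(gap, gc), collapse = ""), gene_seq)
    cursor[ci] <- g_end

    loc2gen <- function(ls, le) {
      if (strand == "+") c(g_start + ls - 1L, g_start + le - 1L)
      else c(g_end - le + 1L, g_end - ls + 1L)
    }

    for (t in names(tx_local)) {
      m <- tx_local[[t]]
      for (j in seq_len(nrow(m))) {
        gg <- loc2gen(m[j, 1], m[j, 2])
        exon_rows[[length(exon_rows) + 1L]] <-
          data.frame(chrom = chrom, start = gg[1], end = gg[2],
                     strand = strand, transcript_id = t, gene_id = gid,
                     stringsAsFactors = FALSE)
        # CDS piece of this exon
        cl <- max(m[j, 1], cds_lo)
        ch_ <- min(m[j, 2], cds_hi)
        if (cl <= ch_) {
          gg2 <- loc2gen(cl, ch_)
          cds_rows[[length(cds_rows) + 1L]] <-
            data.frame(chrom = chrom, start = gg2[1], end = gg2[2],
                       strand = strand, transcript_id = t, gene_id = gid,
                       stringsAsFactors = FALSE)
        }
      }
    }
    rep_tx <- c(rep_tx, paste0(gid, ".1"))

    if (is_ei) {
      x <- truth_ei[[length(truth_ei)]]
      gg <- loc2gen(x$local[1], x$local[2])
      truth_ei[[length(truth_ei)]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".2"), chrom = chrom,
        strand = strand, start = gg[1], end = gg[2], length = x$len,
        frame = x$len %% 3L, stringsAsFactors = FALSE)
    }
    if (length(truth_alt) &&
        is.list(truth_alt[[length(truth_alt)]]) &&
        !is.data.frame(truth_alt[[length(truth_alt)]]) &&
        truth_alt[[length(truth_alt)]]$gene_id == gid) {
      truth_alt[[length(truth_alt)]] <- data.frame(
        gene_id = gid, type = truth_alt[[length(truth_alt)]]$type,
        stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, character(1),
                                            collapse = ""))
  names(genome) <- sprintf("Chr%d", seq_len(n_chroms))

  exdf <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges(exdf$chrom,
                                  IRanges::IRanges(exdf$start, exdf$end),
                                  strand = exdf$strand,
                                  transcript_id = exdf$transcript_id,
                                  gene_id = exdf$gene_id)
  cdsdf <- do.call(rbind, cds_rows)
  cds <- GenomicRanges::GRanges(cdsdf$chrom,
                                IRanges::IRanges(cdsdf$start, cdsdf$end),
                                strand = cdsdf$strand,
                                transcript_id = cdsdf$transcript_id,
                                gene_id = cdsdf$gene_id)
  ann <- GenomeAnnotation(exons, cds, representative = rep_tx,
                          seqlens = .genome_lengths(genome))
  truth <- list(
    exitrons = if (length(truth_ei)) do.call(rbind, truth_ei) else NULL,
    alt_events = if (length(truth_alt)) do.call(rbind, truth_alt) else NULL,
    params = list(n_genes = n_genes, gc = gc, exitron_frac = exitron_frac,
                  alt_frac = alt_frac),
    seed = seed
  )
  list(genome = genome, annotation = ann, truth = truth)
}

#' Simulate crosslink peaks, control peaks and iCLIP reads
#'
#' Places true binding-site peaks in the transcriptome with a configurable
#' bias: a fraction centred 25-30 nt upstream of qualifying 5' splice sites,
#' a fraction in 5' UTRs, the rest in CDS regions. The genome sequence under
#' a configurable fraction of sites is rewritten to contain the given motif
#' (a literal such as `"CAGA"`, placed with its first base on the peak, or
#' `"CU-rich"`, replacing the 9-nt site with C/U bases). Control peaks are
#' placed partly co-located with protein sites (within the subtraction
#' distance) and partly at random; reads with random barcodes and a
#' configurable exact-duplicate rate support deduplication testing.
#'
#' @param ann A [GenomeAnnotation-class] from [simulateAnnotation()].
#' @param genome Matching DNAStringSet (returned modified).
#' @param seed Integer seed.
#' @param n_sites Number of true binding sites.
#' @param frac_5ss Fraction of sites placed 25-30 nt upstream of a 5' splice
#'   site.
#' @param frac_utr5 Fraction placed in 5' UTRs.
#' @param motif_rate Fraction of sites with the motif embedded.
#' @param motif `"CAGA"`-style literal (A/C/G/U) or `"CU-rich"`.
#' @param control_rate Control peaks as a fraction of `n_sites`.
#' @param coloc_frac Fraction of control peaks placed within `flank * 2 + 1`
#'   nt of a protein site.
#' @param reads_per_site Reads generated per true site.
#' @param duplicate_rate Probability that a read gains an exact PCR
#'   duplicate.
#' @param barcode_len Random barcode length (default 9).
#' @param adjacent_rate Probability of a lower-scored satellite peak directly
#'   adjacent to a true peak (exercises peak merging).
#' @param flank Site half-width (default 4).
#' @return list with `protein_peaks`, `control_peaks` (width-1 GRanges with
#'   scores), `reads` (data.frame), `genome` (with embedded motifs) and
#'   `truth` (true site table and parameters).
#' @export
simulateCrosslinkData <- function(ann, genome, seed = 1L, n_sites = 200L,
                                  frac_5ss = 0.3, frac_utr5 = 0.4,
                                  motif_rate = 0.8, motif = "CAGA",
                                  control_rate = 0.3, coloc_frac = 0.6,
                                  reads_per_site = 5L, duplicate_rate = 0.3,
                                  barcode_len = 9L, adjacent_rate = 0.5,
                                  flank = 4L) {
  fr <- c(frac_5ss, frac_utr5, motif_rate, control_rate, coloc_frac,
          duplicate_rate, adjacent_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  w <- 2L * flank + 1L
  if (!identical(toupper(motif), "CU-RICH") && nchar(motif) > w) {
    stop("motif longer than the site window", call. = FALSE)
  }
  withr::with_seed(seed, {
    .simulate_crosslink_impl(ann, genome, n_sites, frac_5ss, frac_utr5,
                             motif_rate, motif, control_rate, coloc_frac,
                             reads_per_site, duplicate_rate, barcode_len,
                             adjacent_rate, flank, seed)
  })
}

.simulate_crosslink_impl <- function(ann, genome, n_sites, frac_5ss,
                                     frac_utr5, motif_rate, motif,
                                     control_rate, coloc_frac,
                                     reads_per_site, duplicate_rate,
                                     barcode_len, adjacent_rate, flank,
                                     seed) {
  glen <- .genome_lengths(genome)
  min_sep <- 25L
  edge <- 15L

  donors <- .donor_sites(ann, 50L)
  featR <- featureRanges(ann)
  utr5R <- featR[S4Vectors::mcols(featR)$feature == "5UTR" &
                   BiocGenerics::width(featR) >= 30L]
  cdsR <- featR[S4Vectors::mcols(featR)$feature == "CDS" &
                  BiocGenerics::width(featR) >= 30L]

  n_ss <- round(frac_5ss * n_sites)
  n_utr <- round(frac_utr5 * n_sites)
  n_other <- n_sites - n_ss - n_utr

  acc <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), category = character(0),
                    stringsAsFactors = FALSE)
  ok_pos <- function(chrom, pos, strand) {
    if (pos < edge || pos > glen[[chrom]] - edge) return(FALSE)
    same <- acc$chrom == chrom & acc$strand == strand
    !any(same & abs(acc$pos - pos) < min_sep)
  }
  add_sites <- function(n, gen, category) {
    tries <- 0L
    while (n > 0L && tries < 50L * (n + 10L)) {
      tries <- tries + 1L
      cand <- gen()
      if (is.null(cand)) next
      if (ok_pos(cand$chrom, cand$pos, cand$strand)) {
        acc <<- rbind(acc, data.frame(chrom = cand$chrom, pos = cand$pos,
                                      strand = cand$strand,
                                      category = category,
                                      stringsAsFactors = FALSE))
        n <- n - 1L
      }
    }
    if (n > 0L) warning("could not place ", n, " ", category, " site(s)")
  }

  if (n_ss > 0L && length(donors)) {
    add_sites(n_ss, function() {
      i <- sample.int(length(donors), 1)
      u <- sample(25:30, 1)
      st <- as.character(BiocGenerics::strand(donors))[i]
      d <- BiocGenerics::start(donors)[i]
      list(chrom = as.character(GenomeInfoDb::seqnames(donors))[i],
           pos = if (st == "+") d - u else d + u, strand = st)
    }, "5ss")
  }
  pick_in <- function(ranges) {
    if (!length(ranges)) return(NULL)
    i <- sample.int(length(ranges), 1)
    s <- BiocGenerics::start(ranges)[i] + 10L
    e <- BiocGenerics::end(ranges)[i] - 10L
    if (s > e) return(NULL)
    list(chrom = as.character(GenomeInfoDb::seqnames(ranges))[i],
         pos = sample(s:e, 1),
         strand = as.character(BiocGenerics::strand(ranges))[i])
  }
  if (n_utr > 0L) add_sites(n_utr, function() pick_in(utr5R), "5utr")
  if (n_other > 0L) add_sites(n_other, function() pick_in(cdsR), "cds")

  n_true <- nrow(acc)
  # embed motifs ----------------------------------------------------------
  chrom_chars <- lapply(names(genome), function(ch) {
    strsplit(as.character(genome[[ch]]), "")[[1]]
  })
  names(chrom_chars) <- names(genome)
  n_motif <- round(motif_rate * n_true)
  motif_idx <- if (n_motif > 0) sample.int(n_true, n_motif) else integer(0)
  cu_rich <- identical(toupper(motif), "CU-RICH")
  for (i in motif_idx) {
    ch <- acc$chrom[i]; p <- acc$pos[i]; st <- acc$strand[i]
    ins <- if (cu_rich) {
      paste(sample(c("C", "T"), 2L * flank + 1L, replace = TRUE),
            collapse = "")
    } else .to_dna(motif)
    lo <- if (cu_rich) p - flank else p  # literal motif starts on the peak
    hi <- lo + nchar(ins) - 1L
    if (st == "-") {
      ins <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ins)))
      hi <- if (cu_rich) p + flank else p
      lo <- hi - nchar(ins) + 1L
    }
    chrom_chars[[ch]][lo:hi] <- strsplit(ins, "")[[1]]
  }
  acc$motif <- seq_len(n_true) %in% motif_idx
  genome2 <- Biostrings::DNAStringSet(vapply(chrom_chars, paste, character(1),
                                             collapse = ""))
  names(genome2) <- names(genome)

  # protein peaks ---------------------------------------------------------
  main_scores <- round(stats::runif(n_true, 2, 10), 3)
  pp <- data.frame(chrom = acc$chrom, pos = acc$pos, strand = acc$strand,
                   score = main_scores, stringsAsFactors = FALSE)
  sat <- which(stats::runif(n_true) < adjacent_rate)
  if (length(sat)) {
    side <- sample(c(-1L, 1L), length(sat), replace = TRUE)
    pp <- rbind(pp, data.frame(
      chrom = acc$chrom[sat], pos = acc$pos[sat] + side,
      strand = acc$strand[sat],
      score = round(main_scores[sat] * stats::runif(length(sat), 0.3, 0.8),
                    3),
      stringsAsFactors = FALSE))
  }
  protein_peaks <- .peaks_gr(pp)

  # control peaks ---------------------------------------------------------
  n_ctrl <- round(control_rate * n_true)
  n_coloc <- round(coloc_frac * n_ctrl)
  ctl <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  if (n_coloc > 0L) {
    i <- sample.int(n_true, n_coloc, replace = n_coloc > n_true)
    off <- sample(c(-(2 * flank + 1):-1, 1:(2 * flank + 1)), n_coloc,
                  replace = TRUE)
    ctl <- rbind(ctl, data.frame(chrom = acc$chrom[i],
                                 pos = acc$pos[i] + off,
                                 strand = acc$strand[i],
                                 stringsAsFactors = FALSE))
  }
  n_far <- n_ctrl - n_coloc
  tries <- 0L
  while (n_far > 0L && tries < 5000L) {
    tries <- tries + 1L
    cand <- pick_in(cdsR)
    if (is.null(cand)) break
    same <- acc$chrom == cand$chrom & acc$strand == cand$strand
    if (any(same & abs(acc$pos - cand$pos) <= 3L * (2L * flank + 1L))) next
    if (nrow(ctl) && any(ctl$chrom == cand$chrom & ctl$strand == cand$strand &
                           abs(ctl$pos - cand$pos) < min_sep)) next
    ctl <- rbind(ctl, data.frame(chrom = cand$chrom, pos = cand$pos,
                                 strand = cand$strand,
                                 stringsAsFactors = FALSE))
    n_far <- n_far - 1L
  }
  ctl <- ctl[!duplicated(paste(ctl$chrom, ctl$strand, ctl$pos)), ,
             drop = FALSE]
  ctl$score <- round(stats::runif(nrow(ctl), 1, 5), 3)
  control_peaks <- .peaks_gr(ctl)

  # reads -----------------------------------------------------------------
  alphabet <- c("A", "C", "G", "T")
  reads <- do.call(rbind, lapply(seq_len(n_true), function(i) {
    off <- sample(0:10, reads_per_site, replace = TRUE)
    st <- acc$strand[i]
    data.frame(
      chrom = acc$chrom[i],
      start = if (st == "+") acc$pos[i] - off else acc$pos[i] + off,
      strand = st,
      barcode = vapply(seq_len(reads_per_site), function(j) {
        paste(sample(alphabet, barcode_len, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }))
  if (duplicate_rate > 0 && nrow(reads)) {
    dup <- which(stats::runif(nrow(reads)) < duplicate_rate)
    if (length(dup)) reads <- rbind(reads, reads[dup, , drop = FALSE])
  }
  rownames(reads) <- NULL

  truth <- list(
    sites = data.frame(acc, site_start = acc$pos - flank,
                       site_end = acc$pos + flank, stringsAsFactors = FALSE),
    n_colocated_controls = n_coloc,
    motif = motif,
    params = list(n_sites = n_sites, frac_5ss = frac_5ss,
                  frac_utr5 = frac_utr5, motif_rate = motif_rate,
                  control_rate = control_rate, coloc_frac = coloc_frac,
                  duplicate_rate = duplicate_rate,
                  adjacent_rate = adjacent_rate, flank = flank),
    seed = seed
  )
  list(protein_peaks = protein_peaks, control_peaks = control_peaks,
       reads = reads, genome = genome2, truth = truth)
}

.peaks_gr <- function(df) {
  if (!nrow(df)) {
    gr0 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr0) <- S4Vectors::DataFrame(name = character(0),
                                                  score = numeric(0))
    return(gr0)
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                               strand = df$strand,
                               name = sprintf("peak_%05d", seq_len(nrow(df))),
                               score = df$score)
  .sort_peaks(gr)
}

#' Simulate junction/intron count tables with planted delta-PSI effects
#'
#' Draws per-replicate inclusion counts binomially around condition PSIs:
#' control PSI is a per-event baseline (retained introns low, PSI <= 0.1;
#' exitrons high, PSI >= 0.9, reflecting typical wild-type behaviour; other
#' types intermediate) and test PSI is the baseline plus the planted effect,
#' clipped to `[0, 1]` with a warning.
#'
#' @param events data.frame with `event_id` and `type` (e.g. from
#'   [enumerateEvents()]).
#' @param effects Named numeric vector of true delta-PSI per event id;
#'   unlisted events get 0.
#' @param n_reps Replicates per condition (>= 3).
#' @param depth Total junction reads per event and sample (> 0).
#' @param seed Integer seed.
#' @param control,test Condition labels.
#' @return list with `counts` (data.frame: `event_id`, `sample_id`,
#'   `condition`, `replicate`, `inclusion`, `exclusion`) and `truth`
#'   (data.frame with baseline/test PSI and true delta-PSI per event).
#' @export
simulateJunctionCounts <- function(events, effects = NULL, n_reps = 3L,
                                   depth = 1000L, seed = 1L,
                                   control = "control", test = "test") {
  if (n_reps < 3L) stop("n_reps must be >= 3", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  withr::with_seed(seed, {
    n <- nrow(events)
    base <- numeric(n)
    for (i in seq_len(n)) {
      base[i] <- switch(events$type[i],
                        RI = stats::runif(1, 0.02, 0.10),
                        EI = stats::runif(1, 0.90, 0.98),
                        stats::runif(1, 0.30, 0.70))
    }
    eff <- rep(0, n)
    if (!is.null(effects)) {
      hit <- match(events$event_id, names(effects))
      eff[!is.na(hit)] <- effects[hit[!is.na(hit)]]
    }
    test_psi <- base + eff
    if (any(test_psi < 0 | test_psi > 1)) {
      warning("planted effect pushes PSI outside [0, 1]; clipped")
      test_psi <- pmin(pmax(test_psi, 0), 1)
    }
    rows <- vector("list", 2L * n_reps)
    ri <- 0L
    for (cond in c(control, test)) {
      psi <- if (cond == control) base else test_psi
      for (r in seq_len(n_reps)) {
        ri <- ri + 1L
        incl <- rbinom(n, depth, psi)
        rows[[ri]] <- data.frame(
          event_id = events$event_id,
          sample_id = paste0(cond, "_", r),
          condition = cond, replicate = r,
          inclusion = incl, exclusion = depth - incl,
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- data.frame(event_id = events$event_id, type = events$type,
                        base_psi = base, true_dpsi = test_psi - base,
                        test_psi = test_psi, stringsAsFactors = FALSE)
    list(counts = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate gene sets with an exact planted overlap
#'
#' @param N Universe size.
#' @param n1,n2 Set sizes (`<= N`).
#' @param observed Planted intersection size (`<= min(n1, n2)`, and
#'   `n1 + n2 - observed <= N`).
#' @param seed Integer seed.
#' @return list with `set1`, `set2`, `universe`; `length(intersect(set1,
#'   set2)) == observed` exactly.
#' @export
simulateGeneSets <- function(N, n1, n2, observed, seed = 1L) {
  if (observed > min(n1, n2) || n1 > N || n2 > N ||
      n1 + n2 - observed > N || observed < 0) {
    stop("infeasible set sizes", call. = FALSE)
  }
  withr::with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(N))
    inter <- sample(universe, observed)
    rest <- setdiff(universe, inter)
    only1 <- if (n1 > observed) sample(rest, n1 - observed) else character(0)
    rest2 <- setdiff(rest, only1)
    only2 <- if (n2 > observed) sample(rest2, n2 - observed) else character(0)
    list(set1 = sort(c(inter, only1)), set2 = sort(c(inter, only2)),
         universe = universe)
  })
}
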