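test_that("sites are assigned to features of the representative model", {
  ann <- toy_annotation()
  lens <- c(Chr1 = 2000L)
  # peaks: 5'UTR of A, CDS of A, intron 1 of A (wholly inside), 5'UTR of B,
  # intergenic
  pk <- make_peaks("Chr1", c(120, 300, 230, 1380, 1900),
                   c("+", "+", "+", "-", "+"), 1:5)
  sites <- defineBindingSites(pk, lens)
  suppressMessages(af <- assignFeatures(sites, ann))
  sa <- af$site_annotation
  expect_equal(sa$feature, c("5UTR", "CDS", "intron", "5UTR", "intergenic"))
  expect_equal(sa$gene_id[1:4], c("A", "A", "A", "B"))

  # per-gene summary and percentages over site-bearing genes (n = 2)
  gsum <- af$gene_summary
  expect_equal(nrow(gsum), 2L)
  fp <- af$feature_percentages
  expect_equal(fp$n_genes[fp$feature == "5UTR"], 2L)
  expect_equal(fp$pct[fp$feature == "5UTR"], 100)
  expect_equal(fp$n_genes[fp$feature == "CDS"], 1L)
  expect_equal(fp$pct[fp$feature == "CDS"], 50)

  # a site overlapping two features is assigned by its peak position:
  # peak at 150 (5'UTR, last base) with window into the CDS
  pk2 <- make_peaks("Chr1", 150, "+", 1)
  suppressMessages(
    af2 <- assignFeatures(defineBindingSites(pk2, lens), ann))
  expect_equal(af2$site_annotation$feature, "5UTR")
})

test_that("TSS distances are strand-aware and window-bounded", {
  ann <- toy_annotation()
  lens <- c(Chr1 = 2000L)
  # gene A TSS = 101 (+); gene B TSS = 1400 (-)
  pk <- make_peaks("Chr1", c(111, 1390, 95, 390), c("+", "-", "+", "+"),
                   1:4)
  sites <- defineBindingSites(pk, lens)
  tp <- tssProfile(sites, ann, window = 250)
  d <- tp$distances
  expect_equal(d$dist[d$site == "site_00001"], 10L)
  # minus strand: 10 nt downstream of TSS at 1400 is genomic 1390
  expect_equal(d$dist[d$site == "site_00002"], 10L)
  # upstream of the TSS: excluded
  expect_false("site_00003" %in% d$site)
  # beyond the window (289 nt): excluded
  expect_false("site_00004" %in% d$site)
  expect_equal(sum(tp$histogram$count), 2L)
})

test_that("uniformly planted TSS-window sites give a flat histogram", {
  sim <- simulateAnnotation(30, seed = 17)
  ann <- sim$annotation
  tx <- transcripts(ann)
  rep_tx <- tx[tx$representative, ]
  withr::with_seed(18, {
    picks <- sample(nrow(rep_tx), 400, replace = TRUE)
    offs <- sample(0:250, 400, replace = TRUE)
  })
  pos <- ifelse(rep_tx$strand[picks] == "+", rep_tx$start[picks] + offs,
                rep_tx$end[picks] - offs)
  pk <- make_peaks(rep_tx$chrom[picks], pos, rep_tx$strand[picks], 1,
                   name = sprintf("p%04d", seq_along(pos)))
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  sites <- defineBindingSites(pk, lens)
  tp <- tssProfile(sites, ann)
  # chi-square goodness of fit against uniform over 0..250, coarse bins
  cnt <- tp$histogram$count
  bins <- tapply(cnt, rep(1:10, length.out = length(cnt)), sum)
  p <- suppressWarnings(stats::chisq.test(bins)$p.value)
  expect_gt(p, 0.001)
})

test_that("5' splice-site distances follow the sign convention and filters", {
  ann <- toy_annotation()
  lens <- c(Chr1 = 2000L)
  # gene A donors: exon1 end 200, exon2 end 400 (both exons >= 50 nt)
  pk <- make_peaks("Chr1", c(173, 420), "+", c(1, 2))
  sites <- defineBindingSites(pk, lens)
  dp <- donorProfile(sites, ann)
  # peak 27 nt before the donor at 200 -> -27
  expect_equal(dp$distances$dist[1], -27L)
  # peak 20 nt after donor 400, inside intron 2 -> +20
  expect_equal(dp$distances$dist[2], 20L)

  # minus-strand donor: gene B exon rank 1 [1261, 1400] -> donor at 1261
  pkm <- make_peaks("Chr1", 1288, "-", 1)
  dpm <- donorProfile(defineBindingSites(pkm, lens), ann)
  expect_equal(dpm$distances$dist, -27L)

  # exons shorter than min_exon_len contribute no donors
  exdf <- data.frame(chrom = "Chr1", start = c(101, 170, 301),
                     end = c(149, 240, 400), strand = "+",
                     transcript_id = "S.1", gene_id = "S")
  short_ann <- df_annotation(exdf, seqlens = c(Chr1 = 1000L))
  pks <- make_peaks("Chr1", 130, "+", 1)  # 19 nt before the 49-nt exon's end
  dps <- donorProfile(defineBindingSites(pks, c(Chr1 = 1000L)), short_ann,
                      min_exon_len = 50)
  # the 49-nt first exon is skipped; nearest qualifying donor is exon 2 (240)
  expect_equal(dps$distances$dist, 130L - 240L)
})

test_that("planted upstream enrichment is recovered as the histogram mode", {
  sim <- simulateAnnotation(40, seed = 51)
  cx <- simulateCrosslinkData(sim$annotation, sim$genome, seed = 52,
                              n_sites = 200, frac_5ss = 0.3,
                              control_rate = 0)
  res <- callBindingSites(cx$protein_peaks, cx$control_peaks,
                          setNames(Biostrings::width(cx$genome),
                                   names(cx$genome)))
  dp <- donorProfile(res$sites, sim$annotation)
  h <- dp$histogram
  mode_dist <- h$dist[which.max(h$count)]
  expect_true(mode_dist >= -30 && mode_dist <= -25)
})

test_that("upstream windows stack at the peak with strand-aware extraction", {
  sim <- simulateAnnotation(40, seed = 61)
  cx <- simulateCrosslinkData(sim$annotation, sim$genome, seed = 62,
                              n_sites = 150, frac_5ss = 0.5, frac_utr5 = 0.2,
                              motif_rate = 1, motif = "CU-rich",
                              control_rate = 0)
  res <- callBindingSites(cx$protein_peaks, cx$control_peaks,
                          setNames(Biostrings::width(cx$genome),
                                   names(cx$genome)))
  uw <- upstreamWindows(res$sites, sim$annotation, cx$genome)
  expect_equal(unique(Biostrings::width(uw$sequences)), 21L)
  expect_equal(unname(colSums(uw$pfm)), rep(uw$n, 21))
  # CU-rich planting: mean pyrimidine fraction beats the uniform background
  expect_gt(mean(uw$pyrimidine_fraction), 0.5)

  # minus-strand extraction is the reverse complement of the genomic slice
  got <- sitePeaks(res$sites)
  neg <- which(as.character(BiocGenerics::strand(got)) == "-")
  i <- intersect(S4Vectors::mcols(got)$name[neg], names(uw$sequences))
  if (length(i)) {
    nm <- i[1]
    j <- match(nm, S4Vectors::mcols(got)$name)
    p <- BiocGenerics::start(got)[j]
    ch <- as.character(GenomeInfoDb::seqnames(got))[j]
    fwd <- Biostrings::subseq(cx$genome[[ch]], p - 10, p + 10)
    expect_equal(as.character(uw$sequences[[nm]]),
                 as.character(Biostrings::reverseComplement(fwd)))
  }
})

test_that("profiles are invariant under coordinate translation and renaming", {
  sim <- simulateAnnotation(15, seed = 71)
  cx <- simulateCrosslinkData(sim$annotation, sim$genome, seed = 72,
                              n_sites = 60, control_rate = 0)
  lens <- setNames(Biostrings::width(cx$genome), names(cx$genome))
  res <- callBindingSites(cx$protein_peaks, cx$control_peaks, lens)
  base_tss <- tssProfile(res$sites, sim$annotation)$histogram$count
  base_ss <- donorProfile(res$sites, sim$annotation)$histogram$count

  shift <- 100L
  remap <- function(gr) {
    if (!length(gr)) return(gr)
    gr2 <- GenomicRanges::GRanges(
      paste0("X_", as.character(GenomeInfoDb::seqnames(gr))),
      IRanges::IRanges(BiocGenerics::start(gr) + shift,
                       BiocGenerics::end(gr) + shift),
      strand = BiocGenerics::strand(gr))
    S4Vectors::mcols(gr2) <- S4Vectors::mcols(gr)
    gr2
  }
  ex2 <- remap(exons(sim$annotation))
  cds2 <- remap(cdsParts(sim$annotation))
  lens2 <- setNames(unname(lens) + shift, paste0("X_", names(lens)))
  ann2 <- GenomeAnnotation(ex2, cds2,
                           representative = unname(representativeTx(sim$annotation)),
                           seqlens = lens2)
  pk2 <- remap(cx$protein_peaks)
  res2 <- callBindingSites(pk2, remap(cx$control_peaks), lens2)
  expect_equal(tssProfile(res2$sites, ann2)$histogram$count, base_tss)
  expect_equal(donorProfile(res2$sites, ann2)$histogram$count, base_ss)
})
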