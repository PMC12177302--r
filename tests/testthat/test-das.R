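# gene with an exitron pair, a boundary-touching intron, and a shared intron
exitron_toys <- function() {
  ex <- rbind(
    # gene C: C.1 one long CDS exon; C.2 splices 2301..2380 out of it -> EI
    data.frame(chrom = "Chr1", start = 2101, end = 2700, strand = "+",
               transcript_id = "C.1", gene_id = "C"),
    data.frame(chrom = "Chr1", start = c(2101, 2381), end = c(2300, 2700),
               strand = "+", transcript_id = "C.2", gene_id = "C"),
    # gene D: intron 5' boundary equals the sibling CDS exon start -> not EI
    data.frame(chrom = "Chr1", start = 4101, end = 4700, strand = "+",
               transcript_id = "D.1", gene_id = "D"),
    data.frame(chrom = "Chr1", start = c(4001, 4281), end = c(4150, 4700),
               strand = "+", transcript_id = "D.2", gene_id = "D"),
    # gene E: both transcripts share the same intron -> not an exitron
    data.frame(chrom = "Chr1", start = c(6101, 6301), end = c(6200, 6500),
               strand = "+", transcript_id = "E.1", gene_id = "E"),
    data.frame(chrom = "Chr1", start = c(6101, 6301), end = c(6200, 6500),
               strand = "+", transcript_id = "E.2", gene_id = "E")
  )
  cds <- rbind(
    data.frame(chrom = "Chr1", start = 2151, end = 2650, strand = "+",
               transcript_id = "C.1", gene_id = "C"),
    data.frame(chrom = "Chr1", start = c(2151, 2381), end = c(2300, 2650),
               strand = "+", transcript_id = "C.2", gene_id = "C"),
    # D.2's intron is 4151..4280; D.1's CDS exon starts exactly at 4151
    data.frame(chrom = "Chr1", start = 4151, end = 4650, strand = "+",
               transcript_id = "D.1", gene_id = "D"),
    data.frame(chrom = "Chr1", start = c(4051, 4281), end = c(4150, 4650),
               strand = "+", transcript_id = "D.2", gene_id = "D"),
    data.frame(chrom = "Chr1", start = c(6151, 6301), end = c(6200, 6450),
               strand = "+", transcript_id = "E.1", gene_id = "E"),
    data.frame(chrom = "Chr1", start = c(6151, 6301), end = c(6200, 6450),
               strand = "+", transcript_id = "E.2", gene_id = "E")
  )
  df_annotation(ex, cds, representative = c("C.1", "D.1", "E.1"),
                seqlens = c(Chr1 = 10000L))
}

test_that("exitron definition is strict and frame-aware", {
  ann <- exitron_toys()
  ei <- detectExitrons(ann)
  expect_equal(ei$gene_id, "C")
  expect_equal(ei$start, 2301)
  expect_equal(ei$end, 2380)
  expect_equal(ei$frame, 80L %% 3L)
  # gene D (boundary not strictly internal) and gene E (shared intron) absent
  expect_false(any(c("D", "E") %in% ei$gene_id))
})

test_that("planted exitrons in the synthetic annotation are all recovered", {
  sim <- simulateAnnotation(40, seed = 81)
  ei <- detectExitrons(sim$annotation)
  truth <- sim$truth$exitrons
  found <- paste(ei$gene_id, ei$start, ei$end)
  planted <- paste(truth$gene_id, truth$start, truth$end)
  expect_true(all(planted %in% found))
  tf <- truth$frame[match(intersect(planted, found), planted)]
  expect_equal(ei$frame[match(intersect(planted, found), found)], tf)
})

test_that("event enumeration covers AA/AD/CE/RI and degenerate genes", {
  # two transcripts differing only in one acceptor -> exactly one AA event
  ex <- rbind(
    data.frame(chrom = "Chr1", start = c(101, 261), end = c(200, 400),
               strand = "+", transcript_id = "A.1", gene_id = "A"),
    data.frame(chrom = "Chr1", start = c(101, 273), end = c(200, 400),
               strand = "+", transcript_id = "A.2", gene_id = "A")
  )
  ann <- df_annotation(ex, seqlens = c(Chr1 = 1000L))
  ev <- enumerateEvents(ann)
  expect_equal(sum(ev$type == "AA"), 1L)
  expect_equal(sum(ev$type == "AD"), 0L)
  # two distinct introns -> two RI events against the pre-mRNA
  expect_equal(sum(ev$type == "RI"), 2L)

  # intronless single-transcript gene: no events at all
  ex0 <- data.frame(chrom = "Chr1", start = 101, end = 400, strand = "+",
                    transcript_id = "Z.1", gene_id = "Z")
  expect_equal(nrow(enumerateEvents(df_annotation(ex0))), 0L)

  # minus-strand AD: same genomic change flips the label
  exm <- ex
  exm$strand <- "-"
  exm$transcript_id <- sub("A", "M", exm$transcript_id)
  exm$gene_id <- "M"
  evm <- enumerateEvents(df_annotation(exm))
  expect_equal(sum(evm$type == "AD"), 1L)
  expect_equal(sum(evm$type == "AA"), 0L)

  # cassette exon: skipping junction bridges the two flanking junctions
  exce <- rbind(
    data.frame(chrom = "Chr1", start = c(101, 301, 501), end = c(200, 400, 600),
               strand = "+", transcript_id = "K.1", gene_id = "K"),
    data.frame(chrom = "Chr1", start = c(101, 501), end = c(200, 600),
               strand = "+", transcript_id = "K.2", gene_id = "K")
  )
  evce <- enumerateEvents(df_annotation(exce))
  ce <- evce[evce$type == "CE", ]
  expect_equal(nrow(ce), 1L)
  expect_equal(ce$start, 301)
  expect_equal(ce$end, 400)
})

test_that("event enumeration matches a brute-force pairwise oracle", {
  sim <- simulateAnnotation(60, seed = 91)
  ev <- enumerateEvents(sim$annotation)

  # oracle: nested loops over transcript pairs of each gene
  ann <- sim$annotation
  intr <- intronsByTranscript(ann)
  idf <- data.frame(
    gene = as.character(S4Vectors::mcols(intr)$gene_id),
    tx = as.character(S4Vectors::mcols(intr)$transcript_id),
    strand = as.character(BiocGenerics::strand(intr)),
    s = BiocGenerics::start(intr), e = BiocGenerics::end(intr)
  )
  aa <- character(0); ad <- character(0)
  for (g in unique(idf$gene)) {
    d <- idf[idf$gene == g, ]
    d <- d[!duplicated(d[c("s", "e")]), ]
    if (nrow(d) < 2) next
    for (i in seq_len(nrow(d) - 1)) for (j in seq(i + 1, nrow(d))) {
      don_i <- if (d$strand[i] == "+") d$s[i] else d$e[i]
      don_j <- if (d$strand[j] == "+") d$s[j] else d$e[j]
      acc_i <- if (d$strand[i] == "+") d$e[i] else d$s[i]
      acc_j <- if (d$strand[j] == "+") d$e[j] else d$s[j]
      if (don_i == don_j && acc_i != acc_j) aa <- c(aa, paste(g, don_i,
                                                   min(acc_i, acc_j),
                                                   max(acc_i, acc_j)))
      if (acc_i == acc_j && don_i != don_j) ad <- c(ad, paste(g, acc_i,
                                                   min(don_i, don_j),
                                                   max(don_i, don_j)))
    }
  }
  expect_equal(sum(ev$type == "AA"), length(unique(aa)))
  expect_equal(sum(ev$type == "AD"), length(unique(ad)))
  # RI: one event per distinct annotated intron
  expect_equal(sum(ev$type == "RI"),
               nrow(unique(idf[c("gene", "s", "e")])))
  # planted alternative events are all present
  truth <- sim$truth$alt_events
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      expect_true(any(ev$gene_id == truth$gene_id[i] &
                        ev$type == truth$type[i]))
    }
  }
})

test_that("PSI is inclusion over total, with 0/0 missing", {
  expect_equal(computePSI(8, 2), 0.8)
  expect_true(is.na(computePSI(0, 0)))
  expect_error(computePSI(-1, 2), "non-negative")
  expect_equal(computePSI(c(1, 0), c(1, 5)), c(0.5, 0))

  # consistency: planted PSI 0.5 at depth 1e4 recovered within +/- 0.02
  withr::with_seed(3, {
    x <- rbinom(200, 10000, 0.5)
  })
  psi <- computePSI(x, 10000 - x)
  expect_true(all(abs(psi - 0.5) <= 0.02))
})

test_that("delta-PSI posterior behaves at the symmetric and extreme points", {
  same <- deltaPSI(c(50, 55, 45), c(50, 45, 55), c(50, 55, 45),
                   c(50, 45, 55), seed = 2)
  expect_lt(abs(same$dpsi), 0.02)
  expect_lt(abs(same$probability - 0.5), 0.1)

  ext <- deltaPSI(c(0, 0, 0), c(100, 100, 100), c(100, 100, 100),
                  c(0, 0, 0), seed = 2)
  expect_gt(ext$dpsi, 0.95)
  expect_gte(ext$probability, 0.99)

  # min-samples rule: fewer than 3 defined replicates excludes the event
  excl <- deltaPSI(c(10, 0, 0), c(10, 0, 0), c(5, 5, 5), c(5, 5, 5),
                   seed = 2)
  expect_false(excl$included)

  # sign recovery across a planted grid at depth 1000, 3 replicates
  for (eff in c(-0.3, -0.1, 0.1, 0.3)) {
    base <- 0.5
    withr::with_seed(7 + round(eff * 10), {
      ci <- rbinom(3, 1000, base)
      ti <- rbinom(3, 1000, base + eff)
    })
    dp <- deltaPSI(ci, 1000 - ci, ti, 1000 - ti, seed = 5)
    expect_equal(sign(dp$dpsi), sign(eff))
  }
})

test_that("significance filters mirror the rule-by-rule oracle", {
  withr::with_seed(23, {
    n <- 200
    res <- data.frame(
      event_id = sprintf("e%03d", 1:n),
      type = sample(c("AA", "AD", "CE", "RI", "EI"), n, replace = TRUE),
      incl_total = rpois(n, 3),
      excl_total = rpois(n, 3),
      ctrl_incl_all_pos = sample(c(TRUE, FALSE), n, replace = TRUE),
      test_incl_all_pos = sample(c(TRUE, FALSE), n, replace = TRUE),
      dpsi = runif(n, -0.5, 0.5),
      probability = runif(n),
      included = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.9, .1))
    )
  })
  out <- filterSignificant(res)
  oracle <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    ok <- r$included
    if (r$type %in% c("AA", "AD")) {
      ok <- ok && r$incl_total >= 1 && r$excl_total >= 1
    }
    if (r$type == "RI") {
      ok <- ok && (r$ctrl_incl_all_pos || r$test_incl_all_pos)
    }
    oracle[i] <- ok && r$probability >= 0.9 && abs(r$dpsi) >= 0.1
  }
  expect_equal(out$significant, oracle)
  expect_equal(out$strong, oracle & abs(res$dpsi) >= 0.3)

  # spot rules: an AA event with one junction never observed is excluded
  aa <- data.frame(event_id = "x", type = "AA", incl_total = 5L,
                   excl_total = 0L, ctrl_incl_all_pos = TRUE,
                   test_incl_all_pos = TRUE, dpsi = 0.5, probability = 1,
                   included = TRUE)
  expect_false(filterSignificant(aa)$significant)
  # an RI with reads in all test samples but none in control is kept
  ri <- data.frame(event_id = "y", type = "RI", incl_total = 5L,
                   excl_total = 5L, ctrl_incl_all_pos = FALSE,
                   test_incl_all_pos = TRUE, dpsi = 0.5, probability = 1,
                   included = TRUE)
  expect_true(filterSignificant(ri)$significant)
})

test_that("event-type summary reports percentages and the AA:AD ratio", {
  das <- data.frame(type = c(rep("AA", 10), rep("AD", 10), rep("RI", 20)),
                    dpsi = 0.2)
  s <- eventTypeSummary(das)
  expect_equal(s$aa_ad_ratio, 1.0)
  expect_equal(sum(s$summary$n), 40L)
  expect_equal(sum(s$summary$pct), 100)
  expect_equal(s$summary$pct[s$summary$type == "RI"], 50)
  empty <- eventTypeSummary(das[0, ])
  expect_true(is.na(empty$aa_ad_ratio))
})

test_that("direction summary matches exact hypergeometric enumeration", {
  # all RI positive, all EI negative, 10 each: p = 2 / C(20, 10)
  das <- data.frame(type = rep(c("RI", "EI"), each = 10),
                    dpsi = rep(c(0.2, -0.2), each = 10))
  ds <- directionSummary(das)
  expect_equal(ds$ri_ei_fisher_p, 2 / choose(20, 10))
  expect_equal(ds$by_type$pct_up[ds$by_type$type == "RI"], 100)
  expect_equal(ds$by_type$pct_down[ds$by_type$type == "EI"], 100)

  # seeded 2x2 tables vs the enumeration oracle (all n <= 40)
  withr::with_seed(29, {
    for (rep_i in 1:10) {
      nri <- sample(3:20, 1); nei <- sample(3:20, 1)
      ri_up <- sample(0:nri, 1); ei_up <- sample(0:nei, 1)
      das2 <- data.frame(
        type = c(rep("RI", nri), rep("EI", nei)),
        dpsi = c(rep(0.2, ri_up), rep(-0.2, nri - ri_up),
                 rep(0.2, ei_up), rep(-0.2, nei - ei_up))
      )
      m <- matrix(c(ri_up, nri - ri_up, ei_up, nei - ei_up), 2,
                  byrow = TRUE)
      expect_equal(directionSummary(das2)$ri_ei_fisher_p,
                   oracle_fisher2x2(m), tolerance = 1e-8)
    }
  })

  # single event: 100/0 split
  one <- directionSummary(data.frame(type = "RI", dpsi = 0.4))
  expect_equal(one$by_type$pct_up, 100)
  expect_equal(one$by_type$pct_down, 0)
  expect_equal(one$by_type$pct_strong_up, 100)
})

test_that("planted direction fractions are recovered within binomial error", {
  withr::with_seed(37, {
    nri <- 300; nei <- 150
    ri_up <- rbinom(1, nri, 0.762)
    ei_dn <- rbinom(1, nei, 0.702)
  })
  das <- data.frame(
    type = c(rep("RI", nri), rep("EI", nei)),
    dpsi = c(rep(0.2, ri_up), rep(-0.2, nri - ri_up),
             rep(-0.2, ei_dn), rep(0.2, nei - ei_dn))
  )
  ds <- directionSummary(das)
  expect_lt(abs(ds$by_type$pct_up[ds$by_type$type == "RI"] - 76.2), 7)
  expect_lt(abs(ds$by_type$pct_down[ds$by_type$type == "EI"] - 70.2), 10)
  expect_lt(ds$ri_ei_fisher_p, 1e-10)
})

test_that("splicing index is the longest isoform share of total signal", {
  expect_equal(splicingIndex(c(30, 70), c(1500, 900)), 0.3)
  expect_equal(splicingIndex(42, 1000), 1.0)
  expect_true(is.na(splicingIndex(c(0, 0), c(10, 20))))
  # order invariance
  expect_equal(splicingIndex(c(70, 30), c(900, 1500)),
               splicingIndex(c(30, 70), c(1500, 900)))
})

test_that("DE classification applies inclusive fold-change bounds", {
  st <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   l2fc = c(1, -1, 2, 0.5),
                   adj_p = c(0.01, 0.04, 0.2, 0.001))
  de <- classifyDE(st)
  expect_equal(de$class, c("up", "down", "unchanged", "unchanged"))
  expect_equal(de$total_de, 2L)

  # all p = 1: nothing is differential
  st1 <- data.frame(gene_id = "g", l2fc = 5, adj_p = 1)
  expect_equal(classifyDE(st1)$total_de, 0L)

  # missing values are logged and left unchanged
  stna <- data.frame(gene_id = "g", l2fc = NA, adj_p = 0.01)
  expect_message(dena <- classifyDE(stna), "missing")
  expect_equal(dena$class, "unchanged")
})

test_that("expression filter keeps genes with CPM >= 1 in >= 3 samples", {
  cpm <- rbind(a = c(2, 2, 2, 0, 0, 0, 0, 0, 0),
               b = c(2, 2, 0, 0, 0, 0, 0, 0, 0),
               c = rep(1, 9))
  expect_equal(unname(filterExpressed(cpm)), c(TRUE, FALSE, TRUE))
})

test_that("full DAS pipeline recovers planted effects end to end", {
  sim <- simulateAnnotation(50, seed = 101)
  ev <- enumerateEvents(sim$annotation)
  withr::with_seed(102, {
    hit <- sample(nrow(ev), 40)
    eff <- setNames(ifelse(ev$type[hit] == "EI", -0.3,
                           ifelse(ev$type[hit] == "RI", 0.3,
                                  sample(c(-0.3, 0.3), length(hit),
                                         replace = TRUE))),
                    ev$event_id[hit])
  })
  jc <- simulateJunctionCounts(ev, effects = eff, n_reps = 3, depth = 1000,
                               seed = 103)
  res <- dasAnalysis(ev, jc$counts, control = "control", test = "test",
                     config = clipConfig(seed = 104), n_draws = 1000)
  sig <- res[res$significant, ]
  # power on planted |dpsi| = 0.3
  planted <- res[res$event_id %in% names(eff), ]
  expect_gte(mean(planted$significant), 0.9)
  # planted effect signs recovered
  ok <- sign(planted$dpsi[planted$significant]) ==
    sign(eff[planted$event_id[planted$significant]])
  expect_true(all(ok))
  # null events rarely called
  null_ev <- res[!res$event_id %in% names(eff), ]
  expect_lte(mean(null_ev$significant), 0.05)
})
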