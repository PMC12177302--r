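# clipsplice

Linking an RNA-binding protein's iCLIP binding landscape to
alternative-splicing outcomes.

Serine/arginine-rich (SR) splicing factors bind pre-mRNA at specific
positions and reshape splice-site choice. Individual-nucleotide resolution
crosslinking and immunoprecipitation (iCLIP) maps those protein–RNA contacts
to single crosslink nucleotides; RNA-seq of lines where the factor is
knocked out or overexpressed reveals the splicing events it controls.
`clipsplice` implements the computational path between the two, for analysts
working on plant (or any compact-genome) SR-protein data:

1. **Binding-site definition** — PCR-duplicate removal by (mapping start,
   random barcode) identity; grouping of crosslink peaks at immediately
   adjacent nucleotides keeping the highest peak-caller score; extension of
   each retained peak by 4 nt on both sides into a 9-nt *binding site* whose
   centre is the *binding-site peak*; subtraction of sites with a
   same-strand control (e.g. GFP-only) site within 9 nt.
2. **Positional annotation** — assignment of sites to 5′ UTR / CDS / intron /
   3′ UTR of each gene's representative transcript; peak-distance profiles
   to the transcription start site (≤ 250 nt) and to 5′ splice sites (exons
   ≥ 50 nt), with extraction of 21-nt windows for sites 25–30 nt upstream of
   a donor site and a position frequency matrix stacked at the peak.
3. **Motif enrichment** — hexamer *z*-scores against a background of 9-nt
   windows resampled (default 1000×) from the same target transcripts:
   `z = (observed − bg_mean) / bg_sd`; exact-match motif scanning (e.g. the
   RNAcompete consensus CAGA) and peak-to-motif distance profiles; per-site
   motif fractions (CU-rich, CAGAU, UCAACC, ...).
4. **Differential alternative splicing** — annotation-driven enumeration of
   alternative acceptor (AA), alternative donor (AD), cassette exon (CE),
   retained intron (RI, quantified against the gene-span pre-mRNA) and
   exitron (EI: an intron whose boundaries lie strictly inside a sibling
   transcript's CDS exon) events; percent spliced-in
   `PSI = inclusion / (inclusion + exclusion)`; ΔPSI (test − control) from a
   Beta(½, ½)-posterior on pooled counts with a Monte-Carlo sign
   probability; the significance gates *probability ≥ 0.9* and
   *|ΔPSI| ≥ 0.1* (strong shifts: *|ΔPSI| ≥ 0.3*), plus junction-detection
   and read-support filters; event-type, direction (RI vs EI Fisher test)
   and splicing-index summaries; DE classification at *|L2FC| ≥ 1,
   adjusted p < 0.05*.
5. **Gene-set overlap statistics** — hypergeometric enrichment
   `P(X ≥ observed)` with the *representation factor*
   `observed / (n1·n2/N)`, plus 2/3-set Venn region counts.
6. **Synthetic data with ground truth** — generators for genomes,
   multi-isoform annotations (incl. planted exitrons with GT…AG junctions),
   crosslink peaks with positional bias and embedded motifs, control noise,
   duplicate-bearing reads, and binomial junction counts with planted ΔPSI
   effects, so every stage is testable without downloads.

## Worked example

```r
library(clipsplice)
library(Biostrings)

sim <- simulateAnnotation(n_genes = 40, seed = 7)
cx  <- simulateCrosslinkData(sim$annotation, sim$genome, seed = 8,
                             n_sites = 150, motif_rate = 0.8)

lens   <- setNames(width(cx$genome), names(cx$genome))
called <- callBindingSites(cx$protein_peaks, cx$control_peaks, lens)
called$sites
#> BindingSiteSet with 123 sites of width 9
called$candidate_count; called$removed_count
#> 150 candidate sites, 27 removed as control-proximal

assignFeatures(called$sites, sim$annotation)$feature_percentages
#>   feature n_genes  pct
#> 1    5UTR      33 86.8
#> 2     CDS      37 97.4
#> 3  intron       0  0.0
#> 4    3UTR       0  0.0

ss  <- siteSequences(called$sites, cx$genome)
txs <- transcriptSeqs(sim$annotation, cx$genome,
                      representativeTx(sim$annotation))
head(hexamerZscores(ss, txs, n_samples = 1000, seed = 9), 5)
#>   hexamer observed bg_mean     bg_sd        z degenerate
#> 1  UCAGAC        9   0.194 0.4319150 20.38827      FALSE
#> 2  AACAGA       10   0.243 0.4941611 19.74457      FALSE
#> 3  ACAGAC        9   0.257 0.5071570 17.23924      FALSE
#> 4  UGCAGA        8   0.209 0.4555508 17.10237      FALSE
#> 5  ACCAGA        7   0.177 0.4169471 16.36419      FALSE
```

The top hexamers all carry the embedded CAGA core: the protein's binding
sites are CAGA-enriched relative to 1000 resamples from the very transcripts
it binds (observed ~9 windows vs ~0.2 expected, z ≈ 20).

```r
ev  <- enumerateEvents(sim$annotation)
eff <- setNames(rep(0.3, 10), ev$event_id[ev$type == "RI"][1:10])
jc  <- simulateJunctionCounts(ev, effects = eff, n_reps = 3, depth = 1000,
                              seed = 10)
res <- dasAnalysis(ev, jc$counts, control = "control", test = "test",
                   config = clipConfig(seed = 11))
eventTypeSummary(res[res$significant, ])$summary
#>   type  n pct
#> 1   RI 10 100
```

All ten planted retention shifts (ΔPSI = +0.3) pass the probability ≥ 0.9
and |ΔPSI| ≥ 0.1 gates; no null event does.

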