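# ripcpe

Characterizing the target spectrum of an RNA-binding protein from RIP-Seq.

RNA immunoprecipitation followed by sequencing (RIP-Seq) identifies the
transcripts bound by a protein by comparing read counts between
immunoprecipitated (IP) and control libraries. For CPEB-family proteins the
bound transcripts ("binders") are expected to carry cytoplasmic
polyadenylation elements (CPEs) in their 3′-UTRs, so a natural follow-up
question is whether called binders differ from non-binders in element
content, element density, and UTR length. `ripcpe` packages that whole
analysis for anyone working with RIP-Seq of a 3′-UTR-binding protein:

1. **Binder calling** (`rip_enrichment()`): median-of-ratios size factors,
   per-transcript method-of-moments negative-binomial dispersion (plugged in
   as a common dispersion for testing), a Wald test of
   `log2(mean_IP / mean_control)` with a delta-method standard error under
   `Var(K) = μ + αμ²`, Benjamini–Hochberg adjustment, and the classification
   rule `log2FC > 0` and `FDR < 0.01` (both thresholds configurable).
2. **CPE scanning** (`scan_utrs()`): literal, sense-strand scanning of
   3′-UTRs for the four element classes — consensus CPE
   (CPEC: `UUUUAU`, `UUUUAAU`), non-consensus CPE (CPENC: `UUUUAAAU`,
   `UUUUACU`, `UUUUCAU`), the polyadenylation hexanucleotide (Hex:
   `AAUAAA`, `AUUAAA`) and the Pumilio-binding element (PBE: `UGUAAAUA`,
   `UGUAUAUA`) — with counts, 1-based positions, per-kilobase densities, a
   BED6 track, and positional cluster maps (`motif_map()`).
3. **Binder-vs-non-binder statistics** (`compare_binders()`): per class, the
   2×2 table of transcripts with more than *k* = 3 elements with a two-sided
   Fisher exact test (minimum-likelihood rule, sample odds ratio *ad/bc*);
   Mann–Whitney rank-sum tests (exact when enumerable, tie- and
   continuity-corrected normal approximation otherwise) for CPEC/CPENC
   per-kb density and UTR length.
4. **Optional binder-probability score** (`binder_score()`): a deterministic
   L2-penalized logistic regression of the binder flag on log10 UTR length
   and the four per-kb densities, with held-out probabilities from fixed
   5-fold splits.
5. **Synthetic data with ground truth** (`generate_utr_set()`,
   `generate_count_matrix()`): seeded log-normal UTR lengths and
   negative-binomial counts in which a binder subset has longer UTRs, higher
   planted motif densities, and IP enrichment — so every stage of the
   pipeline is testable end to end without external data.

`run_pipeline()` (or the `inst/cli/ripcpe.R` script with subcommands
`simulate`, `scan`, `call-binders`, `compare`, `run-all`) orchestrates the
stages and writes TSV/BED/JSON outputs plus a manifest with checksums;
identical configuration and seed give byte-identical outputs.

## Worked example

```r
library(ripcpe)
cfg <- generator_config(n_transcripts = 1000, seed = 7)
g   <- generate_utr_set(cfg)
cm  <- generate_count_matrix(g$labels, cfg)

enr <- rip_enrichment(cm$counts, cm$design)   # log2fc > 0 & q < 0.01
table(called = enr$is_binder, truth = g$labels$is_binder)
#>        truth
#> called  FALSE TRUE
#>   FALSE   900    5
#>   TRUE      0   95
```

Of 100 simulated binders (4-fold IP enrichment), 95 are recovered with no
false positives at FDR < 0.01. Comparing called binders against
non-binders:

```r
prof   <- scan_utrs(g$utrs)$profiles
labels <- data.frame(transcript_id = enr$transcript_id,
                     is_binder = enr$is_binder)
rep <- compare_binders(prof, labels, k = 3)
rep$classes$CPEC
#> $table
#>           high low
#> binder      28  67
#> nonbinder   61 844
#> $odds_ratio
#> [1] 5.782236
#> $fisher_p
#> [1] 5.870897e-10
rep$ranksum$utr_length
#> $U
#> [1] 63103.5
#> $p
#> [1] 5.851424e-14
#> $median_binder
#> [1] 1320
#> $median_nonbinder
#> [1] 783
```

Called binders are ~5.8 times more likely to carry more than three CPEC
elements, and their median UTR is 1320 nt versus 783 nt for non-binders —
the comparative signature the pipeline is designed to detect.

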