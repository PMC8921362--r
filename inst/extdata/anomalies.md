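# Known internal inconsistencies of the embedded reference tables

These are carried verbatim from the publication and are never silently
"corrected" by the package.

1. **Pat3R geometry vs. its recovery coefficient.** Pat3R is printed with
   volume 156.3 cm3, surface 376.6 cm2, SA:V 2.4 cm^-1, yet its RCs
   (~36-38% at cold background) fall far below the value the published
   regression predicts at SA:V 2.4 (~61%). A possible misprint in the
   geometry row; the fixtures keep the printed values.

2. **Abstract vs. Table 2 attribution of 48.4 +/- 8.3%.** The abstract
   quotes 48.4 +/- 8.3% for cortex-only phantoms "at a 10-to-1 TBR";
   Table 2 prints that figure in the infinity-TBR / 36-iteration column
   (the 10:1 / 36-iteration column is 48.0 +/- 7.2). Fixtures follow the
   table.

3. **Discussion's cortex mean of 49.1%.** The discussion quotes a typical
   cortex-only RC of 49.1% (infinity TBR, 72 iterations) where Table 2's
   AVG row gives 49.8. Fixtures follow the table.

4. **Refitting the regression from printed data.** Ordinary least squares
   on the 20 printed (SA:V, RC) pairs does not reproduce the printed
   best-fit coefficients (largely driven by Pat3R); the publication
   presumably fitted unrounded SA:V values. The package reports both the
   refit and the printed coefficients without reconciling them.

5. **Summary cells not recomputable from their own printed columns.**
   Recomputing from the printed per-phantom values: the cortex-only
   infinity/36-iteration SD is 8.244 (displays 8.2, printed 8.3); the
   cortex-only 10:1/36-iteration mean is 48.078 (displays 48.1, printed
   48.0); the whole-parenchyma infinity/72-iteration mean is 77.16
   (displays 77.2, printed 77.1); and the whole-parenchyma minus
   cortex-only 5:1/72 contrast is 26.856 pp (displays 26.9, printed
   26.8). All four recomputations sit within the last printed decimal;
   the publication evidently summarized unrounded per-phantom values.

6. **Spread conventions differ between tables.** The geometry table's
   printed +/- values are population (divide-by-n) SDs (e.g. cortex
   volume 26.8 = 28.45 * sqrt(8/9)); the RC tables use sample (n-1) SDs.
   The package reproduces each table under its own convention.
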