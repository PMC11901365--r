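# abtriage

Developability triage for paired antibody variable-domain sequences.

Repertoire sequencing produces libraries of 10^4–10^5 paired V<sub>H</sub>/V<sub>L</sub>
antibody sequences; only a handful can be characterised experimentally.
`abtriage` screens such libraries for sequences that *look like clinically
successful antibodies*, in three stages applied in fixed order:

1. **Physicochemical filter (PCF).** Five fast sequence statistics —
   CDR-H3 loop length (Chothia window H95–H102, insertions included),
   additive unfolding free energy ΔG = Σ<sub>i</sub>(ΔH<sub>i</sub> − T·ΔS<sub>i</sub>) for
   V<sub>H</sub>, V<sub>L</sub> and their concatenation, and the mean isoelectric point of
   the two chains (Henderson–Hasselbalch with the EMBOSS pKa set) — each
   gated at |x − μ<sub>ref</sub>| ≤ Z·σ<sub>ref</sub> against an approved-antibody
   reference (default Z = 2), plus a hard “at most two cysteines per chain”
   rule.
2. **Layer 1 (unsupervised gate).** Chains are Chothia-numbered onto fixed
   grids (V<sub>H</sub>: 132 slots, V<sub>L</sub>: 122), padded, and encoded position-wise
   into one feature vector per pair (an AntiBERTy-style encoder yields
   (132+122)×512 = 130,048 features; a seeded mock encoder ships for
   weight-free operation). rbf kernel PCA
   (K<sub>ij</sub> = exp(−γ‖x<sub>i</sub>−x<sub>j</sub>‖²), two components) projects library,
   clinical and query antibodies together; a rotated ellipse built from the
   clinical cloud’s Z-score extremes (major radius a = |p₂−p₁|/2, minor
   radius b = h/2, rotation θ = atan2(Δy, Δx), centred at the midpoint)
   retains query points inside it.
3. **Layer 2 (supervised).** Univariate F-regression
   (F = r²(n−2)/(1−r²)) ranks features; the top k (default 2500) feed a
   linear squared-hinge classifier (ridge and logistic variants included)
   with Platt-calibrated probabilities, trained on approved-vs-discontinued
   reference antibodies and thresholded at 0.5 (or 0.8 for high stringency).
   Performance is assessed by stratified 10-fold CV with MCC, sensitivity
   and specificity, with feature selection refit inside every fold.

Every stage can be disabled or tightened independently; seeded synthetic
generators (repertoires on germline templates, embedding clouds, planted
feature matrices) make the whole pipeline testable offline. See the methods
vignette (`vignettes/abtriage-methods.Rmd`) for the models, conventions and
their caveats — in particular, the shipped thermodynamic constants are a
labelled synthetic stand-in, so absolute ΔG values are not comparable with
published ones.

## Worked example

```r
library(abtriage)

clinical <- generate_repertoire(repertoire_spec(10, mutation_rate = 0.01, cdrh3_sd = 2, seed = 11),
                                status = "clinical", prefix = "cln")
library_ <- generate_repertoire(repertoire_spec(25, seed = 12), status = "library", prefix = "lib")
approved <- generate_repertoire(repertoire_spec(8, mutation_rate = 0.01, cdrh3_sd = 2, seed = 13),
                                status = "approved", prefix = "app")
disc     <- generate_repertoire(repertoire_spec(8, mutation_rate = 0.05, seed = 14),
                                status = "discontinued", prefix = "dis")
query    <- generate_repertoire(repertoire_spec(15, seed = 15), status = "query", prefix = "qry")

physchem_features(query[[1]])
#> cdr_h3_length         dG_vh         dG_vl     dG_concat       mean_pI
#>         14.00       4575.95       3501.98       8077.93          7.60

report <- run_pipeline(query,
                       list(clinical = clinical, library = library_,
                            approved = approved, discontinued = disc),
                       pipeline_config(encoder_dim = 2, seed = 1))
report
#> <triage_report>
#>   input=15 -> numbering=15 -> pcf=8 -> layer1=8 -> layer2=8

head(report$rows[c("id", "pcf_retained", "layer1_inside", "layer2_probability", "final")], 4)
#>          id pcf_retained layer1_inside layer2_probability        final
#> 1 qry_00001         TRUE          TRUE          0.8938434     retained
#> 2 qry_00002        FALSE            NA                 NA rejected:pcf
#> 3 qry_00003         TRUE          TRUE          0.6481510     retained
#> 4 qry_00004        FALSE            NA                 NA rejected:pcf
```

Reading the output: 15 query antibodies enter; all number cleanly onto the
grids; 7 fail the Z = 2 physicochemical gate against the approved-reference
statistics (the synthetic query has a much broader CDR-H3 length
distribution than the tight approved set, so rejections are expected); the 8
survivors all fall inside the Z = “all” clinical ellipse and are scored by
the Layer-2 classifier, whose calibrated probability ≥ 0.5 reads
“approved-like”. `write_report(report, "report.tsv")` writes the per-antibody
TSV plus a JSON run header with the seeds and survivor counts.

A minimal command-line front end is installed as `exec/abtriage`
(`abtriage physchem`, `abtriage synth`, `abtriage run`; see
`?abtriage_cli`).

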