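# Bundled data

`synthetic_hif_phenotypes.tsv` and `synthetic_ft_expression.tsv` are SYNTHETIC
stand-ins generated by `sim_hif()` and `sim_expression()` (seeds 77 / 78).
They exist so examples and readers can run out of the box; they are not
measurements.

Two analyses in `tests/testthat/test-acceptance.R` compare mixed-model F
statistics against the published greenhouse HIF analysis. They look for the
original (non-redistributable) supplementary datasets here under the names

- `dataset_S1.txt` — HIF phenotypes: Block, Flowering_time,
  Leaf_number_at_flowering, Height_at_flowering, nFT_genotype, HIF, Family
- `dataset_S2.txt` — FT expression: Plant_ID, HIF, Family, nFT_genotype,
  Visible_bud, delta_Ct

and fail (they do not skip) when the files are absent.
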