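# Bundled fixtures

All files are small plain-text TSVs used by the examples and tests.

- `bcac_snp_or.tsv` — per-SNP breast-cancer odds ratios (OR, 95% CI, p) for
  17 BMI-associated SNPs as reported by the Breast Cancer Association
  Consortium (BCAC, iCOGS); per effect-allele increase, adjusted for age,
  study and eight principal components.
- `drive_snp_or.tsv` — the same SNPs as reported by the GAME-ON DRIVE
  consortium (summary statistics).
- `combined_snp_or_published.tsv` — the reported fixed-effects combination of
  the two consortia for the same SNPs, used as a reference when checking that
  the package's log-scale conversion + inverse-variance recombination
  reproduces the printed combined ORs at their printed precision.
- `synthetic_panel_84.tsv` — a SYNTHETIC 84-SNP BMI instrument panel produced
  by `simulate_panel(seed = 84)`; it mimics the shape of a curated GWAS
  instrument file (rsid, position, alleles, EAF, per-allele beta, SE, p) and
  carries no real genetic associations.
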