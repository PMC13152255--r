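# Pipeline configuration.
#
# Prior probabilities of pathogenicity for the multifactorial likelihood
# model, keyed by Align-GVGD grade (missense variants) or by variant type
# (variants without a grade). These defaults follow the published
# Align-GVGD prior conventions for BRCA2; curation databases maintain the
# authoritative values, so edit this file to match the table in force.
priors:
  align_gvgd_grade:
    C0: 0.02
    C15: 0.29
    C25: 0.29
    C35: 0.66
    C45: 0.66
    C55: 0.66
    C65: 0.81
  variant_type:
    nonsense: 0.96
    canonical_splice: 0.96
    synonymous: 0.02
    intronic: 0.02
    missense: 0.29

# Combined likelihood ratios within this window (inclusive) are considered
# uninformative: no IARC class is assigned.
exclusion_window: [0.5, 2.0]
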