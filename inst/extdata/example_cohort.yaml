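# Example cohort configuration: one inheritance model per family plus
# optional overrides of the filter thresholds and fixture paths.
families:
  fam01: AD
  fam30: AR
maf_threshold_ad: 0.005
maf_threshold_ar: 0.05
missing_maf_policy: keep
missing_genotype_policy: noninformative
ar_carrier_scope: parents
min_segregations: 3
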