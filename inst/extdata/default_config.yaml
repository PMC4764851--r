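# Declarative defaults for every tunable threshold in the pipeline.
# Values follow the published conventions for each analysis step.

# orthology / integrity
blast_e_max: 1.0e-5          # general pairwise-hit significance cutoff
ohr_identity_min: 90         # percent identity filter (strict >) before OHR
ohr_full_length_min: 0.8     # OHR at or above which a transcript is "full-length"

# expression / differential expression
de_fold_change_min: 2        # minimum |weighted-proportion fold change|
de_alpha: 0.01               # Bonferroni-corrected p-value cutoff
de_min_total_count: 10       # reliability filter defining the tested universe
enrichment_p_max: 1.0e-5     # hypergeometric significance cutoff
enrichment_min_observed: 5   # observed matches must be strictly greater
bootstrap_n: 1000            # bootstrap replicates for sample clustering

# mobilome
repeat_min_length: 100       # candidate repeats must be strictly longer (nt)
te_domain_whitelist:         # TE-related protein domains that re-include a candidate
  - IPR000477   # reverse transcriptase
  - IPR023109   # integrase/recombinase N-terminal
  - IPR001584   # integrase catalytic core
  - IPR004242   # transposase
  - IPR002156   # ribonuclease H
  - IPR025476   # TE endonuclease (Helitron helicase-like)
  - IPR004875   # DDE superfamily endonuclease
  - IPR013103   # reverse transcriptase RNase H-like

# expansion scan
cluster_identity_min: 0.75   # amino-acid identity for redundancy reduction
expansion_min_focal_count: 20
expansion_alpha: 0.05

# molecular evolution
ortholog_e_max: 1.0e-50      # strict cutoff for 1:1 ortholog selection
rrt_alpha: 0.05
column_max_gap_fraction: 0.0 # alignment-column filtering
actinodin_motif: "C[ND]PxxDPxC"
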