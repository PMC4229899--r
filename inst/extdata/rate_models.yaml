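# Packaged mutation-rate models.
# per_marker_rate: mutations per marker (or per HVS-I segment) per
# generation; per_haplotype_rate: mutations per whole haplotype per
# generation, stored as the published (rounded) constant where the source
# prints one (rounded_from_product: true) -- downstream interval and TMRCA
# arithmetic uses these printed constants.
# genealogical: family-genealogy-calibrated Y-STR rate (slope constant
#   0.00166/marker/25 y, taken as a calibrated input).
# germline: father-son pedigree aggregate over 126,873 meioses.
# hvs1_pedigree: pooled mother-child HVS-I rate (28 substitutions over
#   2633 transmissions); hvs1_fossil: phylogenetically calibrated rate for
#   the 16,051-16,400 segment.
# nry_sites: per-site SNP rate over the ~10.15 Mb callable NRY, for
#   mutation-interval arithmetic.
models:
  genealogical:
    per_marker_rate: 0.00166
    per_marker_sd: ~
    n_markers: 12
    per_haplotype_rate: 0.020
    rounded_from_product: true
    generation_years: 25
    back_correction: smm_inversion
  germline:
    per_marker_rate: 2.113e-3
    per_marker_sd: 1.369e-3
    n_markers: 12
    per_haplotype_rate: 0.025
    rounded_from_product: true
    generation_years: 25
    back_correction: none
    meioses: 126873
  hvs1_pedigree:
    per_marker_rate: 1.06e-2
    per_marker_sd: ~
    n_markers: 1
    per_haplotype_rate: 1.06e-2
    rounded_from_product: false
    generation_years: 25
    back_correction: none
    mutations: 28
    transmissions: 2633
  hvs1_fossil:
    per_marker_rate: 1.42e-3
    per_marker_sd: ~
    n_markers: 1
    per_haplotype_rate: 1.42e-3
    rounded_from_product: false
    generation_years: 25
    back_correction: none
    segment: [16051, 16400]
  nry_sites:
    per_marker_rate: 3.0e-8
    per_marker_sd: ~
    n_markers: 10150000
    per_haplotype_rate: 0.3045
    rounded_from_product: false
    generation_years: 25
    back_correction: none
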