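# Map from structured claim-annotation codes (INFORMAS-style code families)
# to the two claim types of EU Regulation 1924/2006. Extend as needed; codes
# not listed here are rejected by resolve_claims().
nutrition-content: nutrition
nutrition-comparative: nutrition
nutrient-function: health
other-function: health
disease-risk-reduction: health
general-health: health
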