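# Statements screened out before taxonomy mapping: eight families of on-pack
# text that are not health-related claims. Rules are evaluated in this order,
# case-insensitively, on whitespace-normalised text; the first match wins.
- id: natural-organic-halal
  keywords: ["natural", "organic", "halal"]
- id: additive-absence
  keywords: ["no additives", "no preservatives", "no colourings",
             "no flavourings", "no artificial", "free from additives",
             "preservative free", "additive free"]
- id: allergy-advice
  keywords: ["contains nuts", "may contain", "allergy advice", "allergen"]
- id: diet-statement
  keywords: ["gluten free", "gluten-free", "wheat free", "lactose free",
             "dairy free", "vegetarian", "vegan", "suitable for a"]
- id: storage-advice
  keywords: ["stays fresh", "keep refrigerated", "store in a", "once opened",
             "best before"]
- id: food-presence
  keywords: ["contains chocolate", "made with real", "contains real",
             "with whole"]
- id: sport-cause-advertising
  keywords: ["official product", "olympic", "official sponsor", "supporting",
             "proud partner"]
- id: nutrition-labelling
  keywords: ["traffic light", "guideline daily amount", "gda",
             "reference intake", "% ri", "front of pack", "per serving contains"]
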