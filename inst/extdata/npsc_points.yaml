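# FSANZ NPSC band tables (FSA/Ofcom-derived schedule).
# Points for a nutrient = number of thresholds strictly exceeded; exact
# equality with a threshold scores the lower band. Category 3 (fats, oils,
# spreads, cheese) extends the saturated-fat band at 1 g/point and the
# sodium band at 90 mg/point to 30 points; override here to match any
# revision of the official schedule.
baseline:
  "1":
    energy_kJ: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
    saturated_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
    total_sugars_g: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
    sodium_mg: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
  "2":
    energy_kJ: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
    saturated_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
    total_sugars_g: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
    sodium_mg: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
  "3":
    energy_kJ: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
    saturated_fat_g: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16,
                      17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30]
    total_sugars_g: [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
    sodium_mg: [90, 180, 270, 360, 450, 540, 630, 720, 810, 900, 990, 1080,
                1170, 1260, 1350, 1440, 1530, 1620, 1710, 1800, 1890, 1980,
                2070, 2160, 2250, 2340, 2430, 2520, 2610, 2700]
modifying:
  fvnl_percent:
    thresholds: [40, 60, 80]
    points: [1, 2, 5]
  protein_g: [1.6, 3.2, 4.8, 6.4, 8.0]
  fibre_g: [0.9, 1.9, 2.8, 3.7, 4.7]
protein_cap:
  baseline_cap: 13
  v_release: 5
# A food FAILS when final score > fail_above for its category.
# orientation "standard" is the FSANZ schedule (beverages strictest);
# orientation "literal" swaps categories 1 and 2, reproducing the reading
# "fails at >0 (or >3 for drinks or >27 for fats, oils and cheeses)".
fail_above:
  "1": 0
  "2": 3
  "3": 27
orientation: standard
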