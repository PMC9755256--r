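# Default world configuration: six populations at relative planar positions
# approximating the west-to-east arrangement of six well-known ape field
# sites, with their reported community sizes, and the default food
# sub-category structure (sizes sum to 32; nutrients alternate Y/Z).
sites:
  - {site: site_1, x: -8.5, y: 7.6, n: 20}
  - {site: site_2, x: -7.3, y: 5.9, n: 42}
  - {site: site_3, x: 29.6, y: -4.7, n: 49}
  - {site: site_4, x: 29.9, y: -6.1, n: 76}
  - {site: site_5, x: 30.4, y: 0.6, n: 50}
  - {site: site_6, x: 31.6, y: 1.7, n: 95}
food_structure:
  - {size: 8, nutrient: Y}
  - {size: 5, nutrient: Z}
  - {size: 4, nutrient: Y}
  - {size: 4, nutrient: Z}
  - {size: 3, nutrient: Y}
  - {size: 2, nutrient: Z}
  - {size: 2, nutrient: Y}
  - {size: 2, nutrient: Z}
  - {size: 1, nutrient: Y}
  - {size: 1, nutrient: Z}
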