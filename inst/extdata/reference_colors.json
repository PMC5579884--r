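{
  "comment": "Reference Lab characterizations of ten background surfaces and four green color cards, transcribed as printed from the published characterization tables. Backgrounds store mean and sigma only (printed mean±sigma bound columns are redundant and contain at least one misprint, 'Stone steps'). Greens print no sigma; consumers fall back to the quarter-range convention |max-min|/4. Cells where the printed minimum/maximum rows are inconsistent with the mean are transcribed as printed and flagged 'suspect', never corrected. table4_label records the row label used by the published coverage table where it differs from the surface name.",
  "surfaces": [
    {
      "name": "Grey paving stones",
      "category": "anthropogenic",
      "table4_label": "Gray pavings",
      "mean": {"L": 18.69, "a": 2.80, "b": 20.81},
      "sigma": {"L": 0.62, "a": 1.00, "b": 0.54}
    },
    {
      "name": "Asphalt",
      "category": "anthropogenic",
      "table4_label": "Asphalt cover",
      "mean": {"L": 12.91, "a": 2.16, "b": 13.53},
      "sigma": {"L": 0.34, "a": 1.71, "b": 1.12}
    },
    {
      "name": "Gravel",
      "category": "anthropogenic",
      "mean": {"L": 7.44, "a": 3.15, "b": 12.24},
      "sigma": {"L": 1.05, "a": 1.00, "b": 1.46}
    },
    {
      "name": "Stone steps",
      "category": "anthropogenic",
      "table4_label": "Flagged floor",
      "mean": {"L": 13.55, "a": 2.34, "b": 15.44},
      "sigma": {"L": 0.50, "a": 0.52, "b": 0.76}
    },
    {
      "name": "Fine chippings",
      "category": "anthropogenic",
      "table4_label": "Concrete",
      "mean": {"L": 15.55, "a": 3.90, "b": 18.52},
      "sigma": {"L": 0.55, "a": 0.50, "b": 0.84}
    },
    {
      "name": "Red paving stones",
      "category": "anthropogenic",
      "table4_label": "Red pavings",
      "mean": {"L": 15.28, "a": 13.61, "b": 24.12},
      "sigma": {"L": 1.28, "a": 2.89, "b": 0.91}
    },
    {
      "name": "Sandy path",
      "category": "anthropogenic",
      "mean": {"L": 11.45, "a": 4.90, "b": 19.72},
      "sigma": {"L": 0.41, "a": 1.62, "b": 1.18}
    },
    {
      "name": "Arable land",
      "category": "natural",
      "table4_label": "Field",
      "mean": {"L": 11.32, "a": 4.81, "b": 20.10},
      "sigma": {"L": 0.13, "a": 0.70, "b": 0.47}
    },
    {
      "name": "Grassland",
      "category": "natural",
      "mean": {"L": 10.35, "a": -2.37, "b": 22.74},
      "sigma": {"L": 0.96, "a": 2.40, "b": 2.06}
    },
    {
      "name": "Grassland with dew",
      "category": "natural",
      "table4_label": "Grassland+dew",
      "mean": {"L": 9.80, "a": -6.32, "b": 19.47},
      "sigma": {"L": 2.23, "a": 2.54, "b": 3.32}
    }
  ],
  "greens": [
    {
      "name": "Green 1",
      "median": {"L": 44.78, "a": -15.21, "b": 44.47},
      "mean":   {"L": 44.80, "a": -15.24, "b": 44.39},
      "min":    {"L": 44.71, "a": -14.85, "b": 43.79},
      "max":    {"L": 44.84, "a": -15.73, "b": 44.69},
      "suspect": ["channel a: printed minimum/maximum rows reversed (min -14.85 > max -15.73)"]
    },
    {
      "name": "Green 2",
      "median": {"L": 40.45, "a": -26.27, "b": 51.75},
      "mean":   {"L": 40.45, "a": -26.18, "b": 51.80},
      "min":    {"L": 40.39, "a": -16.83, "b": 50.82},
      "max":    {"L": 40.55, "a": -25.60, "b": 52.91},
      "suspect": ["channel a: printed minimum -16.83 exceeds printed maximum -25.60"]
    },
    {
      "name": "Green 3",
      "median": {"L": 33.95, "a": -49.86, "b": 33.39},
      "mean":   {"L": 33.95, "a": -49.95, "b": 33.54},
      "min":    {"L": 32.95, "a": -49.61, "b": 32.95},
      "max":    {"L": 34.47, "a": -50.53, "b": 34.47},
      "suspect": ["channel a: printed minimum/maximum rows reversed", "channels L and b: printed min/max values duplicated across channels, possibly a transcription slip in the source table"]
    },
    {
      "name": "Green 4",
      "median": {"L": 29.16, "a": -61.65, "b": -4.33},
      "mean":   {"L": 29.15, "a": -61.51, "b": -4.22},
      "min":    {"L": 28.98, "a": -63.01, "b": -3.25},
      "max":    {"L": 29.32, "a": -60.35, "b": -4.96},
      "suspect": ["channel b: printed minimum/maximum rows reversed (min -3.25 > max -4.96)"]
    }
  ]
}
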