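{
  "version": "1.0",
  "intervals": [
    {
      "feature": "FOREHEAD_SD",
      "grade": "II",
      "lo": 0.39,
      "hi": 2.86,
      "provenance": "forehead-frown table Min/Max rows; HBII lower bound extended to 0.39 to cover calibration patient 5"
    },
    {
      "feature": "FOREHEAD_SD",
      "grade": "III",
      "lo": 3.76,
      "hi": 4.46,
      "provenance": "forehead-frown table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_SD",
      "grade": "IV",
      "lo": 4.54,
      "hi": 5.81,
      "provenance": "forehead-frown table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_SD",
      "grade": "V",
      "lo": 6.33,
      "hi": 11.07,
      "provenance": "forehead-frown table Min/Max rows"
    },
    {
      "feature": "MOUTH_SD",
      "grade": "II",
      "lo": 0.32,
      "hi": 2.72,
      "provenance": "smile table Min/Max rows"
    },
    {
      "feature": "MOUTH_SD",
      "grade": "III",
      "lo": 3,
      "hi": 3.9,
      "provenance": "smile table Min/Max rows"
    },
    {
      "feature": "MOUTH_SD",
      "grade": "IV",
      "lo": 3.99,
      "hi": 4.65,
      "provenance": "smile table Min/Max rows"
    },
    {
      "feature": "MOUTH_SD",
      "grade": "V",
      "lo": 4.99,
      "hi": 6.24,
      "provenance": "smile table Min/Max rows"
    },
    {
      "feature": "TOTAL_SD",
      "grade": "II",
      "lo": 1.03,
      "hi": 5.13,
      "provenance": "total shift-difference table Min/Max rows"
    },
    {
      "feature": "TOTAL_SD",
      "grade": "III",
      "lo": 6.89,
      "hi": 8.13,
      "provenance": "total shift-difference table Min/Max rows"
    },
    {
      "feature": "TOTAL_SD",
      "grade": "IV",
      "lo": 8.98,
      "hi": 10.35,
      "provenance": "total shift-difference table Min/Max rows"
    },
    {
      "feature": "TOTAL_SD",
      "grade": "V",
      "lo": 11.49,
      "hi": 16.39,
      "provenance": "total shift-difference table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_AI",
      "grade": "II",
      "lo": 0.74,
      "hi": 0.98,
      "provenance": "frontal asymmetry-index table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_AI",
      "grade": "III",
      "lo": 0.54,
      "hi": 0.68,
      "provenance": "frontal asymmetry-index table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_AI",
      "grade": "IV",
      "lo": 0.41,
      "hi": 0.52,
      "provenance": "frontal asymmetry-index table Min/Max rows"
    },
    {
      "feature": "FOREHEAD_AI",
      "grade": "V",
      "lo": 0.03,
      "hi": 0.38,
      "provenance": "frontal asymmetry-index table Min/Max rows"
    },
    {
      "feature": "MOUTH_AI",
      "grade": "II",
      "lo": 0.73,
      "hi": 0.94,
      "provenance": "mouth asymmetry-index table Min/Max rows"
    },
    {
      "feature": "MOUTH_AI",
      "grade": "III",
      "lo": 0.55,
      "hi": 0.69,
      "provenance": "mouth asymmetry-index table Min/Max rows"
    },
    {
      "feature": "MOUTH_AI",
      "grade": "IV",
      "lo": 0.43,
      "hi": 0.51,
      "provenance": "mouth asymmetry-index table Min/Max rows"
    },
    {
      "feature": "MOUTH_AI",
      "grade": "V",
      "lo": 0.1,
      "hi": 0.34,
      "provenance": "mouth asymmetry-index table Min/Max rows"
    },
    {
      "feature": "TOTAL_AI",
      "grade": "II",
      "lo": 0.755,
      "hi": 0.93,
      "provenance": "per-grade extrema of per-patient means of the two partial indices"
    },
    {
      "feature": "TOTAL_AI",
      "grade": "III",
      "lo": 0.565,
      "hi": 0.665,
      "provenance": "per-grade extrema of per-patient means of the two partial indices"
    },
    {
      "feature": "TOTAL_AI",
      "grade": "IV",
      "lo": 0.44,
      "hi": 0.51,
      "provenance": "per-grade extrema of per-patient means of the two partial indices"
    },
    {
      "feature": "TOTAL_AI",
      "grade": "V",
      "lo": 0.085,
      "hi": 0.36,
      "provenance": "per-grade extrema of per-patient means of the two partial indices"
    }
  ]
}
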