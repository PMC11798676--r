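{
  "cancer_type": "ToyType2",
  "channel_dispersion": 50,
  "signatures": [
    {
      "signature": "TS01",
      "prevalence": 1,
      "activity_size": 3,
      "activity_mu": 5000
    },
    {
      "signature": "TS02",
      "prevalence": 0.5,
      "activity_size": 1.5,
      "activity_mu": 1500
    },
    {
      "signature": "TS03",
      "prevalence": 0.35,
      "activity_size": 1,
      "activity_mu": 800
    },
    {
      "signature": "TS04",
      "prevalence": 0.25,
      "activity_size": 2,
      "activity_mu": 2500
    }
  ]
}
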