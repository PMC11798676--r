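{
  "cancer_type": "ToyType1",
  "channel_dispersion": 50,
  "signatures": [
    {
      "signature": "TS01",
      "prevalence": 0.95,
      "activity_size": 2,
      "activity_mu": 8000
    },
    {
      "signature": "TS02",
      "prevalence": 0.8,
      "activity_size": 2,
      "activity_mu": 4000
    },
    {
      "signature": "TS03",
      "prevalence": 0.6,
      "activity_size": 1.5,
      "activity_mu": 2000
    },
    {
      "signature": "TS04",
      "prevalence": 0.4,
      "activity_size": 1,
      "activity_mu": 1000
    },
    {
      "signature": "TS05",
      "prevalence": 0.3,
      "activity_size": 1,
      "activity_mu": 500
    },
    {
      "signature": "TS06",
      "prevalence": 0.2,
      "activity_size": 3,
      "activity_mu": 1500
    }
  ]
}
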