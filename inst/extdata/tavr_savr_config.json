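{
  "attributes": [
    {
      "name": "procedure",
      "label": "Type of procedure",
      "direction": "benefit",
      "worst": 0,
      "best": 1,
      "units": "binary"
    },
    {
      "name": "mortality",
      "label": "Mortality (1 month)",
      "direction": "risk",
      "worst": 0.053,
      "best": 0.005,
      "units": "proportion"
    },
    {
      "name": "stroke",
      "label": "Disabling non-fatal stroke",
      "direction": "risk",
      "worst": 0.044,
      "best": 0.002,
      "units": "proportion"
    },
    {
      "name": "independence",
      "label": "Independence",
      "direction": "benefit",
      "worst": 0.227,
      "best": 0.5,
      "units": "proportion"
    },
    {
      "name": "pacemaker",
      "label": "New permanent pacemaker",
      "direction": "risk",
      "worst": 0.142,
      "best": 0.072,
      "units": "proportion"
    },
    {
      "name": "dialysis",
      "label": "Requirement for dialysis",
      "direction": "risk",
      "worst": 0.06,
      "best": 0.021,
      "units": "proportion"
    },
    {
      "name": "proven",
      "label": "Proven to work",
      "direction": "benefit",
      "worst": 5,
      "best": 30,
      "units": "years"
    }
  ],
  "alternatives": [
    {
      "name": "TAVR",
      "performance": {
        "procedure": {
          "mean": 1
        },
        "mortality": {
          "mean": 0.011,
          "ci_low": 0.005,
          "ci_high": 0.017
        },
        "stroke": {
          "mean": 0.008,
          "ci_low": 0.002,
          "ci_high": 0.013
        },
        "independence": {
          "mean": 0.479,
          "ci_low": 0.454,
          "ci_high": 0.5
        },
        "pacemaker": {
          "mean": 0.123,
          "ci_low": 0.103,
          "ci_high": 0.142
        },
        "dialysis": {
          "mean": 0.032,
          "ci_low": 0.021,
          "ci_high": 0.042
        },
        "proven": {
          "mean": 10
        }
      }
    },
    {
      "name": "SAVR",
      "performance": {
        "procedure": {
          "mean": 0
        },
        "mortality": {
          "mean": 0.04,
          "ci_low": 0.028,
          "ci_high": 0.053
        },
        "stroke": {
          "mean": 0.033,
          "ci_low": 0.021,
          "ci_high": 0.044
        },
        "independence": {
          "mean": 0.249,
          "ci_low": 0.227,
          "ci_high": 0.276
        },
        "pacemaker": {
          "mean": 0.09,
          "ci_low": 0.072,
          "ci_high": 0.108
        },
        "dialysis": {
          "mean": 0.047,
          "ci_low": 0.034,
          "ci_high": 0.06
        },
        "proven": {
          "mean": 20
        }
      }
    }
  ]
}
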