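{
  "producer": {
    "levels": ["pfizer", "astrazeneca", "gamaleya", "sinovac", "unspecified"],
    "baseline": "unspecified",
    "unspecified_level": "unspecified",
    "efficacy_map": {
      "pfizer": 95,
      "astrazeneca": 70,
      "gamaleya": 91,
      "sinovac": 50
    },
    "display": {
      "pfizer": "Pfizer, based in the USA",
      "astrazeneca": "AstraZeneca-University of Oxford, based in the UK",
      "gamaleya": "the Gamaleya Institute, based in Russia",
      "sinovac": "Sinovac, based in China",
      "unspecified": ""
    }
  },
  "efficacy_shown": {
    "levels": ["yes", "unspecified"],
    "baseline": "unspecified",
    "unspecified_level": "unspecified"
  },
  "endorser": {
    "levels": ["president", "mayor", "medical_association", "religious_leader", "left_newspaper", "right_newspaper"],
    "baseline": "medical_association",
    "display": {
      "president": "the President",
      "mayor": "the mayor of your municipality",
      "medical_association": "the national medical association",
      "religious_leader": "religious leader",
      "left_newspaper": "a left-leaning newspaper",
      "right_newspaper": "a right-leaning newspaper"
    }
  },
  "distributor": {
    "levels": ["healthcare_system", "military", "civil_society"],
    "baseline": "healthcare_system",
    "display": {
      "healthcare_system": "the public healthcare system",
      "military": "the military",
      "civil_society": "civil society organizations"
    }
  },
  "uptake": {
    "levels": ["1", "25", "50", "75", "unspecified"],
    "baseline": "unspecified",
    "unspecified_level": "unspecified"
  }
}
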