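{
  "swls": {
    "name": "swls",
    "items": ["swls_i1", "swls_i2", "swls_i3", "swls_i4", "swls_i5"],
    "response_min": 1,
    "response_max": 7,
    "reverse": [],
    "scoring": "sum"
  },
  "rss": {
    "name": "rss",
    "items": ["rss_i1", "rss_i2", "rss_i3", "rss_i4", "rss_i5"],
    "response_min": 1,
    "response_max": 6,
    "reverse": ["rss_i2"],
    "scoring": "sum"
  },
  "ecr_anxiety": {
    "name": "ecr_anxiety",
    "items": ["aanx_i1", "aanx_i2", "aanx_i3", "aanx_i4", "aanx_i5", "aanx_i6"],
    "response_min": 1,
    "response_max": 7,
    "reverse": [],
    "scoring": "sum"
  },
  "ecr_avoidance": {
    "name": "ecr_avoidance",
    "items": ["aavo_i1", "aavo_i2", "aavo_i3", "aavo_i4", "aavo_i5", "aavo_i6"],
    "response_min": 1,
    "response_max": 7,
    "reverse": [],
    "scoring": "sum"
  },
  "ucla_loneliness": {
    "name": "ucla_loneliness",
    "items": ["lon_i1", "lon_i2", "lon_i3"],
    "response_min": 1,
    "response_max": 5,
    "reverse": [],
    "scoring": "sum"
  },
  "trust": {
    "name": "trust",
    "items": ["trust_i1", "trust_i2", "trust_i3"],
    "response_min": 0,
    "response_max": 10,
    "reverse": ["trust_i2"],
    "scoring": "sum"
  }
}
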