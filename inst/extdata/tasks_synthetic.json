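[
  {
    "task_id": "bingo",
    "name": "Bingo",
    "subfunction": "sustained",
    "cc": {"sustained": 4, "selective": 2, "divided": 1, "visual": 0,
           "verbal": 0, "working": 0, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "dimension", "values": ["4x4", "5x5", "6x6"],
       "weights": [0, 1, 2]},
      {"name": "presentation_time", "values": [4, 3.5, 3, 2.5, 2],
       "weights": [0, 1, 2, 3, 4]},
      {"name": "level", "values": ["ordered", "disorder"],
       "weights": [0, 1]}
    ],
    "duration": 10
  },
  {
    "task_id": "s01_visual_search",
    "name": "Visual search grid (synthetic)",
    "subfunction": "selective",
    "cc": {"sustained": 2, "selective": 4, "divided": 1, "visual": 1,
           "verbal": 0, "working": 0, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "distractors", "values": [5, 10, 20, 40],
       "weights": [0, 1, 2, 3]},
      {"name": "time_limit", "values": [90, 60, 30], "weights": [0, 1, 2]}
    ],
    "duration": 8
  },
  {
    "task_id": "s02_dual_track",
    "name": "Dual tracking (synthetic)",
    "subfunction": "divided",
    "cc": {"sustained": 1, "selective": 2, "divided": 4, "visual": 0,
           "verbal": 0, "working": 1, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "streams", "values": [1, 2, 3], "weights": [0, 1, 2]},
      {"name": "speed", "values": ["slow", "medium", "fast"],
       "weights": [0, 1, 2]}
    ],
    "duration": 9
  },
  {
    "task_id": "s03_picture_pairs",
    "name": "Picture pairs (synthetic)",
    "subfunction": "visual",
    "cc": {"sustained": 0, "selective": 1, "divided": 0, "visual": 4,
           "verbal": 0, "working": 2, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "pairs", "values": [4, 6, 8, 12], "weights": [0, 1, 2, 3]},
      {"name": "exposure", "values": [5, 3, 2], "weights": [0, 1, 2]}
    ],
    "duration": 7
  },
  {
    "task_id": "s04_word_list",
    "name": "Word list recall (synthetic)",
    "subfunction": "verbal",
    "cc": {"sustained": 0, "selective": 0, "divided": 0, "visual": 0,
           "verbal": 4, "working": 2, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 1, "categorization": 1},
    "parameters": [
      {"name": "words", "values": [5, 8, 12], "weights": [0, 1, 2]},
      {"name": "delay", "values": ["none", "short", "long"],
       "weights": [0, 1, 2]}
    ],
    "duration": 6
  },
  {
    "task_id": "s05_n_back",
    "name": "N-back (synthetic)",
    "subfunction": "working",
    "cc": {"sustained": 2, "selective": 0, "divided": 1, "visual": 1,
           "verbal": 1, "working": 4, "scheduling": 0, "inhibition": 0,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "n", "values": [1, 2, 3], "weights": [0, 2, 4]},
      {"name": "isi", "values": [3, 2, 1.5], "weights": [0, 1, 2]}
    ],
    "duration": 8
  },
  {
    "task_id": "s06_errand_plan",
    "name": "Errand planning (synthetic)",
    "subfunction": "scheduling",
    "cc": {"sustained": 0, "selective": 0, "divided": 0, "visual": 0,
           "verbal": 0, "working": 2, "scheduling": 4, "inhibition": 0,
           "flexibility": 1, "sequencing": 2, "categorization": 0},
    "parameters": [
      {"name": "errands", "values": [3, 5, 7], "weights": [0, 1, 2]},
      {"name": "constraints", "values": [0, 1, 2], "weights": [0, 1, 2]}
    ],
    "duration": 12
  },
  {
    "task_id": "s07_go_nogo",
    "name": "Go/no-go (synthetic)",
    "subfunction": "inhibition",
    "cc": {"sustained": 2, "selective": 1, "divided": 0, "visual": 0,
           "verbal": 0, "working": 0, "scheduling": 0, "inhibition": 4,
           "flexibility": 1, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "nogo_ratio", "values": [0.2, 0.35, 0.5],
       "weights": [0, 1, 2]},
      {"name": "tempo", "values": ["slow", "fast"], "weights": [0, 1]}
    ],
    "duration": 6
  },
  {
    "task_id": "s08_rule_switch",
    "name": "Rule switching (synthetic)",
    "subfunction": "flexibility",
    "cc": {"sustained": 0, "selective": 1, "divided": 1, "visual": 0,
           "verbal": 0, "working": 1, "scheduling": 0, "inhibition": 2,
           "flexibility": 4, "sequencing": 0, "categorization": 1},
    "parameters": [
      {"name": "rules", "values": [2, 3, 4], "weights": [0, 1, 2]},
      {"name": "switch_rate", "values": ["low", "high"], "weights": [0, 1]}
    ],
    "duration": 9
  },
  {
    "task_id": "s09_story_order",
    "name": "Story ordering (synthetic)",
    "subfunction": "sequencing",
    "cc": {"sustained": 0, "selective": 0, "divided": 0, "visual": 1,
           "verbal": 2, "working": 1, "scheduling": 1, "inhibition": 0,
           "flexibility": 0, "sequencing": 4, "categorization": 0},
    "parameters": [
      {"name": "scenes", "values": [3, 5, 8], "weights": [0, 1, 3]}
    ],
    "duration": 7
  },
  {
    "task_id": "s10_sort_objects",
    "name": "Object sorting (synthetic)",
    "subfunction": "categorization",
    "cc": {"sustained": 0, "selective": 1, "divided": 0, "visual": 1,
           "verbal": 1, "working": 0, "scheduling": 0, "inhibition": 0,
           "flexibility": 2, "sequencing": 0, "categorization": 4},
    "parameters": [
      {"name": "categories", "values": [2, 3, 5], "weights": [0, 1, 2]},
      {"name": "ambiguity", "values": ["low", "medium", "high"],
       "weights": [0, 1, 2]}
    ],
    "duration": 8
  },
  {
    "task_id": "s11_vigilance",
    "name": "Long vigilance (synthetic)",
    "subfunction": "sustained",
    "cc": {"sustained": 3, "selective": 1, "divided": 0, "visual": 0,
           "verbal": 0, "working": 0, "scheduling": 0, "inhibition": 1,
           "flexibility": 0, "sequencing": 0, "categorization": 0},
    "parameters": [
      {"name": "duration_level", "values": ["short", "medium", "long"],
       "weights": [0, 1, 2]},
      {"name": "target_rate", "values": ["high", "low"], "weights": [0, 1]}
    ],
    "duration": 11
  }
]
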