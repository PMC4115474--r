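{
  "item_01": {
    "subfunction": "sustained",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 53,
          "sd": 10
        },
        "secondary": {
          "mean": 55,
          "sd": 10
        },
        "higher": {
          "mean": 57,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 50,
          "sd": 10
        },
        "secondary": {
          "mean": 52,
          "sd": 10
        },
        "higher": {
          "mean": 54,
          "sd": 10
        }
      }
    }
  },
  "item_02": {
    "subfunction": "selective",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 58,
          "sd": 10
        },
        "secondary": {
          "mean": 60,
          "sd": 10
        },
        "higher": {
          "mean": 62,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 55,
          "sd": 10
        },
        "secondary": {
          "mean": 57,
          "sd": 10
        },
        "higher": {
          "mean": 59,
          "sd": 10
        }
      }
    }
  },
  "item_03": {
    "subfunction": "divided",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 63,
          "sd": 10
        },
        "secondary": {
          "mean": 65,
          "sd": 10
        },
        "higher": {
          "mean": 67,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 60,
          "sd": 10
        },
        "secondary": {
          "mean": 62,
          "sd": 10
        },
        "higher": {
          "mean": 64,
          "sd": 10
        }
      }
    }
  },
  "item_04": {
    "subfunction": "visual",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 68,
          "sd": 10
        },
        "secondary": {
          "mean": 70,
          "sd": 10
        },
        "higher": {
          "mean": 72,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 65,
          "sd": 10
        },
        "secondary": {
          "mean": 67,
          "sd": 10
        },
        "higher": {
          "mean": 69,
          "sd": 10
        }
      }
    }
  },
  "item_05": {
    "subfunction": "verbal",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 73,
          "sd": 10
        },
        "secondary": {
          "mean": 75,
          "sd": 10
        },
        "higher": {
          "mean": 77,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 70,
          "sd": 10
        },
        "secondary": {
          "mean": 72,
          "sd": 10
        },
        "higher": {
          "mean": 74,
          "sd": 10
        }
      }
    }
  },
  "item_06": {
    "subfunction": "working",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 78,
          "sd": 10
        },
        "secondary": {
          "mean": 80,
          "sd": 10
        },
        "higher": {
          "mean": 82,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 75,
          "sd": 10
        },
        "secondary": {
          "mean": 77,
          "sd": 10
        },
        "higher": {
          "mean": 79,
          "sd": 10
        }
      }
    }
  },
  "item_07": {
    "subfunction": "scheduling",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 83,
          "sd": 10
        },
        "secondary": {
          "mean": 85,
          "sd": 10
        },
        "higher": {
          "mean": 87,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 80,
          "sd": 10
        },
        "secondary": {
          "mean": 82,
          "sd": 10
        },
        "higher": {
          "mean": 84,
          "sd": 10
        }
      }
    }
  },
  "item_08": {
    "subfunction": "inhibition",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 88,
          "sd": 10
        },
        "secondary": {
          "mean": 90,
          "sd": 10
        },
        "higher": {
          "mean": 92,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 85,
          "sd": 10
        },
        "secondary": {
          "mean": 87,
          "sd": 10
        },
        "higher": {
          "mean": 89,
          "sd": 10
        }
      }
    }
  },
  "item_09": {
    "subfunction": "flexibility",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 93,
          "sd": 10
        },
        "secondary": {
          "mean": 95,
          "sd": 10
        },
        "higher": {
          "mean": 97,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 90,
          "sd": 10
        },
        "secondary": {
          "mean": 92,
          "sd": 10
        },
        "higher": {
          "mean": 94,
          "sd": 10
        }
      }
    }
  },
  "item_10": {
    "subfunction": "sequencing",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 98,
          "sd": 10
        },
        "secondary": {
          "mean": 100,
          "sd": 10
        },
        "higher": {
          "mean": 102,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 95,
          "sd": 10
        },
        "secondary": {
          "mean": 97,
          "sd": 10
        },
        "higher": {
          "mean": 99,
          "sd": 10
        }
      }
    }
  },
  "item_11": {
    "subfunction": "categorization",
    "norms": {
      "16-45": {
        "primary": {
          "mean": 103,
          "sd": 10
        },
        "secondary": {
          "mean": 105,
          "sd": 10
        },
        "higher": {
          "mean": 107,
          "sd": 10
        }
      },
      "46+": {
        "primary": {
          "mean": 100,
          "sd": 10
        },
        "secondary": {
          "mean": 102,
          "sd": 10
        },
        "higher": {
          "mean": 104,
          "sd": 10
        }
      }
    }
  }
}
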