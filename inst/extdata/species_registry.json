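[
  {
    "species": "Chrysomya albiceps",
    "family": "Calliphoridae",
    "k": 143.52,
    "se": 5.61,
    "unit": "ADD",
    "m": 7,
    "l_min": 5,
    "l_max": 12,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 174.74,
    "printed_slope": -3.67
  },
  {
    "species": "Lucilia sericata",
    "family": "Calliphoridae",
    "k": 6023.2,
    "se": 297.2,
    "unit": "ADH",
    "m": 7,
    "l_min": 5,
    "l_max": 12,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 7676.99,
    "printed_slope": -194.56
  },
  {
    "species": "Phormia regina",
    "family": "Calliphoridae",
    "k": 281,
    "se": 3.6,
    "unit": "ADD",
    "m": 5,
    "l_min": 6,
    "l_max": 10,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 308.89,
    "printed_slope": -3.49
  },
  {
    "species": "Fannia canicularis",
    "family": "Fanniidae",
    "k": 481.73,
    "se": 9.89,
    "unit": "ADD",
    "m": 8,
    "l_min": 3.5,
    "l_max": 7,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 554.41,
    "printed_slope": -13.84
  },
  {
    "species": "Necrobia rufipes",
    "family": "Cleridae",
    "k": 591,
    "se": 39.53,
    "unit": "ADD",
    "m": 6,
    "l_min": 3.5,
    "l_max": 7,
    "range_source": "source III",
    "ecology": "predatory",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 842.57,
    "printed_slope": -47.92
  },
  {
    "species": "Omosita colon",
    "family": "Nitidulidae",
    "k": 514.1,
    "se": 8.7,
    "unit": "ADD",
    "m": 6,
    "l_min": 2,
    "l_max": 3.6,
    "range_source": "source II",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 578.69,
    "printed_slope": -23.07
  },
  {
    "species": "Necrodes littoralis",
    "family": "Silphidae",
    "k": 469.89,
    "se": 24.59,
    "unit": "ADD",
    "m": 8,
    "l_min": 15,
    "l_max": 25,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": 8.5,
    "printed_intercept": 710.82,
    "printed_slope": -12.05
  },
  {
    "species": "Thanatophilus sinuatus",
    "family": "Silphidae",
    "k": 360.46,
    "se": 10.75,
    "unit": "ADD",
    "m": 7,
    "l_min": 9,
    "l_max": 12,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 532.88,
    "printed_slope": -16.42
  },
  {
    "species": "Thanatophilus rugosus",
    "family": "Silphidae",
    "k": 362.758,
    "se": 4.97,
    "unit": "ADD",
    "m": 6,
    "l_min": 8,
    "l_max": 12,
    "range_source": "source I",
    "ecology": "necrophagous",
    "corr_sign": "negative",
    "d0": null,
    "printed_intercept": 415.47,
    "printed_slope": -5.27
  },
  {
    "species": "Creophilus maxillosus",
    "family": "Staphylinidae",
    "k": 405.156,
    "se": 14.63,
    "unit": "ADD",
    "m": 8,
    "l_min": 15,
    "l_max": 25,
    "range_source": "source I",
    "ecology": "predatory",
    "corr_sign": "negative",
    "d0": 11.7,
    "printed_intercept": 548.5,
    "printed_slope": -7.17
  },
  {
    "species": "Nasonia vitripennis",
    "family": "Pteromalidae",
    "k": 4768.8,
    "se": 431.5,
    "unit": "ADH",
    "m": 6,
    "l_min": 1.3,
    "l_max": 2.2,
    "range_source": "source I",
    "ecology": "parasitoid",
    "corr_sign": "positive",
    "d0": null,
    "printed_intercept": 8328.49,
    "printed_slope": 2034.1
  }
]
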