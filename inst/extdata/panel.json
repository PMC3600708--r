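{
  "name": "msatools-11plex",
  "version": "1.0",
  "units": "bp",
  "markers": [
    {
      "name": "BAT25",
      "group": 1,
      "dye": "FAM",
      "window_min": 115,
      "window_max": 145,
      "repeat_unit": 1,
      "product_min": 130,
      "product_max": 130,
      "primer_conc": 0.25
    },
    {
      "name": "BAT26",
      "group": 1,
      "dye": "HEX",
      "window_min": 105,
      "window_max": 135,
      "repeat_unit": 1,
      "product_min": 120,
      "product_max": 120,
      "primer_conc": 2
    },
    {
      "name": "D3S3623",
      "group": 1,
      "dye": "FAM",
      "window_min": 200,
      "window_max": 230,
      "repeat_unit": 2,
      "product_min": 207,
      "product_max": 223,
      "primer_conc": 0.25
    },
    {
      "name": "D5S346",
      "group": 1,
      "dye": "NED",
      "window_min": 70,
      "window_max": 115,
      "repeat_unit": 2
    },
    {
      "name": "D6S262",
      "group": 1,
      "dye": "HEX",
      "window_min": 160,
      "window_max": 190,
      "repeat_unit": 2,
      "product_min": 167,
      "product_max": 183,
      "primer_conc": 0.5
    },
    {
      "name": "D7S481",
      "group": 1,
      "dye": "NED",
      "window_min": 175,
      "window_max": 205,
      "repeat_unit": 2,
      "product_min": 181,
      "product_max": 199,
      "primer_conc": 0.5
    },
    {
      "name": "D2S123",
      "group": 2,
      "dye": "HEX",
      "window_min": 200,
      "window_max": 240,
      "repeat_unit": 2,
      "product_min": 203,
      "product_max": 233,
      "primer_conc": 1
    },
    {
      "name": "D3S1262",
      "group": 2,
      "dye": "HEX",
      "window_min": 120,
      "window_max": 150,
      "repeat_unit": 2,
      "product_min": 132,
      "product_max": 146,
      "primer_conc": 2
    },
    {
      "name": "D9S171",
      "group": 2,
      "dye": "NED",
      "window_min": 100,
      "window_max": 130,
      "repeat_unit": 2,
      "product_min": 102,
      "product_max": 122,
      "primer_conc": 0.25
    },
    {
      "name": "D17S250",
      "group": 2,
      "dye": "NED",
      "window_min": 175,
      "window_max": 210,
      "repeat_unit": 2,
      "product_min": 188,
      "product_max": 203,
      "primer_conc": 0.5
    },
    {
      "name": "D18S61",
      "group": 2,
      "dye": "FAM",
      "window_min": 145,
      "window_max": 180,
      "repeat_unit": 2,
      "product_min": 150,
      "product_max": 176,
      "primer_conc": 0.5
    }
  ],
  "params": {
    "peak_algorithm": "advanced",
    "sizing_method": "local_southern",
    "min_peak_half_width": {
      "1": 4,
      "2": 2
    },
    "mono_cutoff": 0.95,
    "range_filters": [
      {
        "group": 1,
        "dye": "FAM",
        "min_bp": 146,
        "max_bp": 194
      },
      {
        "group": 1,
        "dye": "HEX",
        "min_bp": 136,
        "max_bp": 159
      },
      {
        "group": 1,
        "dye": "NED",
        "min_bp": 116,
        "max_bp": 174
      },
      {
        "group": 2,
        "dye": "FAM",
        "min_bp": 181,
        "max_bp": 250
      },
      {
        "group": 2,
        "dye": "HEX",
        "min_bp": 151,
        "max_bp": 199
      },
      {
        "group": 2,
        "dye": "NED",
        "min_bp": 131,
        "max_bp": 174
      }
    ],
    "peak_height_threshold": 50,
    "stutter_threshold": 0.8
  },
  "ladder": {
    "dye": "ROX",
    "sizes": [35, 50, 75, 100, 139, 150, 160, 200, 250, 300, 340, 350, 400, 450, 490, 500]
  },
  "bins": {
    "BAT25": {
      "centers": [115, 116, 117, 118, 119, 120, 121, 122, 123, 124, 125, 126, 127, 128, 129, 130, 131, 132, 133, 134, 135, 136, 137, 138, 139, 140, 141, 142, 143, 144, 145],
      "max_offset": 0.5
    },
    "BAT26": {
      "centers": [105, 106, 107, 108, 109, 110, 111, 112, 113, 114, 115, 116, 117, 118, 119, 120, 121, 122, 123, 124, 125, 126, 127, 128, 129, 130, 131, 132, 133, 134, 135],
      "max_offset": 0.5
    },
    "D3S3623": {
      "centers": [201, 203, 205, 207, 209, 211, 213, 215, 217, 219, 221, 223, 225, 227, 229],
      "max_offset": 0.5
    },
    "D5S346": {
      "centers": [71, 73, 75, 77, 79, 81, 83, 85, 87, 89, 91, 93, 95, 97, 99, 101, 103, 105, 107, 109, 111, 113, 115],
      "max_offset": 0.5
    },
    "D6S262": {
      "centers": [161, 163, 165, 167, 169, 171, 173, 175, 177, 179, 181, 183, 185, 187, 189],
      "max_offset": 0.5
    },
    "D7S481": {
      "centers": [176, 178, 180, 182, 184, 186, 188, 190, 192, 194, 196, 198, 200, 202, 204],
      "max_offset": 0.5
    },
    "D2S123": {
      "centers": [201, 203, 205, 207, 209, 211, 213, 215, 217, 219, 221, 223, 225, 227, 229, 231, 233, 235, 237, 239],
      "max_offset": 0.5
    },
    "D3S1262": {
      "centers": [121, 123, 125, 127, 129, 131, 133, 135, 137, 139, 141, 143, 145, 147, 149],
      "max_offset": 0.5
    },
    "D9S171": {
      "centers": [101, 103, 105, 107, 109, 111, 113, 115, 117, 119, 121, 123, 125, 127, 129],
      "max_offset": 0.5
    },
    "D17S250": {
      "centers": [176, 178, 180, 182, 184, 186, 188, 190, 192, 194, 196, 198, 200, 202, 204, 206, 208, 210],
      "max_offset": 0.5
    },
    "D18S61": {
      "centers": [146, 148, 150, 152, 154, 156, 158, 160, 162, 164, 166, 168, 170, 172, 174, 176, 178, 180],
      "max_offset": 0.5
    }
  }
}
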