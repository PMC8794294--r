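{
  "format": "nirspipe-montage-1",
  "nominal_separation_mm": {
    "long": 30,
    "short": 8
  },
  "sources": [
    {
      "id": 1,
      "x": 30,
      "y": 95
    },
    {
      "id": 2,
      "x": 50,
      "y": 95
    },
    {
      "id": 3,
      "x": -30,
      "y": 95
    },
    {
      "id": 4,
      "x": -50,
      "y": 95
    },
    {
      "id": 5,
      "x": 30,
      "y": -95
    },
    {
      "id": 6,
      "x": 50,
      "y": -95
    },
    {
      "id": 7,
      "x": -30,
      "y": -95
    },
    {
      "id": 8,
      "x": -50,
      "y": -95
    },
    {
      "id": 9,
      "x": 0,
      "y": 95
    }
  ],
  "long_detectors": [
    {
      "id": 1,
      "x": 20,
      "y": 70
    },
    {
      "id": 2,
      "x": 40,
      "y": 70
    },
    {
      "id": 3,
      "x": 60,
      "y": 70
    },
    {
      "id": 4,
      "x": -20,
      "y": 70
    },
    {
      "id": 5,
      "x": -40,
      "y": 70
    },
    {
      "id": 6,
      "x": -60,
      "y": 70
    },
    {
      "id": 7,
      "x": 20,
      "y": -70
    },
    {
      "id": 8,
      "x": 40,
      "y": -70
    },
    {
      "id": 9,
      "x": 60,
      "y": -70
    },
    {
      "id": 10,
      "x": -20,
      "y": -70
    },
    {
      "id": 11,
      "x": -40,
      "y": -70
    },
    {
      "id": 12,
      "x": -60,
      "y": -70
    },
    {
      "id": 13,
      "x": 0,
      "y": 70
    },
    {
      "id": 14,
      "x": 0,
      "y": -70
    }
  ],
  "short_detectors": [
    {
      "id": 1,
      "x": 38,
      "y": 95,
      "source_id": 1
    },
    {
      "id": 2,
      "x": 58,
      "y": 95,
      "source_id": 2
    },
    {
      "id": 3,
      "x": -22,
      "y": 95,
      "source_id": 3
    },
    {
      "id": 4,
      "x": -42,
      "y": 95,
      "source_id": 4
    },
    {
      "id": 5,
      "x": 38,
      "y": -95,
      "source_id": 5
    },
    {
      "id": 6,
      "x": 58,
      "y": -95,
      "source_id": 6
    },
    {
      "id": 7,
      "x": -22,
      "y": -95,
      "source_id": 7
    },
    {
      "id": 8,
      "x": -42,
      "y": -95,
      "source_id": 8
    },
    {
      "id": 9,
      "x": 8,
      "y": 95,
      "source_id": 9
    }
  ],
  "channels": [
    {
      "channel_id": 1,
      "source_id": 1,
      "detector_id": 3,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "lateral_FC",
      "qc_region": "lateral_PreFC_right"
    },
    {
      "channel_id": 2,
      "source_id": 2,
      "detector_id": 3,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "lateral_FC",
      "qc_region": "lateral_PreFC_right"
    },
    {
      "channel_id": 3,
      "source_id": 1,
      "detector_id": 2,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "lateral_preFC",
      "qc_region": "lateral_PreFC_right"
    },
    {
      "channel_id": 4,
      "source_id": 2,
      "detector_id": 2,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "lateral_preFC",
      "qc_region": "lateral_PreFC_right"
    },
    {
      "channel_id": 5,
      "source_id": 1,
      "detector_id": 1,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "medial_PFC",
      "qc_region": "medial_PreFC"
    },
    {
      "channel_id": 6,
      "source_id": 2,
      "detector_id": 1,
      "hemisphere": "right",
      "region": "PreFC",
      "roi": "medial_PFC",
      "qc_region": "medial_PreFC"
    },
    {
      "channel_id": 7,
      "source_id": 3,
      "detector_id": 6,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "lateral_FC",
      "qc_region": "lateral_PreFC_left"
    },
    {
      "channel_id": 8,
      "source_id": 4,
      "detector_id": 6,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "lateral_FC",
      "qc_region": "lateral_PreFC_left"
    },
    {
      "channel_id": 9,
      "source_id": 3,
      "detector_id": 5,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "lateral_preFC",
      "qc_region": "lateral_PreFC_left"
    },
    {
      "channel_id": 10,
      "source_id": 4,
      "detector_id": 5,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "lateral_preFC",
      "qc_region": "lateral_PreFC_left"
    },
    {
      "channel_id": 11,
      "source_id": 3,
      "detector_id": 4,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "medial_PFC",
      "qc_region": "medial_PreFC"
    },
    {
      "channel_id": 12,
      "source_id": 4,
      "detector_id": 4,
      "hemisphere": "left",
      "region": "PreFC",
      "roi": "medial_PFC",
      "qc_region": "medial_PreFC"
    },
    {
      "channel_id": 13,
      "source_id": 5,
      "detector_id": 7,
      "hemisphere": "right",
      "region": "S1",
      "roi": "superior_S1",
      "qc_region": "superior_S1"
    },
    {
      "channel_id": 14,
      "source_id": 6,
      "detector_id": 7,
      "hemisphere": "right",
      "region": "S1",
      "roi": "superior_S1",
      "qc_region": "superior_S1"
    },
    {
      "channel_id": 15,
      "source_id": 5,
      "detector_id": 8,
      "hemisphere": "right",
      "region": "S1",
      "roi": "central_S1",
      "qc_region": "central_S1"
    },
    {
      "channel_id": 16,
      "source_id": 6,
      "detector_id": 8,
      "hemisphere": "right",
      "region": "S1",
      "roi": "central_S1",
      "qc_region": "central_S1"
    },
    {
      "channel_id": 17,
      "source_id": 5,
      "detector_id": 9,
      "hemisphere": "right",
      "region": "S1",
      "roi": "inferior_S1",
      "qc_region": "inferior_S1"
    },
    {
      "channel_id": 18,
      "source_id": 6,
      "detector_id": 9,
      "hemisphere": "right",
      "region": "S1",
      "roi": "inferior_S1",
      "qc_region": "inferior_S1"
    },
    {
      "channel_id": 19,
      "source_id": 7,
      "detector_id": 10,
      "hemisphere": "left",
      "region": "S1",
      "roi": "superior_S1",
      "qc_region": "superior_S1"
    },
    {
      "channel_id": 20,
      "source_id": 8,
      "detector_id": 10,
      "hemisphere": "left",
      "region": "S1",
      "roi": "superior_S1",
      "qc_region": "superior_S1"
    },
    {
      "channel_id": 21,
      "source_id": 7,
      "detector_id": 11,
      "hemisphere": "left",
      "region": "S1",
      "roi": "central_S1",
      "qc_region": "central_S1"
    },
    {
      "channel_id": 22,
      "source_id": 8,
      "detector_id": 11,
      "hemisphere": "left",
      "region": "S1",
      "roi": "central_S1",
      "qc_region": "central_S1"
    },
    {
      "channel_id": 23,
      "source_id": 7,
      "detector_id": 12,
      "hemisphere": "left",
      "region": "S1",
      "roi": "inferior_S1",
      "qc_region": "inferior_S1"
    },
    {
      "channel_id": 24,
      "source_id": 8,
      "detector_id": 12,
      "hemisphere": "left",
      "region": "S1",
      "roi": "inferior_S1",
      "qc_region": "inferior_S1"
    }
  ]
}
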