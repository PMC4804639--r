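{
  "screen": {
    "width_px": 1280,
    "height_px": 1024,
    "sample_rate_hz": 50
  },
  "stimuli": [
    {
      "id": "A",
      "name": "Human face (still image)",
      "duration_s": 7,
      "aois": [
        {
          "id": "eyes",
          "role": "aoi1",
          "rect": [440, 280, 840, 430],
          "direction": "asd_lower"
        },
        {
          "id": "mouth",
          "role": "aoi2",
          "rect": [500, 600, 780, 740],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "B",
      "name": "Human face (blinking)",
      "duration_s": 7,
      "aois": [
        {
          "id": "eyes",
          "role": "aoi1",
          "rect": [440, 280, 840, 430],
          "direction": "asd_lower"
        },
        {
          "id": "mouth",
          "role": "aoi2",
          "rect": [500, 600, 780, 740],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "C",
      "name": "Human face (mouth moving)",
      "duration_s": 4,
      "aois": [
        {
          "id": "eyes",
          "role": "aoi1",
          "rect": [440, 280, 840, 430],
          "direction": "asd_lower"
        },
        {
          "id": "mouth",
          "role": "aoi2",
          "rect": [500, 600, 780, 740],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "D",
      "name": "Human face (silent)",
      "duration_s": 3,
      "aois": [
        {
          "id": "eyes",
          "role": "aoi1",
          "rect": [440, 280, 840, 430],
          "direction": "asd_lower"
        },
        {
          "id": "mouth",
          "role": "aoi2",
          "rect": [500, 600, 780, 740],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "E",
      "name": "Human face (talking)",
      "duration_s": 7,
      "aois": [
        {
          "id": "eyes",
          "role": "aoi1",
          "rect": [440, 280, 840, 430],
          "direction": "asd_lower"
        },
        {
          "id": "mouth",
          "role": "aoi2",
          "rect": [500, 600, 780, 740],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "F",
      "name": "Biological motion",
      "duration_s": 20,
      "aois": [
        {
          "id": "upright",
          "role": "aoi1",
          "rect": [40, 112, 600, 912],
          "direction": "asd_lower"
        },
        {
          "id": "inverted",
          "role": "aoi2",
          "rect": [680, 112, 1240, 912],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "G",
      "name": "People and geometry (same size)",
      "duration_s": 16,
      "aois": [
        {
          "id": "people",
          "role": "aoi1",
          "rect": [40, 112, 600, 912],
          "direction": "asd_lower"
        },
        {
          "id": "geometry",
          "role": "aoi2",
          "rect": [680, 112, 1240, 912],
          "direction": "asd_higher"
        }
      ]
    },
    {
      "id": "H",
      "name": "People and geometry (small window)",
      "duration_s": 16,
      "aois": [
        {
          "id": "geometry",
          "role": "aoi1",
          "rect": [832, 624, 1232, 944],
          "direction": "asd_higher"
        }
      ]
    }
  ]
}
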