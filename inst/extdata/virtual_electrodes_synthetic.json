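{
  "name": ["V1-L-01", "V1-L-02", "V1-L-03", "V1-L-04", "V1-L-05", "V1-L-06", "V1-L-07", "V1-L-08", "V1-L-09", "V1-L-10", "V1-R-01", "V1-R-02", "V1-R-03", "V1-R-04", "V1-R-05", "V1-R-06", "V1-R-07", "V1-R-08", "V1-R-09", "V1-R-10", "SEF", "FEF-L", "FEF-R", "IPS-L", "IPS-R"],
  "x": [-8, -8, -8, -8, -8, -8, -8, -8, -8, -8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 0, -40, 28, -30, 36],
  "y": [-96, -93, -90, -87, -84, -81, -78, -75, -72, -69, -96, -93, -90, -87, -84, -81, -78, -75, -72, -69, -9, 0, -6, -54, -58],
  "z": [0, 1.3, 2.7, 4, 5.3, 6.7, 8, 9.3, 10.7, 12, 0, 1.3, 2.7, 4, 5.3, 6.7, 8, 9.3, 10.7, 12, 70.5, 44, 50, 52, 58]
}
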