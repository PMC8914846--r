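timestamp,device_id,ta_c,rh_pct,tg_c,lw_wm2,tirt_c,light_lx,wind_ms
2021-09-02T00:00:00Z,office-east,22.29,49.627,22.078,436.412,,0,
2021-09-02T01:00:00Z,office-east,21.233,46.331,22.001,426.574,,0,
2021-09-02T02:00:00Z,office-east,21.211,47.552,21.647,427.403,,0,
2021-09-02T03:00:00Z,office-east,21.19,44.843,21.229,432.605,,0,
2021-09-02T04:00:00Z,office-east,21.224,48.987,22.023,433.958,,0,
2021-09-02T05:00:00Z,office-east,21.37,45.912,21.997,433.66,,0,
2021-09-02T06:00:00Z,office-east,22.332,46.748,22.235,428.866,,0,
2021-09-02T07:00:00Z,office-east,22.472,45.546,25.606,430.351,,7433.75,
2021-09-02T08:00:00Z,office-east,23.829,44.314,28.028,446.403,,10643.357,
2021-09-02T09:00:00Z,office-east,23.981,39.097,28.492,443.354,,11068.518,
2021-09-02T10:00:00Z,office-east,25.168,39.494,26.519,445.75,,6661.151,
2021-09-02T11:00:00Z,office-east,26.186,33.427,25.35,447.742,,0,
2021-09-02T12:00:00Z,office-east,25.705,33.961,25.677,444.996,,0,
2021-09-02T13:00:00Z,office-east,26.514,32.842,26.243,456.047,,0,
2021-09-02T14:00:00Z,office-east,26.858,29.112,26.614,453.174,,0,
2021-09-02T15:00:00Z,office-east,27.191,33.81,26.946,453.781,,0,
2021-09-02T16:00:00Z,office-east,26.813,34.353,26.222,458.926,,0,
2021-09-02T17:00:00Z,office-east,25.801,33.822,26.579,457.096,,0,
2021-09-02T18:00:00Z,office-east,25.389,37.046,25.888,457.928,,0,
2021-09-02T19:00:00Z,office-east,25.896,35.408,25.576,445.965,,0,
2021-09-02T20:00:00Z,office-east,24.684,35.747,24.931,448.56,,0,
2021-09-02T21:00:00Z,office-east,23.466,41.18,24.216,449.02,,0,
2021-09-02T22:00:00Z,office-east,23.172,40.621,23.032,433.285,,0,
2021-09-02T23:00:00Z,office-east,22.864,47.024,22.706,431.546,,0,
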