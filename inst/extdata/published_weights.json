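{
  "type": "mlp_parameters",
  "shape": [9, 10, 4],
  "hidden_activation": "logistic",
  "output_activation": "identity",
  "input_labels": ["storage_temp", "meat_temp", "butcher_A", "butcher_B", "butcher_C", "butcher_D", "weekday_Friday", "weekday_Monday", "weekday_Wednesday"],
  "output_labels": ["mab", "lab", "e_coli", "s_aureus"],
  "W1": [
    [3.7, 99.23, -65.6, 107.49, 41.19, -65.26, 6.55, 4.87, 6.45],
    [0.37, 142.56, -105.46, 303.75, -63.16, -103.04, 6.67, 10.37, 15.05],
    [-147.96, 58.25, -37.8, 29.99, 59.55, 1.93, 52.01, 25.22, -23.48],
    [-17.66, 20.1, -7.51, 2.4, 3.81, 2.01, 7.05, -1.54, -4.91],
    [-82.56, 65.6, -20.39, 20.45, 19.07, 14.19, 73.63, -2.84, -37.44],
    [-15.34, 27.46, -14.53, 2.62, 4.05, 7.24, 7.72, 0.28, -8.57],
    [231.07, -94.96, 35.69, -80.11, 34.42, -114.51, 44.36, -37.29, -131.65],
    [29.54, 105.16, -78.06, 115.68, -64.03, 98.64, 78, 58.36, -64.04],
    [28.94, 151.15, 61.4, 41.76, -101.17, -34.24, 93.39, -73.23, -52.44],
    [-14.48, 25.96, -121.1, 52.01, 53.46, 56.38, 73.42, 66.34, -98.96]
  ],
  "B1": [17.8, 32.05, 53.77, 0.68, 33.38, -0.58, -124.66, 72.23, -32.28, 40.75],
  "W2": {
    "mab": [65.57, -65.39, -5.27, -0.52, 5.61, 5.91, -3.4, -0.25, 0.08, -5.5],
    "lab": [3.41, -3.35, -38.85, 0.96, 38.44, 15.05, -27.28, 0.49, -0.15, -16.01],
    "e_coli": [55.53, -55.56, 71.22, 0.43, -71.6, 2.03, 50.36, 0.16, -0.1, -2.21],
    "s_aureus": [20.4, -20.35, -13.56, -0.59, 13.24, -33.94, -9.39, 0.4, 0.04, 34.45]
  },
  "B2": [0.3, 0.56, 0.09, -0.06],
  "checksum": {
    "abs_sum": 5939.57,
    "n_values": 144
  }
}
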