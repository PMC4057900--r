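# Frozen copies of the published study tables, kept independent of the
# package's own fixture loader so tests can catch fixture drift.

# 22 congeners: locant string, tabulated mu1 / mu2 (4 decimals),
# experimental lgKOA, group membership.
study_table <- function() {
  data.frame(
    congener = c(
      "2", "3", "2,4", "2,4'", "2,6", "3,4", "3,4'", "4,4'",
      "2,3,4", "2,4,6", "2,4',6", "3,3',4", "3,4,4'",
      "2,2',4,4'", "2,3',4,4'", "2,3',4,6", "2,4,4',6", "3,3',4,4'",
      "2,2',3,3',4", "2,2',4,4',5", "2,3',4,4',6", "2,2',4,4',5,5'"
    ),
    mu1 = c(
      0, 0, 0.0625, 0.0204, 0.0625, 0.1111, 0.0156, 0.0123,
      0.2847, 0.1875, 0.1033, 0.1471, 0.1391,
      0.2182, 0.2498, 0.2587, 0.2407, 0.2862,
      0.5478, 0.4127, 0.4230, 0.6276
    ),
    mu2 = c(
      1.1111, 1.0625, 2.1511, 2.1511, 2.2222, 2.1025, 2.1025, 2.0800,
      3.2136, 3.2622, 3.2622, 3.1650, 3.1425,
      4.3022, 4.2536, 4.3247, 4.3022, 4.2050,
      5.3872, 5.3647, 5.3647, 6.4272
    ),
    lgkoa = c(
      7.24, 7.36, 8.37, 8.47, 8.12, 8.55, 8.57, 8.64,
      9.49, 9.02, 9.28, 9.61, 9.68,
      10.34, 10.49, 10.23, 10.13, 10.7,
      11.14, 11.28, 11.52, 12.15
    ),
    group = c(
      "I", "II", "I", "I", "I", "II", "I", "I",
      "I", "II", "I", "I", "I",
      "II", "I", "I", "I", "II",
      "I", "I", "I", "II"
    ),
    pred_mlr = c(
      7.56, 7.38, 8.43, 8.46, 8.54, 8.40, 8.39, 8.35,
      9.22, 9.53, 9.54, 9.34, 9.32,
      10.41, 10.34, 10.45, 10.47, 10.27,
      11.38, 11.35, 11.28, 12.23
    ),
    pred_ann = c(
      7.45, 7.40, 8.43, 8.45, 8.50, 8.35, 8.41, 8.39,
      9.33, 9.44, 9.49, 9.37, 9.35,
      10.44, 10.37, 10.43, 10.42, 10.30,
      11.29, 11.36, 11.35, 12.26
    ),
    re_mlr = c(
      4.42, 0.27, 0.72, -0.12, 5.17, -1.75, -2.10, -3.36,
      -2.85, 5.65, 2.80, -2.81, -3.72,
      0.68, -1.43, 2.15, 3.36, -4.02,
      2.15, 0.62, -2.08, 0.66
    ),
    re_ann = c(
      3.59, 0.54, 0.36, -0.12, 5.05, -2.34, -1.63, -3.01,
      -2.42, 4.66, 2.26, -2.81, -3.82,
      0.97, -1.05, 1.96, 2.96, -3.74,
      2.15, 0.27, -1.39, 0.91
    ),
    stringsAsFactors = FALSE
  )
}
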