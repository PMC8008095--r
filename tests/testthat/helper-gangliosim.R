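# Hand-assembled reference facts used across test files.

# Identifier -> systematic Svennerholm name, assembled by hand from the
# naming rules (count letter, core number 4 - n + 1, series from the
# position II branch, alpha from the position III Neu5Ac).
KNOWN_SSN <- c(
  "LT" = "GA4",
  "[S3]LT" = "GM4",
  "[S8S3]LT" = "GD4",
  "[S8S8S3]LT" = "GT4",
  "L4GT" = "GA3",
  "[S3]L4GT" = "GM3",
  "[S8S3]L4GT" = "GD3",
  "[S8S8S3]L4GT" = "GT3",
  "Vb4L4GT" = "GA2",
  "Vb4[S3]L4GT" = "GM2",
  "Vb4[S8S3]L4GT" = "GD2",
  "Vb4[S8S8S3]L4GT" = "GT2",
  "L3Vb4L4GT" = "GA1",
  "S3L3Vb4L4GT" = "GM1",
  "S8S3L3Vb4L4GT" = "GD1",
  "S8S8S3L3Vb4L4GT" = "GT1",
  "S3L3[S6]Vb4L4GT" = "GD1α",
  "S8S3L3[S6]Vb4L4GT" = "GT1α",
  "S8S8S3L3[S6]Vb4L4GT" = "GQ1α",
  "L3Vb4[S3]L4GT" = "GM1a",
  "S3L3Vb4[S3]L4GT" = "GD1a",
  "L3Vb4[S8S3]L4GT" = "GD1b",
  "S3L3Vb4[S8S3]L4GT" = "GT1b",
  "S8S3L3Vb4[S8S3]L4GT" = "GQ1b",
  "L3Vb4[S8S8S3]L4GT" = "GT1c",
  "S3L3Vb4[S8S8S3]L4GT" = "GQ1c",
  "S3L3[S6]Vb4[S8S8S3]L4GT" = "GP1cα",
  "S8S8S3L3[S6]Vb4[S8S8S3]L4GT" = "GS1cα"
)

# The classical worked example and its names.
GP1CA_ID <- "S3L3[S6]Vb4[S8S8S3]L4GT"
GM1A_ID <- "L3Vb4[S3]L4GT"
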