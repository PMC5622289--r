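{
  "comment": "Average-row cells as printed in the source report, kept for provenance. Per-category counts in the per-rater tables sum to 99 (one smartphone lung scan and one scanner thyroid scan are missing), yet the printed average denominators are /100 and the printed accurate averages mix /99 and /100 arithmetic; tabulate_agreement() always returns column sums over the records actually present.",
  "swsi_rater_A": {"accurate": "0.61 (61/100)", "lsen": "0.16 (16/100)", "lspe": "0.22 (22/100)"},
  "swsi_rater_B": {"accurate": "0.74 (73/100)", "lsen": "0.11 (11/100)", "lspe": "0.15 (15/100)"},
  "scanner_rater_D": {"accurate": "0.87 (86/100)", "lsen": "0.06 (6/100)", "lspe": "0.07 (7/100)"},
  "scanner_rater_E": {"accurate": "0.75 (75/100)", "lsen": "0.05 (5/100)", "lspe": "0.19 (19/100)"}
}
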