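{
  "comment": "Hand-enumerated survivor counts for each filter applied to toy_filter_table.tsv. wt_background: freq >= wt_mean + 3*wt_sd (A5G 1e-4>=4e-5; A5T 3.9e-5<4e-5 fails; A5V 4e-5>=4e-5 boundary retained; C7R 2e-5>=2e-5 retained; C7S 1.9e-5<2e-5 fails; D9N 5e-4>=0; D9E 5e-5<7e-5 fails; E11K 2e-4>=4e-5). se: se <= 0.3 (fails: A5V 0.31, C7S 0.50). frequency: nonselect_freq >= 5e-5 (passes: A5G, D9N, D9E boundary, E11K). cpm: count/depth >= 10 per million (A5G 10.5; A5T 9.5 fails; A5V 10 boundary; C7R 20; C7S 2.5 fails; D9N 500; D9E 50; E11K 200).",
  "n_records": 8,
  "wt_background": 5,
  "se": 6,
  "frequency": 4,
  "cpm": 6
}
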