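# Example scenario configuration. Probabilities are true per-patient DLT
# probabilities, low dose to high; `monotonize: true` applies the
# running-maximum rule to observed proportions that dip with dose.
scenarios:
  - name: AZD3514-replica
    target: 0.33
    doses:
      - {label: "250 mg QD",   prob: 0.00}
      - {label: "500 mg QD",   prob: 0.00}
      - {label: "1000 mg QD",  prob: 0.17}
      - {label: "1000 mg BID", prob: 0.50}
      - {label: "2000 mg BID", prob: 1.00}
  - name: custom-flat
    target: 0.33
    monotonize: true
    probs: [0.05, 0.10, 0.10, 0.08, 0.40]
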