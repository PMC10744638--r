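C:
- shift: 0
  abundance: 0.9893
- shift: 1
  abundance: 0.0107
H:
- shift: 0
  abundance: 0.999885
- shift: 1
  abundance: 0.000115
'N':
- shift: 0
  abundance: 0.99636
- shift: 1
  abundance: 0.00364
O:
- shift: 0
  abundance: 0.99757
- shift: 1
  abundance: 0.00038
- shift: 2
  abundance: 0.00205
S:
- shift: 0
  abundance: 0.9499
- shift: 1
  abundance: 0.0075
- shift: 2
  abundance: 0.0425
- shift: 4
  abundance: 0.0001
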