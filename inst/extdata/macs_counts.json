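{
  "n_ptb": 530,
  "y_ptb": 166,
  "n_tb": 933,
  "y_tb": 5,
  "source": "MACS cohort, 1463 singleton pregnancies: perinatal mortality/morbidity by preterm (<= 33+6 weeks) vs term birth"
}
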