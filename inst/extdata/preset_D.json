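{
  "m_0": 8640,
  "I_0": 5,
  "S_E": 1.44,
  "S_I": 0.72,
  "gamma": 432,
  "K_f": 141.42135623731,
  "K_g": 4081.25797600037,
  "K_h": 200,
  "k_IN": 71,
  "k_RE": 0.028,
  "k_D": 0.07,
  "beta_TOT": 1,
  "c_max": 22957.759200104,
  "G_0": 80
}
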