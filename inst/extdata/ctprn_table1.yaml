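variant: interface_m
temperature: 283.15
gas_constant: 0.0019872
classes:
  A:
    G_intr: 5.3
    G_int: -9.0
    m_intr: 0.0
    m_int: 0.9
  I:
    G_intr: 4.8
    G_int: -7.7
    m_intr: 0.0
    m_int: 0.6
  S:
    G_intr: 2.95
    G_int: -6.3
    m_intr: 0.0
    m_int: 1.0
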