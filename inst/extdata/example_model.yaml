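# Synthetic example configuration: equilibrated double-flap substrate,
# internal (dsDNA) labeling scheme, 20 nM enzyme.
model:
  k_on: 1.4e+08
  conc: 20
  k_off: 0.45
  E_unbent: 0.27
  E_bent: 0.54
  sigma_E: 0.05
  scheme: dsdna
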