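units:
  ef_m: kg CO2-eq per kg fertilizer-N
  ef_d: kg N2O-N per kg applied N
ef_m:
  urea: 8.09999999999999964
  cf: 7.40000000000000036
  dap: 10.30000000000000071
  abc: 7.20000000000000018
ef_d:
- region: NEC
  crop: maize
  ef: 0.0051
- region: NC
  crop: wheat
  ef: 0.0028
- region: NC
  crop: maize
  ef: 0.007
- region: MLYR
  crop: wheat
  ef: 0.0086
- region: MLYR
  crop: maize
  ef: 0.0067
- region: NWC
  crop: wheat
  ef: 0.0032
- region: NWC
  crop: maize
  ef: 0.0057
- region: SSWC
  crop: wheat
  ef: 0.005
- region: SSWC
  crop: maize
  ef: 0.0047
constants:
  gwp_n2o: 298.0
  n_to_n2o: 1.5714285714285714
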