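# Default material constants for the segment model (MPa, kg/m^3).
# bone_orthotropic lists axial moduli (Yxx, Yyy, Yzz), shear moduli
# (Gxy, Gyz, Gxz) and Poisson ratios (nu_xy, nu_yz, nu_zx).
bone_isotropic:
  E: 3500
  nu: 0.25
  rho: 1908
bone_orthotropic:
  Yxx: 11300
  Yyy: 11300
  Yzz: 22000
  Gxy: 3800
  Gyz: 5400
  Gxz: 5400
  nu_xy: 0.484
  nu_yz: 0.203
  nu_zx: 0.203
  rho: 1908
disc:
  E: 252
  nu: 0.47
  rho: 1120
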