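isotope_13C	1.003355
isotope_13C2	2.006710
NH3	17.026549
H2O_loss	18.010565
Na-H	21.981944
K-H	37.955882
CO2_loss	43.989829
HCOOH	46.005479
CH3COOH	60.021129
HCOONa	67.987424
SO3	79.956815
HPO3	79.966331
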