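# Synthetic reconstruction of the distensibility range of healthy,
# normotensive adult thoracic aortas versus pressure. Magnitudes are
# literature-derived (adult ascending/thoracic aortic distensibility of
# order 1e-3 to 5e-3 per mmHg at physiological pressure, decreasing with
# pressure): lower = 1.1e-3*exp(-0.010*(P-100)),
# upper = 3.8e-3*exp(-0.011*(P-100)). The tabulated values are a smooth
# synthetic envelope, not measured data. Units: mmHg and 1/mmHg.
pressure_mmHg,lower_per_mmHg,upper_per_mmHg
50,0.001814,0.006588
60,0.001641,0.005902
70,0.001485,0.005287
80,0.001343,0.004736
90,0.001216,0.004242
100,0.001100,0.003800
110,0.000995,0.003404
120,0.000901,0.003050
130,0.000815,0.002732
140,0.000737,0.002447
150,0.000667,0.002192
160,0.000604,0.001964
170,0.000546,0.001759
180,0.000494,0.001576
190,0.000447,0.001412
200,0.000405,0.001264
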