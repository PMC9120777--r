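strain	ccmK1	ccmK2	ccmK3	ccmK4	ccmL	ccmM	ccmN	ccmO	ccmP	rbcL	rbcS	rbcX	ccaA	ecaB
Leptodesmis A121	85.2	91.3	56.9	64.8	56.4	49.5	35.0	54.2	72.0	85.1	63.9	41.7	49.7	39.5
Leptolyngbya JSC-1	84.3	91.3	62.9	61.5	67.6	47.1	37.9	58.6	73.7	84.3	68.1	42.2	48.1	41.0
Leptothermofonsia E412	85.2	94.2	63.8	61.8	57.8	48.9	38.2	54.0	72.8	83.9	63.9	42.9	48.6	38.1
Thermoleptolyngbya A183	85.2	x	63.1	63.1	66.0	44.9	37.8	55.6	75.6	83.7	67.8	39.4	39.5	x
Thermoleptolyngbya O-77	85.2	x	63.6	63.1	66.0	41.3	37.4	54.9	76.1	83.5	67.8	38.9	39.3	42.8
Thermostichus 60AY4M2	82.6	88.3	x	x	60.4	49.9	37.8	52.4	67.6	86.3	65.0	44.7	x	x
Thermostichus 63AY4M2	82.6	88.3	x	x	60.4	49.5	37.8	52.1	67.6	86.3	65.0	44.7	x	x
Thermostichus 65AY6A5	82.6	88.3	x	x	60.4	49.7	38.1	52.4	67.6	86.3	65.0	44.7	x	x
Thermostichus 65AY6Li	82.6	88.3	x	x	60.4	49.6	37.8	52.1	67.6	86.3	65.0	44.7	x	x
Thermostichus JA-2-3Ba	81.7	88.3	x	x	63.7	50.3	37.7	53.9	69.0	87.2	64.2	43.9	x	x
Thermostichus JA-3-3Ab	82.6	88.3	x	x	60.4	49.6	37.6	52.1	67.6	86.3	65.0	44.7	x	x
Thermosynechococcus PCC 6715	86.1	90.3	x	x	53.0	42.7	37.5	54.6	67.3	83.9	62.7	44.7	x	42.8
Thermosynechococcus CL-1	86.1	90.3	x	x	54.1	46.0	38.8	54.3	72.8	84.9	63.1	46.0	x	x
Thermosynechococcus TA-1	86.1	90.3	x	x	54.1	46.0	38.7	54.9	72.8	84.9	61.9	45.3	x	x
Thermosynechococcus BP-1	86.1	90.3	x	x	56.3	45.8	35.7	55.0	72.3	84.1	63.3	46.3	x	x
Thermosynechococcus E542	86.1	90.3	x	x	54.1	45.7	36.4	54.4	72.8	84.7	63.9	45.3	x	x
Thermosynechococcus NIES-2134	86.1	90.3	x	x	54.1	45.8	35.7	53.9	72.3	84.3	63.3	46.3	x	x
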