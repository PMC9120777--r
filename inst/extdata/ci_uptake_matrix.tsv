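strain	ndhD4	ndhF4	cupB	ndhD3	ndhF3	cupA	bicA1	bicA2	sbtA	sbtB	cmpA	cmpB	cmpC	cmpD
Leptodesmis A121	60.9	59.7	62.7	61.5	57.2	71.8	65.8	x	x	x	69.2	70.9	73.6	67.2
Leptolyngbya JSC-1	62.6	56.9	62.9	59.6	59.0	81.7	57.3	x	75.9	79.1	63.9	65.2	70.8	72.2
Leptothermofonsia E412	63.8	59.3	64.7	62.8	60.8	84.2	64.8	59.2	x	x	63.0	64.5	70.8	73.6
Thermoleptolyngbya A183	60.3	55.6	62.3	58.8	57.8	85.7	65.5	62.3	70.7	62.5	x	x	x	x
Thermoleptolyngbya O-77	59.0	56.1	61.3	57.7	57.7	84.7	65.5	x	71.9	63.4	68.7	64.8	78.2	75.8
Thermostichus 60AY4M2	57.6	54.5	56.8	58.6	53.8	75.8	60.2	x	x	x	65.8	65.9	72.2	66.8
Thermostichus 63AY4M2	57.4	54.5	56.8	58.6	53.9	75.8	60.2	x	x	x	65.8	66.2	72.1	66.8
Thermostichus 65AY6A5	57.4	54.5	56.8	58.6	53.8	75.8	59.8	x	x	x	65.8	66.2	72.2	66.8
Thermostichus 65AY6Li	57.4	54.5	56.8	58.4	53.9	75.3	60.0	x	x	x	65.4	66.2	72.2	67.1
Thermostichus JA-2-3Ba	57.6	53.6	59.6	58.1	53.4	76.0	59.8	x	x	x	68.2	67.0	71.7	63.3
Thermostichus JA-3-3Ab	57.4	54.5	56.8	58.4	53.9	75.3	60.2	x	x	x	67.5	66.2	71.8	65.0
Thermosynechococcus PCC 6715	56.8	55.5	59.7	59.2	50.4	70.7	x	57.1	81.6	80.9	x	x	x	x
Thermosynechococcus CL-1	59.3	56.7	61.9	61.5	58.1	70.6	x	57.2	74.1	80.9	66.5	59.5	73.1	71.2
Thermosynechococcus TA-1	60.2	56.8	62.6	61.1	58.0	70.8	x	56.8	x	80.2	x	x	x	x
Thermosynechococcus BP-1	60.3	56.8	61.4	61.4	57.7	70.7	x	56.1	x	x	67.7	61.0	73.3	66.8
Thermosynechococcus E542	59.9	57.4	62.0	62.9	59.0	70.4	x	56.4	72.7	81.8	x	x	x	x
Thermosynechococcus NIES-2134	59.9	56.8	61.4	61.6	58.3	70.7	x	53.2	x	x	67.5	68.1	73.0	68.1
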