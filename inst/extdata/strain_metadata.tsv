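strain	species	isolation_source	niche_temperature_c	niche_ph	completeness_pct	contamination_pct	accession
Leptodesmis A121	Leptodesmis sichuanensis A121	Hot spring, Erdaoqiao, Sichuan, China	40.8	6.32	99.53	0.94	GCA_021379005
Leptolyngbya JSC-1	Leptolyngbya sp. JSC-1	La Duke Hot Springs, Montana, United States	60	6.85	99.53	1.30	GCA_000733415
Leptothermofonsia E412	Leptothermofonsia sichuanensis E412	Hot spring, Lotus Lake, Sichuan, China	42.7	8.61	99.29	0.00	GCA_019891175
Thermoleptolyngbya A183	Thermoleptolyngbya sichuanensis A183	Hot spring, Erdaoqiao, Sichuan, China	40.8	6.32	98.94	0.94	GCA_013177315
Thermoleptolyngbya O-77	Thermoleptolyngbya sp. O-77	Hot spring, Kumamoto, Japan	35-60	NA	98.70	1.53	GCA_001548395
Thermostichus 60AY4M2	Thermostichus sp. 60AY4M2	Mushroom Spring, Yellowstone National Park, United States	60	alkaline	100.00	0.88	GCA_002760375
Thermostichus 63AY4M2	Thermostichus sp. 63AY4M2	Mushroom Spring, Yellowstone National Park, United States	63	alkaline	100.00	0.00	GCA_002760475
Thermostichus 65AY6A5	Thermostichus sp. 65AY6A5	Mushroom Spring, Yellowstone National Park, United States	65	alkaline	100.00	0.88	GCA_002760415
Thermostichus 65AY6Li	Thermostichus sp. 65AY6Li	Mushroom Spring, Yellowstone National Park, United States	65	alkaline	99.61	1.32	GCA_002760345
Thermostichus JA-2-3Ba	Thermostichus sp. JA-2-3Ba	Octopus Spring, Yellowstone National Park, United States	58-65	8.5	100.00	0.00	GCA_000013225
Thermostichus JA-3-3Ab	Thermostichus sp. JA-3-3Ab	Octopus Spring, Yellowstone National Park, United States	58-65	8.5	100.00	1.32	GCA_000013205
Thermosynechococcus PCC 6715	Thermosynechococcus lividus PCC 6715	Hot spring, Yellowstone National Park, United States	NA	NA	98.86	0.12	CP018092
Thermosynechococcus CL-1	Thermosynechococcus sp. CL-1	Chin-Lun hot spring, Taiwan, China	62	9.3	100.00	0.12	GCA_008386235
Thermosynechococcus TA-1	Thermosynechococcus sp. TA-1	Taian hot springs, Taiwan, China	50	7-9	100.00	0.12	GCA_017086385
Thermosynechococcus BP-1	Thermosynechococcus vestitus BP-1	Hot spring, Beppu, Japan	52	7.5	99.76	0.12	GCA_000011345
Thermosynechococcus E542	Thermosynechococcus vestitus E542	Hot spring, Lotus lake, Sichuan, China	67.2	7.95	100.00	0.12	GCA_003555505
Thermosynechococcus NIES-2134	Thermosynechococcus vulcanus NIES-2134	Yunomine Hot Spring, Wakayama, Japan	50-57	NA	99.76	0.12	GCA_003990665
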