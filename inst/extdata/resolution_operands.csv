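experiment,analyte,noise_floor,reference_distance,spacing_ppm,printed_resolution_ppm
exp1,water in isopropyl alcohol,33157,864963,10000,383
exp2,water in isopropyl alcohol,19475,156608,2000,249
exp3,NaCl in water,84262,692414,2000,243
exp4,NaOCl in water,96840,2026160,4000,191
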