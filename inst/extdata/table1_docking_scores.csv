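compound,target,score_kcal_mol,group
Piperine,MAO-A,-7.96,query
Lazabemide,MAO-A,-6.06,control
Rasagiline,MAO-A,-5.96,control
Selegiline,MAO-A,-5.90,control
Compound 1,MAO-A,-8.5,predicted
Compound 2,MAO-A,-9.8,predicted
Compound 3,MAO-A,-9.5,predicted
Compound 4,MAO-A,-8.5,predicted
Compound 5,MAO-A,-8.1,predicted
Piperine,MAO-B,-7.7,query
Lazabemide,MAO-B,-5.7,control
Rasagiline,MAO-B,-6.1,control
Selegiline,MAO-B,-6.3,control
Compound 1,MAO-B,-9.6,predicted
Compound 2,MAO-B,-9.3,predicted
Compound 3,MAO-B,-8.8,predicted
Compound 4,MAO-B,-9.5,predicted
Compound 5,MAO-B,9.3,predicted
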