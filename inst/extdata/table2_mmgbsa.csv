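compound,target,e_bond,e_vdw,e_elec,g_pb,g_sa,ts_s,dg_reported,group
Rasagiline,MAO-A,,-34.36,-0.29,,-3.34,,-33.00,control
Lazabemide,MAO-A,,-33.69,-0.22,,-3.10,,-31.72,control
Selegiline,MAO-A,,-40.77,-0.54,,-4.13,,-39.42,control
Piperine,MAO-A,,-56.88,-4.15,,-5.49,,-51.77,query
Compound 1,MAO-A,,-64.16,-3.15,,-6.07,,-59.24,predicted
Compound 2,MAO-A,,-57.56,-0.85,,-5.53,,-53.31,predicted
Compound 3,MAO-A,,-59.44,-4.83,,-5.52,,-51.32,predicted
Compound 4,MAO-A,,-52.80,-2.95,,-5.49,,-49.08,predicted
Compound 5,MAO-A,,-45.60,-2.29,,-5.51,,-43.63,predicted
Rasagiline,MAO-B,,-40.56,-1.71,,-3.56,,-38.60,control
Lazabemide,MAO-B,,-35.01,-0.27,,-3.44,,-33.19,control
Selegiline,MAO-B,,-40.44,-0.35,,-4.28,,-38.23,control
Piperine,MAO-B,,-57.66,-4.19,,-5.25,,-52.69,query
Compound 1,MAO-B,,-63.52,-3.26,,-5.91,,-59.81,predicted
Compound 2,MAO-B,,-57.01,-2.02,,-5.61,,-51.90,predicted
Compound 3,MAO-B,,-58.30,-4.59,,-5.79,,-52.57,predicted
Compound 4,MAO-B,,-61.57,-4.22,,-5.30,,-53.95,predicted
Compound 5,MAO-B,,-60.75,-3.984,,-5.444,,-55.17,predicted
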