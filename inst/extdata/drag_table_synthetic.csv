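theta_deg,F_kJ_mol_nm,v_m_s,mu_Pa_s,role
0,0.03,1.2,0.00085,central
10,0.0911,1.2,0.00085,central
20,0.1522,1.2,0.00085,central
30,0.2133,1.2,0.00085,central
40,0.2744,1.2,0.00085,central
50,0.3356,1.2,0.00085,central
60,0.3967,1.2,0.00085,central
70,0.4578,1.2,0.00085,central
80,0.5189,1.2,0.00085,central
90,0.58,1.2,0.00085,central
0,2.9,1.2,0.00085,tail
10,1.9439,1.2,0.00085,tail
20,1.3031,1.2,0.00085,tail
30,0.8735,1.2,0.00085,tail
40,0.5855,1.2,0.00085,tail
50,0.3925,1.2,0.00085,tail
60,0.2631,1.2,0.00085,tail
70,0.1763,1.2,0.00085,tail
80,0.1182,1.2,0.00085,tail
90,0.0792,1.2,0.00085,tail
0,-2.6,1.2,0.00085,head
10,-1.7428,1.2,0.00085,head
20,-1.1683,1.2,0.00085,head
30,-0.7831,1.2,0.00085,head
40,-0.5249,1.2,0.00085,head
50,-0.3519,1.2,0.00085,head
60,-0.2359,1.2,0.00085,head
70,-0.1581,1.2,0.00085,head
80,-0.106,1.2,0.00085,head
90,-0.071,1.2,0.00085,head
0,4.7,1.2,0.00085,single
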