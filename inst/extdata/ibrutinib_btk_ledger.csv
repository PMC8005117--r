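residue,modes,dE_gas,dE_deh,dE_aq
Met477,"H-bond, CH-pi",-4.1,3.8,-0.3
Lys481,"H-bond",-3.6,3.3,-0.3
Tyr476,"pi-pi, CH-pi",-4.0,2.5,-1.5
Phe540,"pi-pi, NH-pi",-2.8,0.4,-2.4
Lys430,"cation-pi, NH-pi, CH-pi",-12.8,5.4,-7.3
Val416,"CH-pi",-3.0,0.1,-2.9
Ala428,"CH-pi",-1.5,-0.1,-1.6
Val458,"CH-pi",-1.2,-0.1,-1.3
Ile472,"CH-pi",-1.4,0.0,-1.4
Leu528,"CH-pi",-3.9,1.2,-2.7
Leu542,"CH-pi",-1.4,0.0,-1.4
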