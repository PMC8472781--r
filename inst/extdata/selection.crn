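volume 1
beta 1
species Hi chemostat 1000
species Lo chemostat 5
species X1
species X2
species X3
species B1
species B2
species B3
species Re
reaction Re + 2 X1 <-> 3 X1 ; kf=1e-06 kb=1e-06 label=auto_X1
reaction Re + 2 X2 <-> 3 X2 ; kf=1e-06 kb=1e-06 label=auto_X2
reaction Re + 2 X3 <-> 3 X3 ; kf=1e-06 kb=1e-06 label=auto_X3
reaction X1 + X2 + X3 <-> Lo + X2 + X3 ; kf=0.001 kb=0.001 label=decay_X1
reaction X2 + X1 + X3 <-> Lo + X1 + X3 ; kf=0.001 kb=0.001 label=decay_X2
reaction X3 + X1 + X2 <-> Lo + X1 + X2 ; kf=0.001 kb=0.001 label=decay_X3
reaction Hi + 2 X1 <-> B1 + 2 X1 ; kf=1e-05 kb=1e-05 label=synth_B1
reaction B1 <-> Lo ; kf=1 kb=1 label=bdecay_B1
reaction B1 + 2 X1 <-> Re + 2 X1 ; kf=1e-06 kb=1e-06 label=bif_B1
reaction Hi + 2 X2 <-> B2 + 2 X2 ; kf=1e-05 kb=1e-05 label=synth_B2
reaction B2 <-> Lo ; kf=1 kb=1 label=bdecay_B2
reaction B2 + 2 X2 <-> Re + 2 X2 ; kf=3e-07 kb=3e-07 label=bif_B2
reaction Hi + 2 X3 <-> B3 + 2 X3 ; kf=1e-05 kb=1e-05 label=synth_B3
reaction B3 <-> Lo ; kf=1 kb=1 label=bdecay_B3
reaction B3 + 2 X3 <-> Re + 2 X3 ; kf=1e-07 kb=1e-07 label=bif_B3
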