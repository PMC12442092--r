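system_id,label,role,G_rel_kcal
RF-9-BBN+acetone,I1,intermediate,0.0
RF-9-BBN+acetone,I2,intermediate,-0.3
RF-9-BBN+acetone,I3,intermediate,-3.0
RF-9-BBN+acetone,TS1,transition_state,13.9
RF-9-BBN+acetone,I4,intermediate,-1.6
RF-9-BBN+acetone,TS2,transition_state,42.4
RF-9-BBN+acetone,I5,intermediate,-7.4
RF-9-BBN+acetone,P,product,-0.6
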